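# Brute-force evaluation of the weighted squared-covariance objective:
# literal double loop over ordered block pairs.
brute_objective <- function(chi, W, alphas) {
  J <- length(chi)
  tot <- 0
  for (j in seq_len(J)) for (k in seq_len(J)) {
    if (k == j) next
    cov <- drop(t(alphas[[j]]) %*% t(chi[[j]]) %*% chi[[k]] %*% alphas[[k]])
    tot <- tot + W[j, k] * cov^2
  }
  tot
}

test_that("objectiveValue matches a literal double-loop oracle", {
  set.seed(5)
  N <- 8
  ps <- c(3, 3, 3)
  raw <- lapply(ps, function(p) matrix(rnorm(N * p), N, p))
  d <- prepareBlocks(raw)
  W <- matrix(c(0, 1, 2, 1, 0, 0.5, 2, 0.5, 0), 3, 3)
  g <- blockGraph(matrix(as.numeric(W > 0), 3, 3), W)
  for (rep in 1:5) {
    al <- lapply(ps, function(p) rnorm(p))
    expect_equal(objectiveValue(d, g, al),
                 brute_objective(blocks(d), W, al), tolerance = 1e-12)
  }
})

test_that("objectiveValue is zero at zero loadings and 2N^2 for identical unit-variance scores", {
  set.seed(6)
  N <- 12
  v <- rnorm(N); v <- (v - mean(v)); v <- v * sqrt(N) / sqrt(sum(v^2))
  d <- prepareBlocks(list(matrix(v), matrix(v)))
  g <- full_graph(2)
  expect_identical(objectiveValue(d, g, list(0, 0)), 0)
  # ||chi alpha||^2 = N for both blocks and perfect covariance: N^2 per
  # ordered pair, both pairs counted
  expect_equal(objectiveValue(d, g, list(1, 1)), 2 * N^2, tolerance = 1e-10)
})

test_that("objectiveValue uses C instead of D under sgccaMode", {
  d <- make_toy_data(n = 15, ps = c(3, 3), seed = 2)
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 1] <- 1; C[1, 3] <- C[3, 1] <- 1
  D <- C * 3
  g <- blockGraph(C, D)
  al <- lapply(blocks(d), function(b) rnorm(ncol(b)))
  expect_equal(objectiveValue(d, g, al, sgccaMode = TRUE) * 3,
               objectiveValue(d, g, al), tolerance = 1e-12)
})

test_that("innerComponent equals naive term-by-term accumulation", {
  set.seed(7)
  N <- 6
  ps <- c(2, 3, 4, 2)
  d <- prepareBlocks(lapply(ps, function(p) matrix(rnorm(N * p), N, p)))
  W <- matrix(runif(16), 4, 4); W <- (W + t(W)) / 2; diag(W) <- 0
  g <- blockGraph(matrix(1, 4, 4) - diag(4), W)
  al <- lapply(ps, function(p) rnorm(p))
  chi <- blocks(d)
  for (j in 1:4) {
    ups <- numeric(N)
    vj <- drop(chi[[j]] %*% al[[j]])
    for (k in setdiff(1:4, j)) {
      vk <- drop(chi[[k]] %*% al[[k]])
      ups <- ups + W[j, k] * sum(vj * vk) * vk
    }
    expect_equal(innerComponent(j, d, g, al), ups, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("innerComponent of an unconnected block is zero", {
  d <- make_toy_data(n = 10, ps = c(3, 3), seed = 3, labels = FALSE)
  C <- matrix(0, 2, 2)
  g <- blockGraph(C)
  al <- lapply(blocks(d), function(b) rnorm(ncol(b)))
  expect_equal(innerComponent(1, d, g, al), numeric(10))
})

test_that("ustUpdate soft-thresholds columnwise inner products", {
  X <- diag(3)
  u <- c(2, -0.5, 1.2)
  expect_equal(ustUpdate(X, u, 1), c(1, 0, 0.2))
  expect_equal(ustUpdate(X, u, 0), u)          # no shrinkage
  expect_equal(ustUpdate(X, u, 2.5), c(0, 0, 0))  # full shrinkage
  expect_error(ustUpdate(X, u, -0.1), "nonnegative")
})

test_that("support size is non-increasing in lambda", {
  set.seed(8)
  X <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
  u <- rnorm(20)
  lams <- seq(0, max(abs(crossprod(X, u))), length.out = 25)
  nnz <- vapply(lams, function(l) sum(ustUpdate(X, u, l) != 0), integer(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("normalizeLoading enforces the score-norm contract", {
  set.seed(9)
  X <- scale(matrix(rnorm(120), 15, 8), scale = FALSE)
  for (rep in 1:5) {
    a <- rnorm(8) * sample(c(0, 1), 8, replace = TRUE)
    if (all(a == 0)) a[1] <- 1
    an <- normalizeLoading(a, X)
    expect_equal(sum(drop(X %*% an)^2), 15, tolerance = 1e-8)
    expect_identical(which(an != 0), which(a != 0))  # sparsity unchanged
    expect_equal(normalizeLoading(7 * a, X), an, tolerance = 1e-12)
  }
  au <- normalizeLoading(rnorm(8), X, convention = "unit")
  expect_equal(sum(drop(X %*% au)^2), 1, tolerance = 1e-10)
  z <- normalizeLoading(numeric(8), X)
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_equal(unname(z[1:8]), numeric(8))
})

test_that("selectLambdaCV honors degenerate grids and the sparser tie-break", {
  set.seed(10)
  X <- scale(matrix(rnorm(60), 30, 2), scale = FALSE)
  u <- rnorm(30)
  expect_identical(selectLambdaCV(X, u, grid = 0.7), 0.7)
  expect_error(selectLambdaCV(X, u, grid = numeric()), "empty")
  expect_error(selectLambdaCV(X, u, K = 1), ">= 2")
  # single predictive column: every non-annihilating lambda refits to the
  # same prediction, so CV errors tie and the largest candidate wins
  X1 <- scale(matrix(rnorm(40), 40, 1), scale = FALSE)
  u1 <- drop(X1) * 2
  grid <- c(0.1, 0.3, 0.5) * max(abs(crossprod(X1, u1)))
  expect_identical(selectLambdaCV(X1, u1, grid = grid), grid[3])
})

test_that("selectLambdaCV recovers a noise-free sparse signal", {
  set.seed(11)
  X <- scale(matrix(rnorm(600), 60, 10), scale = FALSE)
  beta <- c(3, -2, rep(0, 8))
  u <- drop(X %*% beta)
  lam <- selectLambdaCV(X, u, K = 5)
  a <- ustUpdate(X, u, lam)
  expect_true(all(a[1:2] != 0))  # true columns retained
})

test_that("deflation removes the fitted span and is idempotent", {
  set.seed(12)
  base <- rnorm(20)
  X1 <- outer(base, c(1, 2, -1))        # rank-1 block
  X2 <- matrix(rnorm(20 * 4), 20, 4)
  d <- prepareBlocks(list(X1, X2))
  al <- list(c(1, 0.5, 0), rnorm(4))
  d1 <- deflateBlocks(d, al)
  expect_lt(max(abs(blocks(d1)[[1]])), 1e-8)    # span removed entirely
  v2 <- drop(blocks(d)[[2]] %*% al[[2]])
  expect_lt(max(abs(crossprod(blocks(d1)[[2]], v2))), 1e-8)
  # re-deflating with the same loading changes nothing further
  expect_equal(blocks(deflateBlocks(d1, al))[[2]], blocks(d1)[[2]],
               tolerance = 1e-10)
})

test_that("deflation skips the class block by default", {
  d <- make_toy_data(n = 20, ps = c(3, 3), seed = 4)
  al <- list(rnorm(3), rnorm(3), 1)
  d1 <- deflateBlocks(d, al)
  expect_identical(blocks(d1)[[classIndex(d)]], blocks(d)[[classIndex(d)]])
})

test_that("two collinear blocks at lambda = 0 reach the analytic maximum", {
  set.seed(13)
  X <- matrix(rnorm(30 * 4), 30, 4)
  d <- prepareBlocks(list(X, X))
  g <- full_graph(2)
  opt <- fitOptions(nRanks = 1, lambdaGrid = 0, seed = 13, maxIter = 200,
                    discriminant = FALSE)
  set.seed(13)
  rk <- fitRank(d, g, opt)
  # perfect correlation achievable: squared covariance N^2 per ordered pair
  expect_equal(max(rk$objectiveTrace), 2 * 30^2, tolerance = 1e-4)
  expect_true(rk$converged)
})

test_that("infinite tolerance stops after exactly one sparse sweep", {
  d <- make_toy_data(n = 25, ps = c(4, 4), seed = 14)
  g <- full_graph(3, names = c("B1", "B2", "CLASS"))
  opt <- fitOptions(nRanks = 1, tol = Inf, warmMaxIter = 0, seed = 14)
  set.seed(14)
  rk <- fitRank(d, g, opt)
  expect_identical(rk$sweeps, 1L)
  expect_length(rk$objectiveTrace, 1L)
  expect_true(rk$converged)
})

test_that("fits are bit-reproducible from the seed", {
  s <- small_sim(n = 60, seed = 3)
  f1 <- multidaFit(s$data, options = fitOptions(nRanks = 2, seed = 21))
  f2 <- multidaFit(s$data, options = fitOptions(nRanks = 2, seed = 21))
  expect_identical(f1@loadings, f2@loadings)
  expect_identical(f1@lambdas, f2@lambdas)
  expect_identical(f1@objectiveTrace, f2@objectiveTrace)
})

test_that("a single-rank fit equals one seeded fitRank call", {
  s <- small_sim(n = 60, seed = 4)
  opt <- fitOptions(nRanks = 1, seed = 5)
  fit <- multidaFit(s$data, options = opt)
  set.seed(5)
  rk <- fitRank(s$data, defaultGenomicGraph(), opt)
  expect_identical(blockLoadings(fit, 1), rk$loadings)
})

test_that("an annihilating shrinkage level yields zero effective ranks", {
  s <- small_sim(n = 50, seed = 6)
  fit <- multidaFit(s$data,
                    options = fitOptions(nRanks = 3, lambdaGrid = 1e12,
                                         seed = 1))
  expect_identical(nRanks(fit), 0L)
})

test_that("slack-off fits reduce exactly to the binary-weight objective path", {
  s <- small_sim(n = 80, seed = 7)
  gC <- blockGraph(designMatrix(defaultGenomicGraph()),
                   blockNames = blockNames(defaultGenomicGraph()))
  f_plain <- multidaFit(s$data, gC,
                        fitOptions(nRanks = 2, seed = 9,
                                   discriminant = FALSE))
  f_sg <- multidaFit(s$data, defaultGenomicGraph(),
                     fitOptions(nRanks = 2, seed = 9, sgccaMode = TRUE))
  expect_identical(f_plain@loadings, f_sg@loadings)
  # and no slack state is kept in either
  expect_true(all(lengths(f_plain@slack) == 0))
  expect_true(all(lengths(f_sg@slack) == 0))
})

test_that("the objective trace never decreases within a rank", {
  for (s in 1:4) {
    sim <- small_sim(n = 50, seed = s)
    fit <- multidaFit(sim$data, options = fitOptions(nRanks = 2, seed = s))
    for (r in seq_len(nRanks(fit))) {
      tr <- objectiveTrace(fit, r)
      if (length(tr) > 1)
        expect_true(all(diff(tr) >= -1e-9 * pmax(1, abs(tr[-length(tr)]))))
    }
  }
})
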