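test_that("generator moments match their analytic values", {
  set.seed(41)
  n <- 1e5
  x1 <- generateColumns("type1", n, mu = 2.4)
  expect_equal(mean(x1), 2.4, tolerance = 0.02 / 2.4)
  expect_equal(var(drop(x1)), 1, tolerance = 0.02)
  # E[type2] = mu + delta
  x2 <- generateColumns("type2", n, mu = 1, delta = 0.6)
  expect_lt(abs(mean(x2) - 1.6), 0.02)
  # AR(1): lag-1 correlation rho, lag-2 rho^2
  x3 <- generateColumns("type3", n, p = 3, mu = 0, rho = 0.8)
  expect_lt(abs(cor(x3[, 1], x3[, 2]) - 0.8), 0.02)
  expect_lt(abs(cor(x3[, 1], x3[, 3]) - 0.64), 0.02)
  # type4 variance parameter is a variance, not an sd
  x4 <- generateColumns("type4", n, mu = 2, sigma = 2)
  expect_lt(abs(mean(x4) - 2), 0.02)
  expect_lt(abs(var(drop(x4)) - 2), 0.04)
})

test_that("generator parameter validation rejects bad values", {
  expect_error(generateColumns("type2", 10, delta = 1.4), "delta")
  expect_error(generateColumns("type3", 10, p = 2, rho = 1), "rho")
  expect_error(generateColumns("type4", 10, sigma = 0), "sigma")
})

test_that("the AR(1) covariance is symmetric positive-definite", {
  for (rho in c(-0.9, 0, 0.5, 0.99)) {
    S <- ar1Covariance(12, rho)
    expect_equal(S, t(S))
    expect_equal(S[1, 4], rho^3)
    expect_no_error(chol(S))
  }
})

test_that("design blocks follow the published column layout", {
  set.seed(42)
  bl <- buildDesignBlocks(20000)
  expect_identical(vapply(bl, ncol, integer(1)),
                   c(SNP = 100L, CNV = 200L, DM = 300L))
  # spot-check segment moments at large n
  expect_lt(max(abs(colMeans(bl$SNP[, 1:5]) - 2.4)), 0.05)
  expect_lt(max(abs(colMeans(bl$SNP[, 6:10]) + 2.6)), 0.05)
  expect_lt(abs(mean(bl$SNP[, 11:40]) - 1.6), 0.05)      # Type2(1, 0.6)
  expect_lt(abs(cor(bl$SNP[, 41], bl$SNP[, 42]) - 0.8), 0.05)
  expect_lt(abs(mean(bl$CNV[, 61:200]) - 2), 0.05)       # Type4(2, 2)
  expect_lt(abs(var(bl$CNV[, 100]) - 2), 0.1)
  expect_lt(abs(var(bl$DM[, 100]) - 1), 0.1)             # Type4(0, 1)
  expect_lt(abs(cor(bl$DM[, 211], bl$DM[, 212]) - 0.9), 0.05)
})

test_that("response coefficients live in the leading signal corner only", {
  set.seed(43)
  bl <- buildDesignBlocks(200)
  resp <- buildResponseBlock(bl)
  expect_identical(ncol(resp$X4), 50L)
  for (Bj in resp$B) {
    expect_true(all(Bj[-(1:10), ] == 0))          # rows beyond ten are zero
    expect_true(all(Bj[, -(1:10)] == 0))
    expect_true(all(Bj[1:10, 1:10] != 0))
    expect_true(all(abs(Bj[1:10, 1:10]) >= 0.5 &
                    abs(Bj[1:10, 1:10]) <= 1.5))
  }
  # residual after removing the linear part is the unit-variance noise
  lin <- Reduce(`+`, Map(`%*%`, bl, resp$B))
  expect_lt(abs(sd(resp$X4 - lin) - 1), 0.05)
})

test_that("class labels follow the logistic model", {
  set.seed(44)
  # flat predictor: every sample sits exactly at pi = 0.5
  X4 <- matrix(1, 50, 4) %*% diag(c(1, 2, 3, 4))
  cls <- buildClassBlock(X4, nSignal = 2)
  expect_identical(unique(cls$pi), 0.5)
  expect_true(all(cls$labels %in% c(-1, 1)))
  # empirical class frequency tracks mean(pi)
  set.seed(45)
  X4b <- matrix(rnorm(1e4 * 5), 1e4, 5)
  clsb <- buildClassBlock(X4b, nSignal = 3)
  expect_lt(abs(mean(clsb$labels == 1) - mean(clsb$pi)), 0.02)
})

test_that("simulated datasets have the documented shape and truth record", {
  sim <- simulateMultiblock(n = 500, seed = 46)
  expect_identical(vapply(blocks(sim$data), ncol, integer(1)),
                   c(100L, 200L, 300L, 50L, 1L))
  expect_identical(nrow(blocks(sim$data)[[1]]), 500L)
  expect_identical(blockNames(sim$data), c("SNP", "CNV", "DM", "GE", "CLASS"))
  expect_false(isPrepared(sim$data))
  masks <- truthMasks(sim$truth)
  expect_identical(vapply(masks, sum, numeric(1)),
                   c(SNP = 10, CNV = 10, DM = 10, GE = 10))
  expect_true(all(masks$SNP[1:10]))
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulateMultiblock(n = 40, seed = 47)
  s2 <- simulateMultiblock(n = 40, seed = 47)
  expect_identical(blocks(s1$data), blocks(s2$data))
  expect_identical(s1$truth@coefficients, s2$truth@coefficients)
  s3 <- simulateMultiblock(n = 40, seed = 48)
  expect_false(identical(blocks(s1$data)[[1]], blocks(s3$data)[[1]]))
})

test_that("signal columns covary with the response more than noise columns", {
  sim <- simulateMultiblock(n = 500, seed = 49)
  d <- prepareBlocks(sim$data)
  X4sig <- blocks(d)[[4]][, 1:10]
  for (j in 1:3) {
    cv <- abs(crossprod(blocks(d)[[j]], X4sig))
    expect_gt(mean(cv[1:10, ]), mean(cv[-(1:10), ]))
  }
})
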