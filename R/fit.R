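#' Create fitting options
#'
#' Constructor for [FitOptions-class] with the package defaults: 3 ranks,
#' at most 100 Wold sweeps per rank at relative tolerance 1e-6, 5-fold
#' cross-validation over an automatic 20-point lambda grid, discriminant
#' slack enabled, and the `||chi alpha||^2 = N` normalization.
#'
#' @param nRanks,maxIter,tol,cvFolds,lambdaGrid,seed,discriminant,sgccaMode,normalization,cvEverySweep,warmMaxIter
#'   see [FitOptions-class].
#' @return a validated [FitOptions-class] object.
#' @export
fitOptions <- function(nRanks = 3L, maxIter = 100L, tol = 1e-6,
                       cvFolds = 5L, lambdaGrid = "auto", seed = 1L,
                       discriminant = TRUE, sgccaMode = FALSE,
                       normalization = "sqrtN", cvEverySweep = FALSE,
                       warmMaxIter = 25L) {
  new("FitOptions", nRanks = as.integer(nRanks),
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      cvFolds = as.integer(cvFolds), lambdaGrid = lambdaGrid,
      seed = as.integer(seed), discriminant = isTRUE(discriminant),
      sgccaMode = isTRUE(sgccaMode), normalization = normalization,
      cvEverySweep = isTRUE(cvEverySweep),
      warmMaxIter = as.integer(warmMaxIter))
}

# One full block-update sweep (Gauss-Seidel over `ord`), in place on `st`.
# st: list(chi, V, alpha, m, b) ; lambdas: per-block thresholds, selected
# against targets of norm `tnorm0`; each update rescales its threshold by
# the current target norm so the sparsity level is invariant to the
# covariance prefactor of the inner component.
.wold_sweep <- function(st, ord, W, ci, dblock, disc, conv, lambdas,
                        tnorm0 = NULL) {
  for (j in ord) {
    cv <- drop(crossprod(st$V, st$V[, j]))
    cv[j] <- 0
    ups <- drop(st$V %*% (W[j, ] * cv))
    lam <- lambdas[j]
    if (!is.null(tnorm0) && lam > 0 && tnorm0[j] > 0)
      lam <- lam * sqrt(sum(ups^2)) / tnorm0[j]
    a <- if (disc && !is.na(dblock) && j == dblock)
      updateDiscriminantLoading(st$chi[[j]], ups, lam)
    else
      ustUpdate(st$chi[[j]], ups, lam)
    a <- normalizeLoading(a, st$chi[[j]], conv)
    if (isTRUE(attr(a, "degenerate"))) {
      st$degenerate <- j
      return(st)
    }
    st$alpha[[j]] <- a
    st$V[, j] <- st$chi[[j]] %*% a
  }
  if (disc) {
    st$m <- updateSlack(st$chi[[dblock]], st$alpha[[dblock]], st$V[, ci], st$b)
    st$chi[[ci]] <- augmentedClassBlock(st$chi0ci, st$b, st$m)
    a <- normalizeLoading(st$alpha[[ci]], st$chi[[ci]], conv)
    if (isTRUE(attr(a, "degenerate"))) {
      st$degenerate <- ci
      return(st)
    }
    st$alpha[[ci]] <- a
    st$V[, ci] <- st$chi[[ci]] %*% a
  }
  st$degenerate <- NA_integer_
  st
}

.state_objective <- function(st, W) {
  covs <- crossprod(st$V)
  diag(covs) <- 0
  sum(W * covs^2)
}

#' Fit a single rank (component) of the multiblock model
#'
#' The core Wold iteration: blocks are updated cyclically (feature blocks,
#' then the class block, then the discriminant block last so it sees fresh
#' neighbor scores); each update soft-thresholds the regression of the
#' block's inner component on the block and renormalizes. When the
#' discriminant is active, each sweep ends with the slack update
#' `m = max(b * (v_ge - v_class), 0)` and the slack-augmented class block is
#' refreshed. The run starts from a seeded random loading, converges a dense
#' (lambda = 0) warm start first, selects each block's lambda once by
#' cross-validation against the warm inner components, then iterates the
#' sparse problem until the relative objective change drops below `tol`.
#' A sweep that would decrease the objective is rolled back and the rank is
#' declared converged (ascent-only acceptance), so the recorded trace is
#' non-decreasing.
#'
#' Uses the current RNG stream; seed via `set.seed()` or use [multidaFit()],
#' which seeds from `options@seed`.
#'
#' @param data a prepared [MultiblockData-class].
#' @param graph a [BlockGraph-class] over the same blocks.
#' @param options a [FitOptions-class].
#' @return a list with elements `loadings`, `scores`, `lambdas`,
#'   `objectiveTrace`, `warmTrace`, `converged`, `degenerate` (per-block
#'   logical), `slack` (`list(b, m)` or empty), and `sweeps`.
#' @export
fitRank <- function(data, graph, options = fitOptions()) {
  stopifnot(is(data, "MultiblockData"), is(graph, "BlockGraph"),
            is(options, "FitOptions"))
  validObject(options)
  if (!isPrepared(data)) stop("data must be prepared (see prepareBlocks)")
  J <- nBlocks(data)
  if (nBlocks(graph) != J)
    stop("graph and data disagree on the number of blocks")
  bl <- blocks(data)
  N <- nrow(bl[[1L]])
  ci <- classIndex(data)
  W <- if (options@sgccaMode) graph@C else graph@D
  conv <- options@normalization
  tol <- options@tol

  # update order: plain feature blocks, class block, discriminant block last
  dblock <- NA_integer_
  if (!is.na(ci)) {
    nb <- which(graph@C[ci, ] == 1)
    if (length(nb)) dblock <- nb[which.max(graph@D[ci, nb])]
    ord <- c(setdiff(seq_len(J), c(ci, dblock)), ci, dblock)
    ord <- ord[!is.na(ord)]
  } else ord <- seq_len(J)
  disc <- options@discriminant && !options@sgccaMode && !is.na(ci) &&
    !is.na(dblock)

  zero_result <- function(converged) {
    list(loadings = lapply(bl, function(x) numeric(ncol(x))),
         scores = lapply(bl, function(x) numeric(N)),
         lambdas = rep(NA_real_, J), objectiveTrace = numeric(),
         warmTrace = numeric(), converged = converged,
         degenerate = rep(TRUE, J),
         slack = if (disc) list(b = drop(bl[[ci]]), m = numeric(N)) else list(),
         sweeps = 0L)
  }

  st <- list(chi = bl, V = NULL, alpha = vector("list", J),
             m = numeric(N), b = if (!is.na(ci)) drop(bl[[ci]]) else NULL,
             chi0ci = if (!is.na(ci)) bl[[ci]] else NULL,
             degenerate = NA_integer_)
  for (j in seq_len(J)) {
    a <- normalizeLoading(stats::rnorm(ncol(bl[[j]])), st$chi[[j]], conv)
    if (isTRUE(attr(a, "degenerate"))) return(zero_result(TRUE))
    st$alpha[[j]] <- a
  }
  st$V <- .score_matrix(st$chi, st$alpha)

  # dense warm start: the plain (lambda = 0) multiblock problem
  warmTrace <- numeric()
  obj <- .state_objective(st, W)
  zeros <- rep(0, J)
  for (it in seq_len(options@warmMaxIter)) {
    st <- .wold_sweep(st, ord, W, ci, dblock, disc, conv, zeros)
    if (!is.na(st$degenerate)) return(zero_result(TRUE))
    objn <- .state_objective(st, W)
    warmTrace <- c(warmTrace, objn)
    if (abs(objn - obj) <= tol * max(1, abs(obj))) { obj <- objn; break }
    obj <- objn
  }

  # per-block shrinkage by K-fold CV against the warm inner components;
  # the target norm at selection time anchors the per-sweep rescaling
  pick_lambda <- function() {
    lam <- tn <- numeric(J)
    for (j in seq_len(J)) {
      cv <- drop(crossprod(st$V, st$V[, j]))
      cv[j] <- 0
      ups <- drop(st$V %*% (W[j, ] * cv))
      tn[j] <- sqrt(sum(ups^2))
      lam[j] <- selectLambdaCV(st$chi[[j]], ups, K = options@cvFolds,
                               grid = options@lambdaGrid)
    }
    list(lam = lam, tn = tn)
  }
  sel <- pick_lambda()
  lambdas <- sel$lam
  tnorm0 <- sel$tn

  trace <- numeric()
  converged <- FALSE
  prev_obj <- NA_real_
  prev_st <- NULL
  sweeps <- 0L
  for (it in seq_len(options@maxIter)) {
    if (options@cvEverySweep && it > 1L) {
      sel <- pick_lambda()
      lambdas <- sel$lam
      tnorm0 <- sel$tn
    }
    prev_st <- st
    st <- .wold_sweep(st, ord, W, ci, dblock, disc, conv, lambdas, tnorm0)
    if (!is.na(st$degenerate)) {
      if (it == 1L) return(zero_result(TRUE))
      st <- prev_st           # keep the last accepted iterate
      converged <- TRUE
      break
    }
    obj <- .state_objective(st, W)
    sweeps <- it
    if (it == 1L) {
      trace <- obj
      if (!is.finite(tol)) { converged <- TRUE; break }
    } else {
      if (obj < prev_obj - 1e-12 * max(1, abs(prev_obj))) {
        st <- prev_st          # ascent-only acceptance: roll back and stop
        converged <- TRUE
        break
      }
      trace <- c(trace, obj)
      if (abs(obj - prev_obj) <= tol * max(1, abs(prev_obj))) {
        converged <- TRUE
        break
      }
    }
    prev_obj <- obj
  }

  scores <- lapply(seq_len(J), function(j) {
    v <- drop(st$V[, j])
    names(v) <- rownames(bl[[1L]])
    v
  })
  loadings <- lapply(seq_len(J), function(j) {
    a <- drop(st$alpha[[j]])
    attributes(a) <- NULL
    names(a) <- colnames(bl[[j]])
    a
  })
  list(loadings = loadings, scores = scores, lambdas = lambdas,
       objectiveTrace = trace, warmTrace = warmTrace, converged = converged,
       degenerate = vapply(loadings, function(a) all(a == 0), logical(1)),
       slack = if (disc) list(b = st$b, m = st$m) else list(),
       sweeps = sweeps)
}

#' Fit the sparse multiblock discriminant model
#'
#' Extracts `options@nRanks` components: each rank is fit with [fitRank()],
#' then every feature block is residualized against its own latent score
#' ([deflateBlocks()]) before the next rank. Extraction stops early when a
#' rank comes back with all-zero loadings (the data hold no further
#' information at the selected sparsity). The RNG is seeded once from
#' `options@seed`, making the whole fit bit-reproducible.
#'
#' @param data a prepared [MultiblockData-class] (see [prepareBlocks()]).
#' @param graph a [BlockGraph-class]; defaults to [defaultGenomicGraph()]
#'   when the data have five blocks.
#' @param options a [FitOptions-class].
#' @return a [LoadingSet-class].
#' @examples
#' sim <- simulateMultiblock(n = 60, seed = 7)
#' dat <- prepareBlocks(sim$data)
#' fit <- multidaFit(dat, options = fitOptions(nRanks = 1, seed = 1))
#' fit
#' @export
multidaFit <- function(data, graph = NULL, options = fitOptions()) {
  stopifnot(is(data, "MultiblockData"))
  if (is.null(graph)) {
    if (nBlocks(data) != 5L)
      stop("supply a graph: the default genomic graph needs five blocks")
    graph <- defaultGenomicGraph()
  }
  validObject(options)
  set.seed(options@seed)
  cur <- data
  ranks <- list()
  for (r in seq_len(options@nRanks)) {
    rk <- fitRank(cur, graph, options)
    if (all(rk$degenerate)) break
    ranks[[length(ranks) + 1L]] <- rk
    if (r < options@nRanks)
      cur <- deflateBlocks(cur, rk$loadings)
  }
  new("LoadingSet",
      blockNames = blockNames(data),
      featureNames = lapply(blocks(data), colnames),
      sampleIDs = sampleIDs(data),
      loadings = lapply(ranks, `[[`, "loadings"),
      scores = lapply(ranks, `[[`, "scores"),
      lambdas = lapply(ranks, `[[`, "lambdas"),
      objectiveTrace = lapply(ranks, `[[`, "objectiveTrace"),
      converged = vapply(ranks, `[[`, logical(1), "converged"),
      degenerate = lapply(ranks, `[[`, "degenerate"),
      slack = lapply(ranks, `[[`, "slack"),
      options = options)
}
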