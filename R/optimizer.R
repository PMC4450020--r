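.chi_blocks <- function(data, slack = NULL) {
  chi <- blocks(data)
  ci <- classIndex(data)
  if (!is.null(slack) && !is.na(ci) && length(slack$m))
    chi[[ci]] <- augmentedClassBlock(chi[[ci]], slack$b, slack$m)
  chi
}

.score_matrix <- function(chi, loadings) {
  N <- nrow(chi[[1L]])
  V <- matrix(0, N, length(chi))
  for (j in seq_along(chi)) {
    if (length(loadings[[j]]) != ncol(chi[[j]]))
      stop(sprintf("loading %d has length %d, block has %d columns",
                   j, length(loadings[[j]]), ncol(chi[[j]])))
    V[, j] <- chi[[j]] %*% loadings[[j]]
  }
  V
}

#' Weighted multiblock covariance objective
#'
#' The quantity the fit maximizes: the weighted sum, over all ordered linked
#' block pairs, of squared covariances of the latent scores,
#' `sum_{j != k} D[j,k] (alpha_j' chi_j' chi_k alpha_k)^2`, where the class
#' block enters slack-augmented (`chi_5 = X5 + b*m`) when slack is supplied.
#' Under `sgccaMode` the weights D are replaced by the binary linkage C.
#'
#' @param data a prepared [MultiblockData-class].
#' @param graph a [BlockGraph-class].
#' @param loadings list of per-block loading vectors.
#' @param slack optional `list(b = , m = )` slack state.
#' @param sgccaMode use C instead of D.
#' @return scalar objective value.
#' @export
objectiveValue <- function(data, graph, loadings, slack = NULL,
                           sgccaMode = FALSE) {
  chi <- .chi_blocks(data, slack)
  V <- .score_matrix(chi, loadings)
  W <- if (sgccaMode) graph@C else graph@D
  covs <- crossprod(V)
  diag(covs) <- 0
  sum(W * covs^2)
}

#' Inner component of a block
#'
#' The working target of block j's loading update: the weighted sum of
#' neighbor latent scores, each scaled by its current covariance with block
#' j's own score, `upsilon_j = sum_{k != j} D[j,k] (v_j' v_k) v_k`.
#'
#' @inheritParams objectiveValue
#' @param j block index.
#' @return length-N numeric vector.
#' @export
innerComponent <- function(j, data, graph, loadings, slack = NULL,
                           sgccaMode = FALSE) {
  chi <- .chi_blocks(data, slack)
  V <- .score_matrix(chi, loadings)
  W <- if (sgccaMode) graph@C else graph@D
  w <- W[j, ]
  cv <- drop(crossprod(V, V[, j]))
  cv[j] <- 0
  drop(V %*% (w * cv))
}

#' Univariate soft-thresholding update
#'
#' The closed-form elastic-net loading update: elementwise
#' `sign(x)(|x| - lambda)_+` applied to the columnwise inner products
#' `x = X' upsilon`. The result is not normalized; see [normalizeLoading()].
#'
#' @param X centered N x P block.
#' @param upsilon length-N target vector.
#' @param lambda nonnegative shrinkage level.
#' @return numeric loading vector of length P.
#' @export
ustUpdate <- function(X, upsilon, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  x <- drop(crossprod(X, upsilon))
  sign(x) * pmax(abs(x) - lambda, 0)
}

#' Normalize a loading to the score-norm contract
#'
#' Rescales `alpha` so that `||chi alpha||^2 = N` (convention `"sqrtN"`) or
#' `||chi alpha|| = 1` (`"unit"`). Scale-invariant in the input and
#' sparsity-preserving. An all-zero loading cannot be normalized: it is
#' returned unchanged with attribute `degenerate = TRUE`.
#'
#' @param alpha loading vector.
#' @param chi the block matrix it belongs to.
#' @param convention `"sqrtN"` or `"unit"`.
#' @return rescaled loading; carries `attr(,"degenerate") = TRUE` when the
#'   input was identically zero.
#' @export
normalizeLoading <- function(alpha, chi, convention = c("sqrtN", "unit")) {
  convention <- match.arg(convention)
  nrm <- sqrt(sum(drop(chi %*% alpha)^2))
  if (nrm == 0) {
    attr(alpha, "degenerate") <- TRUE
    return(alpha)
  }
  target <- if (convention == "sqrtN") sqrt(nrow(chi)) else 1
  alpha * (target / nrm)
}

.auto_lambda_grid <- function(X, upsilon, length.out = 20L, cap = 0.95) {
  lmax <- max(abs(drop(crossprod(X, upsilon))))
  if (lmax == 0) return(0)
  c(0, cap * lmax * 10^seq(-3, 0, length.out = length.out - 1L))
}

#' Cross-validated shrinkage selection
#'
#' Chooses lambda for one block by K-fold cross-validation of the
#' soft-thresholded regression of the target `upsilon` on the block: for
#' each candidate, the loading is fit by [ustUpdate()] on the training
#' folds (inner products rescaled to the full-sample scale so thresholds
#' are comparable across folds), its scale refit by least squares, and the
#' held-out entries of `upsilon` predicted; the lambda minimizing mean
#' held-out squared error wins, ties broken toward the larger (sparser)
#' value. Fold assignment draws from the current RNG stream.
#'
#' @param X centered N x P block.
#' @param upsilon length-N target.
#' @param K number of folds (>= 2, <= N).
#' @param grid numeric candidate vector, or `"auto"` for 20 log-spaced
#'   values from 0 to 0.95 of `max |X' upsilon|`.
#' @return the selected lambda (scalar).
#' @export
selectLambdaCV <- function(X, upsilon, K = 5L, grid = "auto") {
  N <- nrow(X)
  if (K < 2L) stop("K must be >= 2")
  if (N < K) stop("need at least K samples")
  if (is.character(grid)) grid <- .auto_lambda_grid(X, upsilon)
  if (!length(grid)) stop("lambda grid is empty")
  if (length(grid) == 1L) return(grid)
  grid <- sort(grid)
  fold <- sample(rep_len(seq_len(K), N))
  mse <- matrix(NA_real_, K, length(grid))
  for (f in seq_len(K)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    utr <- upsilon[tr]; ute <- upsilon[!tr]
    s <- drop(crossprod(Xtr, utr)) * (N / sum(tr))
    for (g in seq_along(grid)) {
      a <- sign(s) * pmax(abs(s) - grid[g], 0)
      if (all(a == 0)) {
        mse[f, g] <- mean(ute^2)
      } else {
        vtr <- drop(Xtr %*% a)
        sc <- sum(vtr * utr) / sum(vtr^2)
        pred <- sc * drop(Xte %*% a)
        mse[f, g] <- mean((ute - pred)^2)
      }
    }
  }
  m <- colMeans(mse)
  best <- min(m)
  ok <- which(m <= best + 1e-9 * max(1, abs(best)))
  grid[max(ok)]
}

#' Deflate blocks against their fitted scores
#'
#' Residualizes each block against its own latent score,
#' `X_j <- X_j - v_j (v_j' v_j)^{-1} v_j' X_j`, so subsequent ranks capture
#' structure orthogonal to what is already explained. Blocks with all-zero
#' loadings, and blocks listed in `skip`, pass through unchanged. By default
#' the class block is skipped: projecting a one-column -1/+1 block onto the
#' orthocomplement of its own score would erase all class information from
#' later ranks.
#'
#' @param data a prepared [MultiblockData-class].
#' @param loadings list of per-block loading vectors (one rank).
#' @param skip integer indices of blocks to leave untouched; defaults to the
#'   class block.
#' @return a new [MultiblockData-class] with residualized blocks.
#' @export
deflateBlocks <- function(data, loadings, skip = classIndex(data)) {
  bl <- blocks(data)
  skip <- skip[!is.na(skip)]
  for (j in seq_along(bl)) {
    if (j %in% skip) next
    a <- loadings[[j]]
    if (all(a == 0)) next
    v <- drop(bl[[j]] %*% a)
    vv <- sum(v^2)
    # a score that is numerically zero relative to the block carries no
    # direction to project out (its normalized projector would be noise)
    if (vv <= (1e-12)^2 * sum(bl[[j]]^2) * sum(a^2)) next
    bl[[j]] <- bl[[j]] - tcrossprod(v / vv, drop(crossprod(bl[[j]], v)))
  }
  initialize(data, blocks = bl)
}
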