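#' AR(1) correlation matrix
#'
#' `Sigma[i, j] = rho^|i - j|`: the stationary first-order autoregressive
#' correlation structure, symmetric positive-definite for `|rho| < 1`.
#'
#' @param p dimension.
#' @param rho autocorrelation in (-1, 1).
#' @return p x p matrix.
#' @export
ar1Covariance <- function(p, rho) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  idx <- seq_len(p)
  rho^abs(outer(idx, idx, "-"))
}

#' Column generators for the synthetic multiblock scheme
#'
#' Four generation functions of increasing complexity, drawn from the
#' current RNG stream:
#' \describe{
#'   \item{type1}{`x = mu + eps`, `eps ~ N(0, 1)` per entry.}
#'   \item{type2}{`x = mu + 1_delta + eps`: a per-entry Bernoulli(delta)
#'     indicator (`1` when an independent uniform draw is `<= delta`) added
#'     to standard normal noise.}
#'   \item{type3}{rows jointly multivariate normal with mean `mu` and AR(1)
#'     covariance `rho^|i-j|` across the `p` columns (multicollinear).}
#'   \item{type4}{`x ~ N(mu, sigma)`, i.e. variance `sigma` per entry.}
#' }
#'
#' @param type one of `"type1"`, `"type2"`, `"type3"`, `"type4"`.
#' @param n number of rows.
#' @param p number of columns (type3 draws them jointly).
#' @param mu mean.
#' @param delta indicator probability in \[0, 1\] (type2).
#' @param rho AR(1) autocorrelation in (-1, 1) (type3).
#' @param sigma variance > 0 (type4).
#' @return an n x p numeric matrix.
#' @export
generateColumns <- function(type = c("type1", "type2", "type3", "type4"),
                            n, p = 1L, mu = 0, delta = NULL, rho = NULL,
                            sigma = NULL) {
  type <- match.arg(type)
  switch(type,
    type1 = matrix(stats::rnorm(n * p, mean = mu), n, p),
    type2 = {
      if (is.null(delta) || delta < 0 || delta > 1)
        stop("type2 needs delta in [0, 1]")
      mu + matrix(as.numeric(stats::runif(n * p) <= delta), n, p) +
        matrix(stats::rnorm(n * p), n, p)
    },
    type3 = {
      if (is.null(rho)) stop("type3 needs rho")
      R <- chol(ar1Covariance(p, rho))
      mu + matrix(stats::rnorm(n * p), n, p) %*% R
    },
    type4 = {
      if (is.null(sigma) || sigma <= 0) stop("type4 needs sigma > 0")
      matrix(stats::rnorm(n * p, mean = mu, sd = sqrt(sigma)), n, p)
    })
}

# Column layout of the three upstream blocks: per block, a list of segments
# (type, count, parameters). Block sizes 100 / 200 / 300.
.design_layout <- function() {
  list(
    SNP = list(
      list(type = "type1", p = 5L, mu = 2.4),
      list(type = "type1", p = 5L, mu = -2.6),
      list(type = "type2", p = 30L, mu = 1, delta = 0.6),
      list(type = "type3", p = 60L, mu = 0, rho = 0.8)),
    CNV = list(
      list(type = "type1", p = 5L, mu = 3),
      list(type = "type1", p = 5L, mu = 4),
      list(type = "type3", p = 50L, mu = 0, rho = 0.9),
      list(type = "type4", p = 140L, mu = 2, sigma = 2)),
    DM = list(
      list(type = "type1", p = 5L, mu = 5),
      list(type = "type1", p = 5L, mu = -3),
      list(type = "type4", p = 200L, mu = 0, sigma = 1),
      list(type = "type3", p = 90L, mu = 0, rho = 0.9))
  )
}

#' Generate the three upstream design blocks
#'
#' Builds the SNP (n x 100), CNV (n x 200) and DM (n x 300) blocks by
#' compounding the four column generators segment by segment: each block
#' starts with two five-column mean-shifted normal segments (the
#' signal-bearing features), followed by threshold-indicator, AR(1)
#' multicollinear and scaled-normal noise segments. Draws from the current
#' RNG stream.
#'
#' @param n number of samples.
#' @return named list of three matrices (`SNP`, `CNV`, `DM`).
#' @export
buildDesignBlocks <- function(n) {
  if (n < 2) stop("need at least two samples")
  lay <- .design_layout()
  out <- vector("list", length(lay))
  names(out) <- names(lay)
  for (bn in names(lay)) {
    segs <- lapply(lay[[bn]], function(s)
      generateColumns(s$type, n = n, p = s$p, mu = s$mu,
                      delta = s$delta, rho = s$rho, sigma = s$sigma))
    X <- do.call(cbind, segs)
    dimnames(X) <- list(paste0("S", seq_len(n)),
                        paste0(bn, "_", seq_len(ncol(X))))
    out[[bn]] <- X
  }
  out
}

#' Generate the gene-expression response block
#'
#' `X4 = X1 B1 + X2 B2 + X3 B3 + Xi` with standard-normal noise `Xi`. Each
#' coefficient matrix `Bj` is nonzero only in its leading `nSignal` x
#' `nSignal` corner: only the first `nSignal` features of each upstream
#' block drive the response, and only the first `nSignal` response features
#' receive that signal (the remaining response columns are pure noise), so
#' every block has exactly `nSignal` truly significant variables. Nonzero
#' entries are drawn uniformly from `coefRange` with random sign.
#'
#' @param design named list of the three upstream blocks.
#' @param p4 number of response features.
#' @param nSignal number of signal-bearing rows per coefficient matrix.
#' @param coefRange length-2 range of absolute coefficient values.
#' @return `list(X4 = matrix, B = list of coefficient matrices)`.
#' @export
buildResponseBlock <- function(design, p4 = 50L, nSignal = 10L,
                               coefRange = c(0.5, 1.5)) {
  n <- nrow(design[[1L]])
  B <- lapply(design, function(X) {
    Bj <- matrix(0, ncol(X), p4)
    nz <- nSignal * nSignal
    Bj[seq_len(nSignal), seq_len(nSignal)] <-
      stats::runif(nz, coefRange[1L], coefRange[2L]) *
      sample(c(-1, 1), nz, replace = TRUE)
    Bj
  })
  X4 <- matrix(stats::rnorm(n * p4), n, p4)
  for (j in seq_along(design)) X4 <- X4 + design[[j]] %*% B[[j]]
  dimnames(X4) <- list(rownames(design[[1L]]), paste0("GE_", seq_len(p4)))
  list(X4 = X4, B = B)
}

#' Generate Bernoulli class labels from the response block
#'
#' Disease probability by the logistic model `pi = exp(eta) / (1 +
#' exp(eta))` with linear predictor `eta = (X4 - colmeans) B4`; `B4` is zero
#' except its first `nSignal` entries, drawn uniformly from `coefRange` with
#' random sign. Labels are Bernoulli(pi), coded -1/+1. Column means are
#' removed from the predictor (an implicit intercept): the upstream
#' generators have large nonzero means whose weighted sum would otherwise
#' saturate pi at the same value for every sample. A draw yielding a single
#' class is redrawn from subsequent RNG values (recorded in the result).
#'
#' @param X4 response block.
#' @param nSignal size of the class-relevant support.
#' @param coefRange length-2 range of absolute coefficient values.
#' @param maxRedraw redraw attempts before giving up.
#' @return `list(labels = -1/+1 vector, B4 = vector, pi = vector,
#'   redraws = integer)`.
#' @export
buildClassBlock <- function(X4, nSignal = 10L, coefRange = c(0.5, 1.5),
                            maxRedraw = 25L) {
  p4 <- ncol(X4)
  B4 <- numeric(p4)
  B4[seq_len(nSignal)] <- stats::runif(nSignal, coefRange[1L], coefRange[2L]) *
    sample(c(-1, 1), nSignal, replace = TRUE)
  eta <- drop(sweep(X4, 2L, colMeans(X4), "-") %*% B4)
  pi <- stats::plogis(eta)
  redraws <- 0L
  repeat {
    y <- ifelse(stats::rbinom(length(pi), 1L, pi) == 1L, 1, -1)
    if (length(unique(y)) == 2L) break
    redraws <- redraws + 1L
    if (redraws > maxRedraw)
      stop("class labels degenerate to a single class; check coefficients")
  }
  names(y) <- rownames(X4)
  list(labels = y, B4 = B4, pi = pi, redraws = redraws)
}

#' Simulate a complete five-block dataset with ground truth
#'
#' End-to-end generator: upstream blocks from [buildDesignBlocks()], the
#' gene-expression response from [buildResponseBlock()], class labels from
#' [buildClassBlock()], assembled into an unprepared
#' [MultiblockData-class] (raw, uncentered blocks plus the -1/+1 class
#' block) and a [SimTruth-class] marking the first `nSignal` features of
#' each upstream block and the class-coefficient support in the response
#' block as truly significant. Fully reproducible from `seed`.
#'
#' @param n number of samples.
#' @param p4 response-block width.
#' @param nSignal signal features per block.
#' @param coefRange absolute-value range of the response coefficients.
#' @param coef4Range absolute-value range of the class coefficients.
#' @param seed integer seed.
#' @return `list(data = MultiblockData, truth = SimTruth)`.
#' @examples
#' sim <- simulateMultiblock(n = 100, seed = 1)
#' sim$data
#' vapply(truthMasks(sim$truth), sum, numeric(1))  # 10 per block
#' @export
simulateMultiblock <- function(n = 500L, p4 = 50L, nSignal = 10L,
                               coefRange = c(0.5, 1.5),
                               coef4Range = coefRange, seed = 1L) {
  set.seed(seed)
  design <- buildDesignBlocks(n)
  resp <- buildResponseBlock(design, p4 = p4, nSignal = nSignal,
                             coefRange = coefRange)
  cls <- buildClassBlock(resp$X4, nSignal = nSignal, coefRange = coef4Range)
  bl <- c(design, list(GE = resp$X4),
          list(CLASS = matrix(cls$labels, ncol = 1L,
                              dimnames = list(rownames(resp$X4), "class"))))
  data <- new("MultiblockData", blocks = unname(bl),
              blockNames = names(bl), classIndex = 5L, prepared = FALSE,
              labelMap = c(control = "-1", case = "+1"))
  masks <- c(
    lapply(design, function(X) {
      mk <- seq_len(ncol(X)) <= nSignal
      names(mk) <- colnames(X)
      mk
    }),
    list(GE = stats::setNames(cls$B4 != 0, colnames(resp$X4))))
  truth <- new("SimTruth", masks = masks,
               coefficients = list(B = resp$B, B4 = cls$B4),
               config = list(n = n, p4 = p4, nSignal = nSignal,
                             coefRange = coefRange, coef4Range = coef4Range,
                             redraws = cls$redraws),
               seed = as.integer(seed))
  list(data = data, truth = truth)
}
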