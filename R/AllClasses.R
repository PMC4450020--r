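#' @import methods
NULL

#' Multiblock data container
#'
#' Holds J feature matrices (blocks) measured on one common set of N samples,
#' e.g. SNP, copy-number, DNA-methylation and gene-expression blocks plus an
#' optional single-column class block coded -1/+1. Blocks carry their sample
#' IDs as rownames and feature names as colnames. Create with
#' [prepareBlocks()], which centers the feature blocks and appends the class
#' block; objects straight from [simulateMultiblock()] are unprepared.
#'
#' @slot blocks list of J numeric matrices sharing row count and row order.
#' @slot blockNames character vector of J block labels.
#' @slot classIndex integer; index of the class block, or `NA` if none.
#' @slot prepared logical; `TRUE` once feature blocks are column-centered.
#' @slot labelMap named character vector recording the original label ->
#'   (-1/+1) encoding, empty when no class block is present.
#'
#' @seealso [prepareBlocks()], [multidaFit()]
#' @export
setClass("MultiblockData",
  slots = c(
    blocks = "list",
    blockNames = "character",
    classIndex = "integer",
    prepared = "logical",
    labelMap = "character"
  ),
  prototype = list(
    blocks = list(), blockNames = character(), classIndex = NA_integer_,
    prepared = FALSE, labelMap = character()
  )
)

setValidity("MultiblockData", function(object) {
  msgs <- character()
  J <- length(object@blocks)
  if (length(object@blockNames) != J)
    msgs <- c(msgs, "blockNames must have one entry per block")
  if (J > 0L) {
    if (!all(vapply(object@blocks, function(b) is.matrix(b) && is.numeric(b),
                    logical(1))))
      msgs <- c(msgs, "all blocks must be numeric matrices")
    ns <- vapply(object@blocks, nrow, integer(1))
    if (length(unique(ns)) > 1L)
      msgs <- c(msgs, sprintf("blocks disagree on sample count: %s",
                              paste(ns, collapse = ", ")))
    rn <- lapply(object@blocks, rownames)
    if (any(vapply(rn, is.null, logical(1))))
      msgs <- c(msgs, "every block must carry sample IDs as rownames")
    else if (length(unique(rn)) > 1L)
      msgs <- c(msgs, "blocks disagree on sample ordering")
  }
  ci <- object@classIndex
  if (!is.na(ci)) {
    if (ci < 1L || ci > J)
      msgs <- c(msgs, "classIndex out of range")
    else {
      cb <- object@blocks[[ci]]
      if (ncol(cb) != 1L)
        msgs <- c(msgs, "class block must have exactly one column")
      else if (!all(cb %in% c(-1, 1)))
        msgs <- c(msgs, "class block values must be -1 or +1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Block linkage and correlation-weight graph
#'
#' The design matrix `C` declares which block pairs contribute squared
#' covariance terms to the objective (binary, symmetric, zero diagonal); the
#' weight matrix `D` generalizes it with nonnegative real weights that
#' rebalance pair contributions. `D[j,k] > 0` is only allowed where
#' `C[j,k] == 1`.
#'
#' @slot C binary symmetric J x J matrix with zero diagonal.
#' @slot D nonnegative symmetric J x J matrix with zero diagonal.
#' @slot blockNames character vector of J block labels.
#'
#' @seealso [blockGraph()], [defaultGenomicGraph()]
#' @export
setClass("BlockGraph",
  slots = c(C = "matrix", D = "matrix", blockNames = "character")
)

setValidity("BlockGraph", function(object) {
  msgs <- character()
  C <- object@C; D <- object@D
  J <- nrow(C)
  if (ncol(C) != J || nrow(D) != J || ncol(D) != J)
    msgs <- c(msgs, "C and D must be square matrices of equal size")
  if (length(object@blockNames) != J)
    msgs <- c(msgs, "blockNames must match matrix dimension")
  if (!all(C %in% c(0, 1))) msgs <- c(msgs, "C entries must be 0 or 1")
  if (!isTRUE(all.equal(C, t(C)))) msgs <- c(msgs, "C must be symmetric")
  if (any(diag(C) != 0)) msgs <- c(msgs, "C must have zero diagonal")
  if (any(D < 0)) msgs <- c(msgs, "D entries must be nonnegative")
  if (!isTRUE(all.equal(D, t(D)))) msgs <- c(msgs, "D must be symmetric")
  if (any(diag(D) != 0)) msgs <- c(msgs, "D must have zero diagonal")
  if (any(D > 0 & C != 1))
    msgs <- c(msgs, "D may be positive only where C == 1")
  if (length(msgs)) msgs else TRUE
})

#' Fitting options
#'
#' Tunable parameters of the multiblock fit. `lambdaGrid = "auto"` builds,
#' per block, 20 log-spaced candidates from 0 up to 0.95 of the largest
#' absolute feature/target inner product, so shrinkage can never eliminate a
#' block's strongest feature. `normalization` chooses between the
#' `||chi alpha||^2 = N` score contract (`"sqrtN"`, the default) and the unit
#' variant `||chi alpha|| = 1` (`"unit"`); the two differ by the constant
#' sqrt(N) and rank features identically. `sgccaMode = TRUE` replaces the
#' weight matrix D by the binary C and disables the slack variables, giving
#' the plain sparse generalized canonical correlation objective.
#'
#' @slot nRanks integer, number of components (ranks) to extract.
#' @slot maxIter integer, maximum Wold sweeps per rank.
#' @slot tol positive real, relative objective-change convergence threshold.
#' @slot cvFolds integer K >= 2 for the lambda cross-validation.
#' @slot lambdaGrid `"auto"` or a numeric vector of nonnegative candidates.
#' @slot seed integer seed; the fit is bit-reproducible given the seed.
#' @slot discriminant logical, enable the class-margin slack machinery.
#' @slot sgccaMode logical, see above.
#' @slot normalization `"sqrtN"` or `"unit"`.
#' @slot cvEverySweep logical, reselect lambda at every sweep (off by
#'   default so the within-rank objective stays monotone).
#' @slot warmMaxIter integer, cap on dense (lambda = 0) warm-start sweeps.
#'
#' @seealso [fitOptions()]
#' @export
setClass("FitOptions",
  slots = c(
    nRanks = "integer", maxIter = "integer", tol = "numeric",
    cvFolds = "integer", lambdaGrid = "ANY", seed = "integer",
    discriminant = "logical", sgccaMode = "logical",
    normalization = "character", cvEverySweep = "logical",
    warmMaxIter = "integer"
  ),
  prototype = list(
    nRanks = 3L, maxIter = 100L, tol = 1e-6, cvFolds = 5L,
    lambdaGrid = "auto", seed = 1L, discriminant = TRUE, sgccaMode = FALSE,
    normalization = "sqrtN", cvEverySweep = FALSE, warmMaxIter = 25L
  )
)

setValidity("FitOptions", function(object) {
  msgs <- character()
  if (object@nRanks < 1L) msgs <- c(msgs, "nRanks must be >= 1")
  if (object@maxIter < 1L) msgs <- c(msgs, "maxIter must be >= 1")
  if (!(object@tol > 0)) msgs <- c(msgs, "tol must be > 0")
  if (object@cvFolds < 2L) msgs <- c(msgs, "cvFolds must be >= 2")
  lg <- object@lambdaGrid
  if (is.character(lg)) {
    if (!identical(lg, "auto")) msgs <- c(msgs, "lambdaGrid must be \"auto\" or numeric")
  } else if (is.numeric(lg)) {
    if (length(lg) == 0L) msgs <- c(msgs, "lambdaGrid must be non-empty")
    if (any(lg < 0)) msgs <- c(msgs, "every lambda must be >= 0")
  } else msgs <- c(msgs, "lambdaGrid must be \"auto\" or numeric")
  if (!object@normalization %in% c("sqrtN", "unit"))
    msgs <- c(msgs, "normalization must be \"sqrtN\" or \"unit\"")
  if (length(msgs)) msgs else TRUE
})

#' Fitted sparse loadings across ranks
#'
#' Result of [multidaFit()]: per rank r and block j, the sparse loading
#' vector alpha and its latent score v = chi alpha, the cross-validated
#' shrinkage level lambda, the objective trace over Wold sweeps, convergence
#' flags, and (when the discriminant is enabled) the class direction b and
#' final slack vector m of each rank.
#'
#' Nonzero loadings satisfy the normalization contract `||chi alpha||^2 = N`
#' (or `= 1` under the `"unit"` convention); an all-zero loading is stored
#' as-is and flagged degenerate.
#'
#' @slot blockNames,featureNames,sampleIDs metadata copied from the data.
#' @slot loadings list over ranks; each element a list over blocks of
#'   numeric loading vectors.
#' @slot scores list over ranks; each a list over blocks of length-N scores.
#' @slot lambdas list over ranks of per-block numeric lambda values.
#' @slot objectiveTrace list over ranks of per-sweep objective values.
#' @slot converged logical per rank.
#' @slot degenerate list over ranks of per-block logical flags.
#' @slot slack list over ranks of `list(b = , m = )` (empty when the
#'   discriminant is off).
#' @slot options the [FitOptions-class] used.
#'
#' @seealso [multidaFit()], [selectFeatures()]
#' @export
setClass("LoadingSet",
  slots = c(
    blockNames = "character", featureNames = "list", sampleIDs = "character",
    loadings = "list", scores = "list", lambdas = "list",
    objectiveTrace = "list", converged = "logical", degenerate = "list",
    slack = "list", options = "FitOptions"
  )
)

setValidity("LoadingSet", function(object) {
  nr <- length(object@loadings)
  if (length(object@scores) != nr || length(object@lambdas) != nr ||
      length(object@objectiveTrace) != nr || length(object@converged) != nr)
    return("per-rank slots must have equal length")
  TRUE
})

#' Ground truth of a simulated multiblock dataset
#'
#' Records which features truly carry signal in a dataset from
#' [simulateMultiblock()]: binary masks per block (the first ten features of
#' blocks 1-3 and the support of the class coefficient vector in block 4),
#' plus the coefficient matrices B1..B3, the class coefficient vector B4,
#' the seed and the generator configuration.
#'
#' @slot masks list of logical vectors, one per feature block.
#' @slot coefficients list with elements `B` (list of the three coefficient
#'   matrices) and `B4` (numeric vector).
#' @slot config list echo of the generator configuration.
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("SimTruth",
  slots = c(masks = "list", coefficients = "list", config = "list",
            seed = "integer")
)

#' Feature-selection score against ground truth
#'
#' Confusion counts and derived metrics of a selected-feature set against a
#' [SimTruth-class] record, pooled over the evaluated blocks. TPR =
#' TP/(TP+FN), PPV = TP/(TP+FP), ACCU = (TP+TN)/total; a 0/0 ratio is
#' defined as 0 and recorded in `flags`.
#'
#' @slot selected list of logical selection masks per evaluated block.
#' @slot confusion named numeric: TP, FP, TN, FN.
#' @slot metrics named numeric: TPR, PPV, ACCU.
#' @slot flags character vector of degenerate-ratio annotations.
#' @slot blocksEvaluated character names of the pooled blocks.
#' @export
setClass("SelectionResult",
  slots = c(selected = "list", confusion = "numeric", metrics = "numeric",
            flags = "character", blocksEvaluated = "character")
)

setValidity("SelectionResult", function(object) {
  cf <- object@confusion
  if (!all(c("TP", "FP", "TN", "FN") %in% names(cf)))
    return("confusion must contain TP, FP, TN, FN")
  tot <- sum(vapply(object@selected, length, integer(1)))
  if (tot > 0 && !isTRUE(all.equal(sum(cf[c("TP", "FP", "TN", "FN")]), tot)))
    return("confusion cells must sum to the number of evaluated features")
  TRUE
})
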