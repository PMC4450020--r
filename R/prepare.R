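#' Assemble and center a multiblock dataset
#'
#' Validates that the raw blocks share one sample set, column-centers every
#' feature block (optionally scales to unit variance), encodes the binary
#' labels as a -1/+1 single-column class block appended after the feature
#' blocks, and returns a [MultiblockData-class] ready for [multidaFit()].
#'
#' Constant columns are centered to all-zero but retained (with a warning),
#' so feature indices stay aligned with any ground-truth masks. The label
#' encoding maps the first level of `factor(labels)` to -1 and the second to
#' +1; numeric labels already in \{-1, +1\} are kept as-is. Preparing an
#' already prepared object is a no-op.
#'
#' @param rawBlocks list of numeric sample-by-feature matrices, or a
#'   [MultiblockData-class] (prepared or not).
#' @param labels binary label vector of length N (any two values), or `NULL`
#'   to build a dataset without a class block.
#' @param blockNames optional block labels; defaults to `B1..BJ` (plus
#'   `CLASS`) or the names carried by the input.
#' @param scale if `TRUE`, also scale feature columns to unit standard
#'   deviation (constant columns are left at zero).
#' @return a prepared [MultiblockData-class]; the label encoding is recorded
#'   in its `labelMap` slot.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' d <- prepareBlocks(list(x), labels = rep(c("case", "control"), 5))
#' colMeans(blocks(d)[[1]])  # ~ 0
#' @export
prepareBlocks <- function(rawBlocks, labels = NULL, blockNames = NULL,
                          scale = FALSE) {
  labelMap <- character()
  if (is(rawBlocks, "MultiblockData")) {
    obj <- rawBlocks
    if (obj@prepared && is.null(labels)) return(obj)
    ci <- obj@classIndex
    if (!is.na(ci) && is.null(labels)) {
      labels <- drop(obj@blocks[[ci]])
      labelMap <- obj@labelMap
      rawBlocks <- obj@blocks[-ci]
      if (is.null(blockNames)) blockNames <- obj@blockNames[-ci]
    } else {
      rawBlocks <- obj@blocks
      if (is.null(blockNames)) blockNames <- obj@blockNames
    }
  }
  if (!is.list(rawBlocks) || !length(rawBlocks))
    stop("rawBlocks must be a non-empty list of matrices")
  rawBlocks <- lapply(rawBlocks, as.matrix)
  ns <- vapply(rawBlocks, nrow, integer(1))
  if (length(unique(ns)) > 1L)
    stop(sprintf("blocks disagree on sample count (%s)",
                 paste(ns, collapse = ", ")))
  N <- ns[1L]
  rn <- lapply(rawBlocks, rownames)
  hasrn <- !vapply(rn, is.null, logical(1))
  if (any(hasrn)) {
    ref <- rn[hasrn][[1L]]
    if (!all(vapply(rn[hasrn], identical, logical(1), ref)))
      stop("blocks disagree on sample ordering (rownames differ)")
    sids <- ref
  } else sids <- paste0("S", seq_len(N))

  J <- length(rawBlocks)
  if (is.null(blockNames)) blockNames <- paste0("B", seq_len(J))

  prep <- vector("list", J)
  for (j in seq_len(J)) {
    X <- rawBlocks[[j]]
    storage.mode(X) <- "double"
    mu <- colMeans(X)
    X <- sweep(X, 2L, mu, "-")
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0))
      warning(sprintf("block %s: %d constant column(s) centered to zero",
                      blockNames[j], sum(sds == 0)))
    if (scale) {
      sds[sds == 0] <- 1
      X <- sweep(X, 2L, sds, "/")
    }
    rownames(X) <- sids
    if (is.null(colnames(X)))
      colnames(X) <- paste0(blockNames[j], "_", seq_len(ncol(X)))
    prep[[j]] <- X
  }

  classIndex <- NA_integer_
  if (!is.null(labels)) {
    if (length(labels) != N)
      stop(sprintf("labels length (%d) does not match sample count (%d)",
                   length(labels), N))
    if (anyNA(labels)) stop("labels must not contain missing values")
    uv <- sort(unique(labels))
    if (length(uv) != 2L)
      stop(sprintf("labels must contain exactly two classes (found %d)",
                   length(uv)))
    if (is.numeric(labels) && setequal(uv, c(-1, 1))) {
      y <- as.numeric(labels)
      labelMap <- c("-1" = "-1", "1" = "+1")
    } else {
      f <- factor(labels)
      y <- ifelse(as.integer(f) == 1L, -1, 1)
      labelMap <- stats::setNames(c("-1", "+1"), levels(f))
    }
    cb <- matrix(y, ncol = 1L, dimnames = list(sids, "class"))
    prep <- c(prep, list(cb))
    if (length(blockNames) == J) blockNames <- c(blockNames, "CLASS")
    classIndex <- J + 1L
  }

  new("MultiblockData", blocks = prep, blockNames = blockNames,
      classIndex = classIndex, prepared = TRUE, labelMap = labelMap)
}
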