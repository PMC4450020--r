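#' @describeIn MultiblockData the list of block matrices.
#' @param x object.
#' @aliases blocks,MultiblockData-method
#' @export
setMethod("blocks", "MultiblockData", function(x) x@blocks)

#' @describeIn MultiblockData block labels.
#' @export
setMethod("blockNames", "MultiblockData", function(x) x@blockNames)

#' @describeIn MultiblockData number of blocks J.
#' @export
setMethod("nBlocks", "MultiblockData", function(x) length(x@blocks))

#' @describeIn MultiblockData sample identifiers (common row order).
#' @export
setMethod("sampleIDs", "MultiblockData", function(x) {
  if (length(x@blocks)) rownames(x@blocks[[1L]]) else character()
})

#' @describeIn MultiblockData per-block feature names.
#' @export
setMethod("featureNames", "MultiblockData",
          function(x) lapply(x@blocks, colnames))

#' @describeIn MultiblockData index of the class block (`NA` if absent).
#' @export
setMethod("classIndex", "MultiblockData", function(x) x@classIndex)

#' @describeIn MultiblockData whether feature blocks have been centered.
#' @export
setMethod("isPrepared", "MultiblockData", function(x) x@prepared)

setMethod("show", "MultiblockData", function(object) {
  J <- length(object@blocks)
  cat(sprintf("MultiblockData: %d block%s, %d sample%s%s\n",
              J, if (J == 1) "" else "s",
              if (J) nrow(object@blocks[[1L]]) else 0L,
              if (J && nrow(object@blocks[[1L]]) == 1) "" else "s",
              if (object@prepared) " (prepared)" else ""))
  for (j in seq_len(J)) {
    tag <- if (!is.na(object@classIndex) && j == object@classIndex)
      " [class]" else ""
    cat(sprintf("  %s: %d feature%s%s\n", object@blockNames[j],
                ncol(object@blocks[[j]]),
                if (ncol(object@blocks[[j]]) == 1) "" else "s", tag))
  }
})

#' @describeIn BlockGraph binary linkage matrix C.
#' @param x object.
#' @export
setMethod("designMatrix", "BlockGraph", function(x) x@C)

#' @describeIn BlockGraph correlation weight matrix D.
#' @export
setMethod("weightMatrix", "BlockGraph", function(x) x@D)

#' @describeIn BlockGraph block labels.
#' @export
setMethod("blockNames", "BlockGraph", function(x) x@blockNames)

#' @describeIn BlockGraph number of blocks.
#' @export
setMethod("nBlocks", "BlockGraph", function(x) nrow(x@C))

setMethod("show", "BlockGraph", function(object) {
  cat(sprintf("BlockGraph over %d blocks: %s\n", nrow(object@C),
              paste(object@blockNames, collapse = ", ")))
  up <- which(upper.tri(object@C) & object@C == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(up))) {
    j <- up[r, 1L]; k <- up[r, 2L]
    cat(sprintf("  %s -- %s (weight %g)\n", object@blockNames[j],
                object@blockNames[k], object@D[j, k]))
  }
})

#' @describeIn LoadingSet loadings; all ranks, one rank (list over blocks),
#'   or one vector when both `rank` and `block` are given.
#' @param x object.
#' @param rank,block optional rank index and block index or name.
#' @export
setMethod("blockLoadings", "LoadingSet", function(x, rank = NULL, block = NULL) {
  .pick_rank_block(x@loadings, x@blockNames, rank, block)
})

#' @describeIn LoadingSet latent scores, same indexing as `blockLoadings`.
#' @export
setMethod("blockScores", "LoadingSet", function(x, rank = NULL, block = NULL) {
  .pick_rank_block(x@scores, x@blockNames, rank, block)
})

#' @describeIn LoadingSet cross-validated lambda per rank and block.
#' @export
setMethod("blockLambdas", "LoadingSet", function(x, rank = NULL) {
  if (is.null(rank)) x@lambdas else x@lambdas[[rank]]
})

#' @describeIn LoadingSet per-sweep objective values of each rank.
#' @export
setMethod("objectiveTrace", "LoadingSet", function(x, rank = NULL) {
  if (is.null(rank)) x@objectiveTrace else x@objectiveTrace[[rank]]
})

#' @describeIn LoadingSet class direction and slack vectors per rank.
#' @export
setMethod("slackVariables", "LoadingSet", function(x, rank = NULL) {
  if (is.null(rank)) x@slack else x@slack[[rank]]
})

#' @describeIn LoadingSet number of extracted ranks.
#' @export
setMethod("nRanks", "LoadingSet", function(x) length(x@loadings))

#' @describeIn LoadingSet per-rank convergence flags.
#' @export
setMethod("isConverged", "LoadingSet", function(x) x@converged)

#' @describeIn LoadingSet block labels.
#' @export
setMethod("blockNames", "LoadingSet", function(x) x@blockNames)

#' @describeIn LoadingSet sample identifiers of the fitted data.
#' @export
setMethod("sampleIDs", "LoadingSet", function(x) x@sampleIDs)

#' @describeIn LoadingSet per-block feature names.
#' @export
setMethod("featureNames", "LoadingSet", function(x) x@featureNames)

.pick_rank_block <- function(store, bn, rank, block) {
  if (is.null(rank)) return(store)
  res <- store[[rank]]
  if (is.null(block)) return(res)
  if (is.character(block)) block <- match(block, bn)
  res[[block]]
}

setMethod("show", "LoadingSet", function(object) {
  nr <- length(object@loadings)
  cat(sprintf("LoadingSet: %d rank%s over %d blocks (%s)\n", nr,
              if (nr == 1) "" else "s", length(object@blockNames),
              paste(object@blockNames, collapse = ", ")))
  for (r in seq_len(nr)) {
    nz <- vapply(object@loadings[[r]], function(a) sum(a != 0), integer(1))
    cat(sprintf("  rank %d: nonzero loadings %s; %d sweeps; %s\n", r,
                paste(nz, collapse = "/"),
                length(object@objectiveTrace[[r]]),
                if (object@converged[r]) "converged" else "not converged"))
  }
})

#' @describeIn SimTruth per-block logical truth masks.
#' @param x object.
#' @export
setMethod("truthMasks", "SimTruth", function(x) x@masks)

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %s true features per block (seed %d)\n",
              paste(vapply(object@masks, sum, numeric(1)), collapse = "/"),
              object@seed))
})

#' @describeIn SelectionResult named TPR/PPV/ACCU vector.
#' @param x object.
#' @export
setMethod("selectionMetrics", "SelectionResult", function(x) x@metrics)

#' @describeIn SelectionResult named TP/FP/TN/FN counts.
#' @export
setMethod("selectionConfusion", "SelectionResult", function(x) x@confusion)

setMethod("show", "SelectionResult", function(object) {
  cf <- object@confusion; m <- object@metrics
  cat(sprintf(
    "SelectionResult over %s\n  TP=%d FP=%d TN=%d FN=%d\n  TPR=%.3f PPV=%.3f ACCU=%.3f%s\n",
    paste(object@blocksEvaluated, collapse = ", "),
    cf["TP"], cf["FP"], cf["TN"], cf["FN"],
    m["TPR"], m["PPV"], m["ACCU"],
    if (length(object@flags)) paste0("  [", paste(object@flags, collapse = "; "), "]")
    else ""))
})
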