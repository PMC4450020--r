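#' Selected-feature masks from a fitted model
#'
#' A feature counts as selected when the absolute value of its loading
#' exceeds `threshold` in any extracted rank (union over ranks). The default
#' threshold 0 keeps exactly the features the soft-thresholding left
#' nonzero.
#'
#' @param fit a [LoadingSet-class].
#' @param threshold nonnegative cutoff; selection is strict (`>`).
#' @return named list of logical vectors, one per block.
#' @export
selectFeatures <- function(fit, threshold = 0) {
  stopifnot(is(fit, "LoadingSet"))
  J <- length(fit@blockNames)
  out <- vector("list", J)
  names(out) <- fit@blockNames
  for (j in seq_len(J)) {
    p <- length(fit@featureNames[[j]])
    sel <- logical(p)
    for (r in seq_along(fit@loadings))
      sel <- sel | (abs(fit@loadings[[r]][[j]]) > threshold)
    names(sel) <- fit@featureNames[[j]]
    out[[j]] <- sel
  }
  out
}

#' Score a feature selection against ground truth
#'
#' Pools the confusion counts (TP, FP, TN, FN) of the selection masks over
#' the evaluated blocks and derives TPR = TP/(TP+FN), PPV = TP/(TP+FP) and
#' ACCU = (TP+TN)/total. A 0/0 ratio is defined as 0 and noted in the
#' result's `flags`. By default every block present in the truth record is
#' evaluated (for the simulated scheme: the four feature blocks, 650
#' features of which 40 are true); restrict with `blocksEvaluated` to score
#' the upstream blocks only.
#'
#' @param selected list of logical masks (e.g. from [selectFeatures()]),
#'   named by block.
#' @param truth a [SimTruth-class] or a list of logical truth masks named
#'   compatibly.
#' @param blocksEvaluated character or integer subset of truth blocks to
#'   pool; default all.
#' @return a [SelectionResult-class].
#' @export
scoreSelection <- function(selected, truth, blocksEvaluated = NULL) {
  masks <- if (is(truth, "SimTruth")) truthMasks(truth) else truth
  if (is.null(blocksEvaluated)) blocksEvaluated <- names(masks)
  if (is.numeric(blocksEvaluated)) blocksEvaluated <- names(masks)[blocksEvaluated]
  tp <- fp <- tn <- fn <- 0L
  kept <- list()
  for (bn in blocksEvaluated) {
    tr <- as.logical(masks[[bn]])
    sl <- selected[[bn]]
    if (is.null(sl)) stop(sprintf("no selection mask for block '%s'", bn))
    sl <- as.logical(sl)
    if (length(sl) != length(tr))
      stop(sprintf("block '%s': selection length %d vs truth length %d",
                   bn, length(sl), length(tr)))
    tp <- tp + sum(sl & tr); fp <- fp + sum(sl & !tr)
    fn <- fn + sum(!sl & tr); tn <- tn + sum(!sl & !tr)
    kept[[bn]] <- sl
  }
  flags <- character()
  rat <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, sprintf("%s undefined (0/0), reported as 0", what))
      return(0)
    }
    num / den
  }
  metrics <- c(TPR = rat(tp, tp + fn, "TPR"),
               PPV = rat(tp, tp + fp, "PPV"),
               ACCU = rat(tp + tn, tp + fp + tn + fn, "ACCU"))
  new("SelectionResult", selected = kept,
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      metrics = metrics, flags = flags,
      blocksEvaluated = as.character(blocksEvaluated))
}

.method_options <- function(method, base, seed) {
  opts <- base
  opts@seed <- as.integer(seed)
  if (method %in% c("sgcca", "sgcca_mode")) {
    opts@sgccaMode <- TRUE
    opts@discriminant <- FALSE
  } else if (method == "multida") {
    opts@sgccaMode <- FALSE
    opts@discriminant <- TRUE
  } else stop(sprintf("unknown method '%s'", method))
  opts
}

#' Replicated simulation study of feature-selection performance
#'
#' For each replication: simulate a dataset ([simulateMultiblock()] with a
#' per-replication seed derived from `masterSeed`), prepare it, fit each
#' requested method on the identical data, select features and score them
#' against the ground truth. Returns the per-replication records and a
#' summary of mean, sample standard deviation and standard error of TPR,
#' PPV and ACCU per method. A replication whose fit fails is recorded with
#' `NA` metrics, excluded from the summary, and reported via a warning —
#' never dropped silently.
#'
#' @param nReplications number of replications.
#' @param methods subset of `c("multida", "sgcca")` (`"sgcca"` = the
#'   unweighted, slack-free ablation).
#' @param masterSeed integer; replication r uses seed `masterSeed + r`.
#' @param n samples per replication.
#' @param simArgs further arguments to [simulateMultiblock()].
#' @param options base [FitOptions-class] for the fits (per-method flags and
#'   seeds are set by the harness).
#' @param threshold selection threshold, see [selectFeatures()].
#' @param blocksEvaluated blocks pooled by [scoreSelection()]. The study
#'   default pools the three upstream blocks (SNP, CNV, DM; 600 features,
#'   30 true): the response block plays the role of the dependent side in
#'   two-block reference methods, so restricting the confusion matrix to
#'   the upstream blocks keeps the score comparable across methods. Pass
#'   `NULL` explicitly via [scoreSelection()] to pool all four feature
#'   blocks instead.
#' @param verbose print one line per replication.
#' @return `list(summary = data.frame(method, metric, mean, sd, se, n_reps),
#'   replications = data.frame of per-replication metrics and confusion
#'   counts, nFailed = integer)`.
#' @export
runStudy <- function(nReplications = 50L, methods = c("multida", "sgcca"),
                     masterSeed = 1L, n = 500L, simArgs = list(),
                     options = fitOptions(), threshold = 0,
                     blocksEvaluated = c("SNP", "CNV", "DM"),
                     verbose = FALSE) {
  methods <- match.arg(methods, c("multida", "sgcca", "sgcca_mode"),
                       several.ok = TRUE)
  recs <- list()
  nFailed <- 0L
  for (r in seq_len(nReplications)) {
    seed_r <- as.integer(masterSeed) + r
    sim <- do.call(simulateMultiblock,
                   c(list(n = n, seed = seed_r), simArgs))
    dat <- prepareBlocks(sim$data)
    for (mth in methods) {
      row <- data.frame(rep = r, seed = seed_r, method = mth,
                        TPR = NA_real_, PPV = NA_real_, ACCU = NA_real_,
                        TP = NA_integer_, FP = NA_integer_,
                        TN = NA_integer_, FN = NA_integer_,
                        failed = FALSE, stringsAsFactors = FALSE)
      res <- tryCatch({
        fit <- multidaFit(dat, options = .method_options(mth, options, seed_r))
        sc <- scoreSelection(selectFeatures(fit, threshold), sim$truth,
                             blocksEvaluated)
        m <- selectionMetrics(sc); cf <- selectionConfusion(sc)
        row[c("TPR", "PPV", "ACCU")] <- m[c("TPR", "PPV", "ACCU")]
        row[c("TP", "FP", "TN", "FN")] <- cf[c("TP", "FP", "TN", "FN")]
        row
      }, error = function(e) {
        warning(sprintf("replication %d (%s) failed: %s", r, mth,
                        conditionMessage(e)), call. = FALSE)
        row$failed <- TRUE
        row
      })
      nFailed <- nFailed + res$failed
      recs[[length(recs) + 1L]] <- res
      if (verbose)
        message(sprintf("rep %3d %-8s TPR=%.3f PPV=%.3f ACCU=%.3f",
                        r, mth, res$TPR, res$PPV, res$ACCU))
    }
  }
  reps <- do.call(rbind, recs)
  ok <- reps[!reps$failed, , drop = FALSE]
  summ <- do.call(rbind, lapply(unique(reps$method), function(mth) {
    sub <- ok[ok$method == mth, , drop = FALSE]
    do.call(rbind, lapply(c("TPR", "PPV", "ACCU"), function(metric) {
      v <- sub[[metric]]
      data.frame(method = mth, metric = metric,
                 mean = mean(v), sd = stats::sd(v),
                 se = stats::sd(v) / sqrt(length(v)),
                 n_reps = length(v), stringsAsFactors = FALSE)
    }))
  }))
  if (nReplications == 1L) summ$sd[is.na(summ$sd)] <- 0
  summ$se[is.na(summ$se)] <- 0
  list(summary = summ, replications = reps, nFailed = nFailed)
}

#' Write a study result to TSV and JSON
#'
#' @param study result of [runStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "study_summary.tsv")
  utils::write.table(study$summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "study_replications.json")
  jsonlite::write_json(
    list(summary = study$summary, replications = study$replications,
         nFailed = study$nFailed),
    js, digits = NA, dataframe = "rows", auto_unbox = TRUE)
  invisible(c(tsv, js))
}
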