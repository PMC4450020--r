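#' Read block matrices from delimited text
#'
#' Each file is a CSV with a header row of feature names and the sample ID
#' in the first column; all files must agree on the sample IDs and order.
#'
#' @param paths character vector of file paths, optionally named (names
#'   become block names).
#' @param sep field separator.
#' @return named list of numeric matrices with sample IDs as rownames.
#' @export
readBlocks <- function(paths, sep = ",") {
  if (!length(paths)) stop("no block files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("block file not found: %s", paste(missing, collapse = ", ")))
  nm <- names(paths)
  if (is.null(nm)) nm <- tools::file_path_sans_ext(basename(paths))
  out <- vector("list", length(paths))
  names(out) <- nm
  for (i in seq_along(paths)) {
    df <- utils::read.csv(paths[i], sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop(sprintf("%s: expected sample-ID column plus features", paths[i]))
    X <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(X))
      stop(sprintf("%s: non-numeric feature values", paths[i]))
    rownames(X) <- as.character(df[[1L]])
    out[[i]] <- X
  }
  out
}

#' Write block matrices as CSV
#'
#' Inverse of [readBlocks()]: one CSV per block, sample IDs in the first
#' column (`sample_id`), features in the header.
#'
#' @param blocks named list of matrices, or a [MultiblockData-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeBlocksCSV <- function(blocks, dir) {
  if (is(blocks, "MultiblockData")) {
    nm <- blockNames(blocks)
    blocks <- stats::setNames(multiblockDA::blocks(blocks), nm)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (bn in names(blocks)) {
    X <- blocks[[bn]]
    df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
    p <- file.path(dir, paste0(bn, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read binary labels from CSV
#'
#' Expects columns `sample_id` and `label`.
#'
#' @param path file path.
#' @return named vector of labels.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop(sprintf("labels file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop(sprintf("%s: expected columns sample_id, label", path))
  stats::setNames(df$label, df$sample_id)
}

#' @rdname readLabels
#' @param labels named label vector.
#' @export
writeLabels <- function(labels, path) {
  utils::write.csv(
    data.frame(sample_id = names(labels), label = unname(labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.num17 <- function(x) sprintf("%.17g", x)

#' Write / read a fitted LoadingSet
#'
#' `writeLoadings` emits one TSV per block (columns `rank`, `feature_name`,
#' `loading`; only nonzero loadings are listed) plus a JSON run manifest
#' (`manifest.json`) holding the options, per-block lambdas, objective
#' traces, convergence and degeneracy flags, slack vectors, scores, feature
#' names and package version. `readLoadings` reconstructs the LoadingSet
#' exactly (numbers round-trip at full precision).
#'
#' @param fit a [LoadingSet-class].
#' @param dir directory to write to / read from.
#' @return `writeLoadings`: invisibly, the paths written; `readLoadings`:
#'   a [LoadingSet-class].
#' @export
writeLoadings <- function(fit, dir) {
  stopifnot(is(fit, "LoadingSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (j in seq_along(fit@blockNames)) {
    rows <- list()
    for (r in seq_along(fit@loadings)) {
      a <- fit@loadings[[r]][[j]]
      nz <- which(a != 0)
      if (length(nz))
        rows[[length(rows) + 1L]] <- data.frame(
          rank = r, feature_name = names(a)[nz], loading = .num17(a[nz]),
          stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(rank = integer(), feature_name = character(),
                    loading = character())
    p <- file.path(dir, paste0("loadings_", fit@blockNames[j], ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  opts <- fit@options
  manifest <- list(
    package_version = as.character(utils::packageVersion("multiblockDA")),
    block_names = fit@blockNames,
    feature_names = fit@featureNames,
    sample_ids = fit@sampleIDs,
    options = list(
      nRanks = opts@nRanks, maxIter = opts@maxIter, tol = opts@tol,
      cvFolds = opts@cvFolds,
      lambdaGrid = if (is.character(opts@lambdaGrid)) opts@lambdaGrid
                   else as.numeric(opts@lambdaGrid),
      seed = opts@seed, discriminant = opts@discriminant,
      sgccaMode = opts@sgccaMode, normalization = opts@normalization,
      cvEverySweep = opts@cvEverySweep, warmMaxIter = opts@warmMaxIter),
    # numeric payloads as %.17g strings: doubles survive the round trip
    # bit for bit, which plain JSON numbers do not guarantee
    lambdas = lapply(fit@lambdas, .num17),
    objective_trace = lapply(fit@objectiveTrace, .num17),
    converged = fit@converged,
    degenerate = fit@degenerate,
    slack = lapply(fit@slack, function(s)
      if (length(s)) list(b = .num17(s$b), m = .num17(s$m)) else list()),
    scores = lapply(fit@scores, function(sr) lapply(sr, .num17)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, mp))
}

#' @rdname writeLoadings
#' @export
readLoadings <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop(sprintf("manifest not found: %s", mp))
  mf <- jsonlite::read_json(mp, simplifyVector = FALSE)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  chr <- function(x) vapply(x, as.character, character(1))
  lgl <- function(x) vapply(x, isTRUE, logical(1))
  bn <- chr(mf$block_names)
  fn <- lapply(mf$feature_names, chr)
  nR <- length(mf$converged)
  loadings <- vector("list", nR)
  store <- lapply(bn, function(b) {
    p <- file.path(dir, paste0("loadings_", b, ".tsv"))
    if (!file.exists(p)) stop(sprintf("loading table not found: %s", p))
    utils::read.table(p, header = TRUE, sep = "\t", colClasses =
                        c("integer", "character", "numeric"))
  })
  names(store) <- bn
  for (r in seq_len(nR)) {
    loadings[[r]] <- lapply(seq_along(bn), function(j) {
      a <- stats::setNames(numeric(length(fn[[j]])), fn[[j]])
      tb <- store[[j]]
      tb <- tb[tb$rank == r, , drop = FALSE]
      a[tb$feature_name] <- tb$loading
      a
    })
  }
  og <- mf$options
  lg <- og$lambdaGrid
  lg <- if (length(lg) == 1L && identical(lg[[1L]], "auto")) "auto" else num(lg)
  opts <- fitOptions(nRanks = og$nRanks, maxIter = og$maxIter, tol = og$tol,
                     cvFolds = og$cvFolds, lambdaGrid = lg,
                     seed = og$seed, discriminant = og$discriminant,
                     sgccaMode = og$sgccaMode,
                     normalization = og$normalization,
                     cvEverySweep = og$cvEverySweep,
                     warmMaxIter = og$warmMaxIter)
  sids <- chr(mf$sample_ids)
  scores <- lapply(seq_len(nR), function(r)
    lapply(seq_along(bn), function(j)
      stats::setNames(num(mf$scores[[r]][[j]]), sids)))
  slack <- lapply(seq_len(nR), function(r) {
    s <- mf$slack[[r]]
    if (!length(s)) list()
    else list(b = stats::setNames(num(s$b), sids),
              m = stats::setNames(num(s$m), sids))
  })
  new("LoadingSet", blockNames = bn, featureNames = fn,
      sampleIDs = sids, loadings = loadings,
      scores = scores,
      lambdas = lapply(mf$lambdas, num),
      objectiveTrace = lapply(mf$objective_trace, num),
      converged = lgl(mf$converged),
      degenerate = lapply(mf$degenerate, lgl),
      slack = slack, options = opts)
}

#' Write a simulation truth record as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  jsonlite::write_json(
    list(masks = lapply(truth@masks, function(m) as.integer(m)),
         coefficients = truth@coefficients,
         config = truth@config, seed = truth@seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) stop(sprintf("truth file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SimTruth",
      masks = lapply(obj$masks, function(m) as.logical(m)),
      coefficients = obj$coefficients,
      config = as.list(obj$config), seed = as.integer(obj$seed))
}
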