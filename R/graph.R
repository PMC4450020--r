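#' Construct a block graph
#'
#' @param C binary symmetric linkage matrix with zero diagonal.
#' @param D optional weight matrix; defaults to `C` (all linked pairs weighted
#'   equally).
#' @param blockNames optional block labels.
#' @return a [BlockGraph-class].
#' @export
blockGraph <- function(C, D = NULL, blockNames = NULL) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (is.null(D)) D <- C
  D <- as.matrix(D)
  storage.mode(D) <- "double"
  if (is.null(blockNames)) {
    blockNames <- rownames(C)
    if (is.null(blockNames)) blockNames <- paste0("B", seq_len(nrow(C)))
  }
  dimnames(C) <- dimnames(D) <- list(blockNames, blockNames)
  # name Class exactly: a slot called "C" would otherwise partially match it
  new(Class = "BlockGraph", C = C, D = D, blockNames = blockNames)
}

#' The five-block integrative genomic graph
#'
#' The default linkage for the SNP / CNV / DM (DNA methylation) / GE (gene
#' expression) / class layout: the three upstream genomic blocks each connect
#' to gene expression, and gene expression connects to the class block. The
#' weight matrix equals the linkage except that the gene-expression/class
#' pair is weighted 3, so the class correlation is not drowned out by the
#' larger genomic blocks.
#'
#' @param classWeight weight of the gene-expression/class pair (default 3).
#' @return a [BlockGraph-class] over blocks SNP, CNV, DM, GE, CLASS.
#' @examples
#' g <- defaultGenomicGraph()
#' designMatrix(g)["SNP", "GE"]  # 1
#' weightMatrix(g)["GE", "CLASS"]  # 3
#' @export
defaultGenomicGraph <- function(classWeight = 3) {
  nm <- c("SNP", "CNV", "DM", "GE", "CLASS")
  C <- matrix(0, 5, 5, dimnames = list(nm, nm))
  C[1:3, 4] <- C[4, 1:3] <- 1
  C[4, 5] <- C[5, 4] <- 1
  D <- C
  D[4, 5] <- D[5, 4] <- classWeight
  blockGraph(C, D, nm)
}

#' Read / write a block graph as JSON
#'
#' The JSON object holds `C` and `D` as nested arrays plus `block_names`.
#'
#' @param path file path.
#' @return `readBlockGraph` returns a [BlockGraph-class];
#'   `writeBlockGraph` returns `path` invisibly.
#' @export
readBlockGraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("C", "D", "block_names"))
    if (is.null(obj[[f]])) stop(sprintf("%s: missing field '%s'", path, f))
  blockGraph(obj$C, obj$D, obj$block_names)
}

#' @rdname readBlockGraph
#' @param graph a [BlockGraph-class].
#' @export
writeBlockGraph <- function(graph, path) {
  stopifnot(is(graph, "BlockGraph"))
  jsonlite::write_json(
    list(C = unname(graph@C), D = unname(graph@D),
         block_names = graph@blockNames),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}
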