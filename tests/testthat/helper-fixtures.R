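# Small in-code fixtures shared across test files.

# Two (or more) feature blocks driven by one shared latent factor, plus a
# class label correlated with it; returned prepared.
make_toy_data <- function(n = 40, ps = c(6, 5), seed = 42, labels = TRUE,
                          noise = 0.5) {
  set.seed(seed)
  z <- stats::rnorm(n)
  raw <- lapply(ps, function(p) {
    w <- stats::rnorm(p)
    z %*% t(w) + matrix(stats::rnorm(n * p), n, p) * noise
  })
  y <- if (labels) ifelse(z + stats::rnorm(n) * noise > 0, "case", "control")
  else NULL
  prepareBlocks(raw, labels = y)
}

# Fully connected unweighted graph over J blocks.
full_graph <- function(J, names = paste0("B", seq_len(J))) {
  C <- matrix(1, J, J) - diag(J)
  blockGraph(C, blockNames = names)
}

# Small complete five-block simulated dataset, prepared, with its truth.
small_sim <- function(n = 60, seed = 1) {
  sim <- simulateMultiblock(n = n, seed = seed)
  list(data = prepareBlocks(sim$data), truth = sim$truth, raw = sim$data)
}

# Build a LoadingSet by hand (for evaluation tests).
manual_loading_set <- function(loadings_by_rank, blockNames, featureNames) {
  nR <- length(loadings_by_rank)
  J <- length(blockNames)
  n <- 4L
  scores <- lapply(seq_len(nR), function(r)
    lapply(seq_len(J), function(j) numeric(n)))
  new("LoadingSet", blockNames = blockNames, featureNames = featureNames,
      sampleIDs = paste0("S", seq_len(n)),
      loadings = loadings_by_rank, scores = scores,
      lambdas = lapply(seq_len(nR), function(r) numeric(J)),
      objectiveTrace = lapply(seq_len(nR), function(r) numeric()),
      converged = rep(TRUE, nR),
      degenerate = lapply(seq_len(nR), function(r) logical(J)),
      slack = lapply(seq_len(nR), function(r) list()),
      options = fitOptions())
}
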