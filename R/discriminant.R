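#' Discriminant loading update (soft-thresholded regression on gamma)
#'
#' Updates the gene-expression loading by univariate soft-thresholding of the
#' columnwise inner products of the (centered) block with the working
#' response gamma, i.e. the elastic-net regression of gamma on the block.
#' Identical arithmetic to [ustUpdate()]; kept as its own entry point because
#' the discriminant derivation arrives at it through the slack-augmented
#' least-squares problem rather than the covariance objective. The caller
#' normalizes the result.
#'
#' @param chi4 centered N x P gene-expression block.
#' @param gamma length-N working response.
#' @param lambda4 nonnegative shrinkage level.
#' @return unnormalized loading vector of length P.
#' @seealso [ustUpdate()], [updateSlack()]
#' @export
updateDiscriminantLoading <- function(chi4, gamma, lambda4) {
  if (lambda4 < 0) stop("lambda4 must be nonnegative")
  ustUpdate(chi4, gamma, lambda4)
}

#' Slack-variable update
#'
#' Elementwise `m_i = max(b_i * (chi4 alpha4 - target)_i, 0)`: the slack
#' grows exactly where the gene-expression score overshoots the class score
#' in the direction of the sample's own class, so slack can only enlarge the
#' class separation, never reverse a label.
#'
#' @param chi4 centered gene-expression block.
#' @param alpha4 its current loading vector.
#' @param target length-N class-side score the residual is taken against
#'   (the class block's latent score).
#' @param b length-N class direction vector in \{-1, +1\}.
#' @return nonnegative slack vector of length N.
#' @export
updateSlack <- function(chi4, alpha4, target, b) {
  v4 <- drop(chi4 %*% alpha4)
  if (length(v4) != length(target) || length(v4) != length(b))
    stop("shape mismatch between scores, target and class direction")
  pmax(b * (v4 - target), 0)
}

#' Slack-augmented class block
#'
#' Returns `X5 + b * m`: each sample's -1/+1 label pushed away from the
#' decision boundary by its nonnegative slack, in its own class direction.
#' This is the working class block used in every covariance term while the
#' discriminant machinery is active.
#'
#' @param X5 N x 1 class block with values in \{-1, +1\}.
#' @param b length-N class direction vector (`b = drop(X5)`).
#' @param m length-N nonnegative slack vector.
#' @return N x 1 matrix.
#' @export
augmentedClassBlock <- function(X5, b, m) {
  X5 <- as.matrix(X5)
  if (ncol(X5) != 1L) stop("class block must have one column")
  if (any(m < 0)) stop("slack must be nonnegative")
  out <- X5 + b * m
  dimnames(out) <- dimnames(X5)
  out
}
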