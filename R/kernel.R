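# The Laplacian kernel K(x, y) = exp(-sigma * ||x - y||) (Euclidean
# norm), used by both regressors.

#' Laplacian kernel between two vectors
#' @param x,y numeric vectors of equal length.
#' @param sigma positive bandwidth.
#' @return exp(-sigma * ||x - y||), in (0, 1].
#' @export
laplacianKernel <- function(x, y, sigma) {
  if (length(x) != length(y))
    stop("dimension mismatch: ", length(x), " vs ", length(y))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  exp(-sigma * sqrt(sum((x - y)^2)))
}

#' Laplacian Gram matrix
#'
#' Cross-kernel matrix between the rows of X and Y (Y defaults to X, in
#' which case the result is symmetric with unit diagonal).
#'
#' @param X,Y numeric matrices with matching column counts (a
#'   [FeatureMatrix-class] is also accepted).
#' @param sigma positive bandwidth.
#' @return matrix of kernel values, nrow(X) x nrow(Y).
#' @export
laplacianGram <- function(X, Y = NULL, sigma) {
  if (is(X, "FeatureMatrix")) X <- as.matrix(X)
  if (!is.null(Y) && is(Y, "FeatureMatrix")) Y <- as.matrix(Y)
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  symm <- is.null(Y)
  if (symm) Y <- X
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("dimension mismatch: ", ncol(X), " vs ", ncol(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  K <- exp(-sigma * sqrt(d2))
  if (symm) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}
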