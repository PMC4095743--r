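# Epsilon-insensitive support vector regression with the Laplacian
# kernel. The primal
#   min 1/2 ||w||^2 + C sum_i (xi_i + xi_i')
#   s.t. |y_i - <w, phi(x_i)> - b| <= epsilon + slack
# is solved through its standard dual in beta_i = alpha_i - alpha_i':
#   max  y'beta - epsilon ||beta||_1 - 1/2 beta' K beta
#   s.t. sum(beta) = 0,  |beta_i| <= C.
# The QP is handed to an established convex solver: kernlab's
# interior-point code (ipop) on the explicit dual for small problems,
# kernlab's SMO (ksvm) for large ones. Both optimise the same objective.

#' Fit epsilon-insensitive SVR with the Laplacian kernel
#'
#' @param X training feature matrix (rows are pairs; a
#'   [FeatureMatrix-class] is accepted).
#' @param y training strengths.
#' @param sigma Laplacian kernel bandwidth.
#' @param C box constraint (> 0).
#' @param epsilon insensitivity half-width (>= 0). The default 0.1
#'   follows the default of the kernel-method package this model family
#'   is traditionally fitted with.
#' @param solver "auto" (interior point up to 100 points, SMO above),
#'   "ipop" or "ksvm".
#' @param svTol dual coefficients with |beta| > svTol count as support
#'   vectors.
#' @return an [SVRModel-class].
#' @export
svrFit <- function(X, y, sigma, C = 1, epsilon = 0.1,
                   solver = c("auto", "ipop", "ksvm"), svTol = 1e-8) {
  if (is(X, "FeatureMatrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training points")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be non-negative")
  solver <- match.arg(solver)
  if (solver == "auto") solver <- if (n <= 100) "ipop" else "ksvm"
  kern <- laplacianSpec(sigma)
  if (solver == "ipop") {
    K <- laplacianGram(X, sigma = sigma)
    # duplicate training rows make the reduced interior-point system
    # singular; SMO handles those, so fall back
    beta <- tryCatch(svrDualIpop(K, y, C, epsilon),
                     error = function(e) svrDualKsvm(X, y, sigma, C, epsilon))
  } else {
    beta <- svrDualKsvm(X, y, sigma, C, epsilon)
  }
  K <- laplacianGram(X, sigma = sigma)
  f <- as.numeric(K %*% beta)
  bias <- svrBias(beta, f, y, C, epsilon)
  dual <- sum(y * beta) - epsilon * sum(abs(beta)) -
    0.5 * sum(beta * (K %*% beta))
  sv <- which(abs(beta) > svTol)
  # note: the C slot is set afterwards because an argument named "C"
  # would partially match new()'s Class formal
  m <- new("SVRModel",
           supportVectors = X[sv, , drop = FALSE],
           coefficients = beta[sv], bias = bias, epsilon = epsilon,
           kernel = kern, dualObjective = dual, nSV = length(sv))
  m@C <- C
  m
}

# interior-point solution of the dual in (alpha, alpha') form
svrDualIpop <- function(K, y, C, epsilon) {
  n <- nrow(K)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  diag(H) <- diag(H) + 1e-10   # tiny ridge: H is PSD but rank-deficient
  cc <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  res <- kernlab::ipop(c = cc, H = H, A = A, b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 9, maxiter = 100)
  if (!kernlab::how(res) %in% c("converged", "convergence"))
    stop("SVR dual solver did not converge: ", kernlab::how(res))
  x <- kernlab::primal(res)
  x[seq_len(n)] - x[n + seq_len(n)]
}

# SMO solution via ksvm; recover signed dual coefficients robustly
svrDualKsvm <- function(X, y, sigma, C, epsilon) {
  m <- kernlab::ksvm(X, y, type = "eps-svr", kernel = "laplacedot",
                     kpar = list(sigma = sigma), C = C, epsilon = epsilon,
                     scaled = FALSE, tol = 1e-6)
  beta <- numeric(nrow(X))
  beta[kernlab::alphaindex(m)] <- kernlab::coef(m)
  # fix the sign convention by checking which orientation leaves a
  # constant intercept against the solver's own predictions
  K <- laplacianGram(X, sigma = sigma)
  p <- as.numeric(kernlab::predict(m, X))
  r1 <- p - as.numeric(K %*% beta)
  r2 <- p + as.numeric(K %*% beta)
  if (stats::sd(r2) < stats::sd(r1)) beta <- -beta
  beta
}

# KKT-based intercept: exact on interior points, interval midpoint when
# every coefficient sits at a bound or zero
svrBias <- function(beta, f, y, C, epsilon) {
  tolC <- 1e-6 * C
  interior_pos <- beta > tolC & beta < C - tolC
  interior_neg <- beta < -tolC & beta > -C + tolC
  if (any(interior_pos) || any(interior_neg)) {
    vals <- c((y - f - epsilon)[interior_pos], (y - f + epsilon)[interior_neg])
    return(mean(vals))
  }
  at_zero <- abs(beta) <= tolC
  lo <- c((y - f + epsilon)[beta <= -C + tolC & !at_zero],
          (y - f - epsilon)[at_zero])
  hi <- c((y - f - epsilon)[beta >= C - tolC & !at_zero],
          (y - f + epsilon)[at_zero])
  lo <- if (length(lo)) max(lo) else -Inf
  hi <- if (length(hi)) min(hi) else Inf
  if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
  else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
}

#' Predict with a fitted model
#'
#' Evaluates f(x) = sum_i beta_i K(x_i, x) + b (SVR) or the posterior
#' mean w' phi(x) (RVM) on new feature vectors. Predictions are raw
#' regression outputs by default; clipping to [0, 1] is opt-in.
#'
#' @param object an [SVRModel-class] or [RVMModel-class].
#' @param newdata feature matrix (or [FeatureMatrix-class]) with the
#'   training dimensionality.
#' @param clip clamp predictions into [0, 1]?
#' @param ... ignored.
#' @return numeric vector of predicted strengths.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, clip = FALSE, ...) {
  if (is(newdata, "FeatureMatrix")) newdata <- as.matrix(newdata)
  newdata <- as.matrix(newdata)
  if (object@nSV == 0) {
    p <- rep(object@bias, nrow(newdata))
  } else {
    if (ncol(newdata) != ncol(object@supportVectors))
      stop("dimension mismatch: ", ncol(newdata), " vs ",
           ncol(object@supportVectors))
    K <- laplacianGram(newdata, object@supportVectors,
                       sigma = object@kernel@sigma)
    p <- as.numeric(K %*% object@coefficients) + object@bias
  }
  if (clip) p <- pmin(pmax(p, 0), 1)
  p
})
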