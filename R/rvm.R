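# Relevance vector machine regression, implemented from scratch by
# evidence (type-II marginal likelihood) maximisation.
#
# Model: y = Phi w + noise, noise ~ N(0, 1/beta), with the design matrix
# Phi = [1, K(., x_1), ..., K(., x_N)] (one Laplacian kernel basis per
# training point plus a constant bias column, M = N + 1 weights) and an
# independent zero-mean Gaussian prior N(0, 1/alpha_i) on each weight.
# The alpha_i are re-estimated by the standard fixed-point updates; most
# diverge, their bases are pruned, and the surviving kernel bases are the
# relevance vectors.

#' Fit a relevance vector machine with the Laplacian kernel
#'
#' Iterates the posterior
#' Sigma = (beta Phi' Phi + diag(alpha))^-1, mu = beta Sigma Phi' y
#' with the evidence updates
#' gamma_i = 1 - alpha_i Sigma_ii, alpha_i = gamma_i / mu_i^2,
#' beta = (N - sum gamma) / ||y - Phi mu||^2,
#' pruning bases whose alpha exceeds \code{pruneThreshold}, until the
#' largest |delta log alpha| falls below \code{tol} or \code{maxIter} is
#' reached. The log marginal likelihood is tracked every iteration.
#'
#' @param X training feature matrix (rows are pairs; a
#'   [FeatureMatrix-class] is accepted).
#' @param y training strengths.
#' @param sigma Laplacian kernel bandwidth.
#' @param maxIter maximum number of update sweeps (0 = return the
#'   posterior at the initial hyperparameters, no re-estimation).
#' @param tol convergence tolerance on max |delta log alpha|.
#' @param pruneThreshold bases with alpha above this are removed.
#' @param alphaInit initial value for every alpha_i.
#' @param betaInit initial noise precision; default 100 / var(y).
#' @param betaFreeze number of initial sweeps during which beta is held
#'   at its initial value while the alpha_i adapt (see the noise
#'   schedule note in the source).
#' @return an [RVMModel-class].
#' @export
rvmFit <- function(X, y, sigma, maxIter = 1000, tol = 1e-6,
                   pruneThreshold = 1e12, alphaInit = 1e-4,
                   betaInit = NULL, betaFreeze = 10L) {
  if (is(X, "FeatureMatrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training points")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  vy <- var(y)
  if (is.null(betaInit)) betaInit <- 100 / if (vy > 0) vy else 1
  kern <- laplacianSpec(sigma)

  Phi_full <- cbind(1, laplacianGram(X, sigma = sigma))
  M <- n + 1L
  active <- seq_len(M)           # 1 = bias, 1 + i = kernel basis at x_i
  alpha <- rep(alphaInit, M)
  beta <- betaInit
  PtP <- crossprod(Phi_full)
  Pty <- as.numeric(crossprod(Phi_full, y))
  yty <- sum(y^2)
  evidence <- numeric(0)

  posterior <- function(active, alpha_a, beta) {
    Hmat <- beta * PtP[active, active, drop = FALSE]
    diag(Hmat) <- diag(Hmat) + alpha_a
    R <- tryCatch(chol(Hmat), error = function(e) {
      warning("posterior precision not factorizable; adding 1e-10 jitter")
      chol(Hmat + diag(1e-10, length(active)))
    })
    Sigma <- chol2inv(R)
    mu <- beta * as.numeric(Sigma %*% Pty[active])
    # log evidence = -1/2 (N log 2pi - sum log alpha - N log beta
    #                + log det H + beta ||y - Phi mu||^2 + mu' A mu)
    rss <- yty - 2 * sum(mu * Pty[active]) +
      sum(mu * (PtP[active, active, drop = FALSE] %*% mu))
    rss <- max(rss, 0)
    logdetH <- 2 * sum(log(diag(R)))
    ev <- -0.5 * (n * log(2 * pi) - sum(log(alpha_a)) - n * log(beta) +
                  logdetH + beta * rss + sum(alpha_a * mu^2))
    list(Sigma = Sigma, mu = mu, rss = rss, ev = ev)
  }

  iter <- 0L
  converged <- FALSE
  repeat {
    post <- posterior(active, alpha[active], beta)
    evidence <- c(evidence, post$ev)
    if (iter >= maxIter) break
    iter <- iter + 1L
    gammas <- 1 - alpha[active] * diag(post$Sigma)
    gammas <- pmin(pmax(gammas, 0), 1)
    alpha_new <- gammas / pmax(post$mu^2, .Machine$double.xmin)
    denom <- max(post$rss, 1e-300)
    # noise-precision schedule: held for the first betaFreeze sweeps and
    # growth-damped afterwards. With a still-flat prior the full basis
    # interpolates y, rss collapses, and an immediately re-estimated
    # beta diverges on the first sweep before any alpha can prune its
    # basis, locking the model into interpolation.
    beta_new <- if (iter <= betaFreeze) beta
      else min(max(n - sum(gammas), 1e-6) / denom, 4 * beta)
    dlog <- abs(log(pmin(alpha_new, pruneThreshold)) -
                log(pmin(alpha[active], pruneThreshold)))
    alpha[active] <- alpha_new
    beta <- beta_new
    keep <- alpha[active] <= pruneThreshold
    if (!any(keep)) stop("all basis functions pruned; decrease sigma or pruneThreshold")
    active <- active[keep]
    if (iter > betaFreeze && max(dlog[keep]) < tol) converged <- TRUE
    if (converged) {
      post <- posterior(active, alpha[active], beta)
      evidence <- c(evidence, post$ev)
      break
    }
  }

  biasIncluded <- 1L %in% active
  kernBases <- active[active > 1L] - 1L
  new("RVMModel",
      relevanceVectors = X[kernBases, , drop = FALSE],
      weights = post$mu, alpha = alpha[active], beta = beta,
      biasIncluded = biasIncluded, kernel = kern,
      evidence = evidence, nRV = length(kernBases),
      converged = converged || maxIter == 0)
}

#' @rdname predict-SVRModel-method
#' @aliases predict,RVMModel-method
#' @export
setMethod("predict", "RVMModel", function(object, newdata, clip = FALSE, ...) {
  if (is(newdata, "FeatureMatrix")) newdata <- as.matrix(newdata)
  newdata <- as.matrix(newdata)
  w <- object@weights
  p <- numeric(nrow(newdata))
  off <- 0L
  if (object@biasIncluded) {
    p <- p + w[1]
    off <- 1L
  }
  if (object@nRV > 0) {
    if (ncol(newdata) != ncol(object@relevanceVectors))
      stop("dimension mismatch: ", ncol(newdata), " vs ",
           ncol(object@relevanceVectors))
    K <- laplacianGram(newdata, object@relevanceVectors,
                       sigma = object@kernel@sigma)
    p <- p + as.numeric(K %*% w[(off + 1L):length(w)])
  }
  if (clip) p <- pmin(pmax(p, 0), 1)
  p
})
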