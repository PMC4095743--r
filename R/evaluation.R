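# The cross-validated evaluation protocol: threefold outer CV with
# nested fivefold kernel-bandwidth selection, coverage filtering of test
# pairs against the training-split APM table, and RMSE reporting.

#' Root mean square error
#' @param predicted,observed numeric vectors of equal, nonzero length.
#' @return sqrt(mean((predicted - observed)^2)).
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0 || length(predicted) != length(observed))
    stop("predicted and observed must have equal, nonzero length")
  sqrt(mean((predicted - observed)^2))
}

#' Build a reproducible nested cross-validation plan
#'
#' Pairs are partitioned uniformly at random into 3 outer folds whose
#' sizes differ by at most 1; each outer training set is further
#' partitioned into 5 inner folds under the same rule.
#'
#' @param n number of pairs (>= 15).
#' @param seed integer seed; identical seeds give identical plans.
#' @param sigmaGrid candidate kernel bandwidths (strictly increasing).
#'   Default 0.01, 0.02, ..., 0.1.
#' @param CGrid candidate SVR box constraints. Default 1, 2, 5.
#' @return a [CVPlan-class].
#' @export
makeCVPlan <- function(n, seed, sigmaGrid = seq(0.01, 0.1, by = 0.01),
                       CGrid = c(1, 2, 5)) {
  if (n < 15) stop("need at least 15 pairs for 3x5 nested CV")
  balancedFolds <- function(idx, k) {
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    shuffled <- sample(idx)
    split(shuffled, rep(seq_len(k), times = sizes))
  }
  plan <- withr::with_seed(as.integer(seed), {
    outer <- balancedFolds(seq_len(n), 3L)
    inner <- lapply(outer, function(f) {
      balancedFolds(setdiff(seq_len(n), f), 5L)
    })
    list(outer = outer, inner = inner)
  })
  new("CVPlan",
      outerFolds = unname(lapply(plan$outer, function(v) sort(as.integer(v)))),
      innerFolds = unname(lapply(plan$inner, function(l)
        unname(lapply(l, function(v) sort(as.integer(v)))))),
      seed = as.integer(seed),
      sigmaGrid = as.numeric(sigmaGrid), CGrid = as.numeric(CGrid))
}

#' Select the kernel bandwidth by inner cross-validation
#'
#' Fits the model on each inner training split for every candidate
#' sigma and returns the grid value minimising the mean validation RMSE.
#' Ties (within 1e-12) go to the smallest sigma. Candidates for which
#' training fails on some inner split are skipped with a recorded
#' reason; if every candidate fails, an error is raised.
#'
#' @param X feature matrix of the (outer) training pairs.
#' @param y their strengths.
#' @param modelKind "svr" or "rvm".
#' @param innerFolds list of index vectors (into rows of X) partitioning
#'   the training set into validation folds.
#' @param sigmaGrid candidate bandwidths.
#' @param C SVR box constraint (ignored for RVM).
#' @param epsilon SVR tube half-width.
#' @param svrSolver forwarded to [svrFit()].
#' @return list with \code{sigma} (the selection), \code{rmse} (mean
#'   validation RMSE per candidate, NA where skipped) and \code{skipped}
#'   (named character vector of failure reasons).
#' @export
selectSigma <- function(X, y, modelKind, innerFolds, sigmaGrid,
                        C = 1, epsilon = 0.1, svrSolver = "auto") {
  if (is(X, "FeatureMatrix")) X <- as.matrix(X)
  X <- as.matrix(X)
  stopifnot(length(sigmaGrid) >= 1)
  means <- rep(NA_real_, length(sigmaGrid))
  skipped <- character(0)
  for (si in seq_along(sigmaGrid)) {
    sg <- sigmaGrid[si]
    errs <- numeric(0)
    ok <- TRUE
    for (fold in innerFolds) {
      tr <- setdiff(seq_len(nrow(X)), fold)
      fit <- tryCatch({
        if (modelKind == "svr")
          svrFit(X[tr, , drop = FALSE], y[tr], sigma = sg, C = C,
                 epsilon = epsilon, solver = svrSolver)
        else
          rvmFit(X[tr, , drop = FALSE], y[tr], sigma = sg)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        skipped[as.character(sg)] <- conditionMessage(fit)
        ok <- FALSE
        break
      }
      errs <- c(errs, rmse(predict(fit, X[fold, , drop = FALSE]), y[fold]))
    }
    if (ok) means[si] <- mean(errs)
  }
  if (all(is.na(means)))
    stop("model training failed for every sigma candidate: ",
         paste(unique(skipped), collapse = "; "))
  best <- min(means, na.rm = TRUE)
  sigma <- sigmaGrid[which(!is.na(means) & means <= best + 1e-12)[1]]
  list(sigma = sigma, rmse = means, skipped = skipped)
}

defaultSigmaGrid <- function(modelKind, mapping) {
  # the low-dimensional APM-score feature needs much larger bandwidths
  # for the RVM to train at all; its grid is 3.0, 3.1, ..., 9.0
  if (modelKind == "rvm" && mapping == "apm") seq(3.0, 9.0, by = 0.1)
  else seq(0.01, 0.1, by = 0.01)
}

#' Run the full cross-validated evaluation protocol
#'
#' Threefold outer cross-validation over the dataset's pairs. Per outer
#' fold: the APM score table is estimated from the training pairs only;
#' test pairs failing the [coverageFilter()] against that table are
#' dropped (for every model, so all models are scored on the same
#' pairs); features are built; the kernel bandwidth is selected by
#' fivefold inner CV; the model is fitted and scored by [rmse()] on the
#' full outer-training set and on the kept test pairs. Feature models
#' additionally get an unfiltered test RMSE. The "apm_baseline" model
#' kind predicts directly by noisy-OR combination of the training APM
#' scores, with no regression.
#'
#' Pairs are put in canonical key order before folds are applied, so the
#' report depends only on the pair set and the plan, not on input order.
#'
#' @param dataset a [PairDataset-class].
#' @param mapping feature mapping: "dn", "spd" or "apm" (ignored for
#'   \code{modelKind = "apm_baseline"}).
#' @param modelKind "svr", "rvm" or "apm_baseline".
#' @param k spectrum word length for mapping "spd".
#' @param plan a [CVPlan-class]; built from \code{seed} when omitted.
#' @param seed used to build the plan when \code{plan} is NULL.
#' @param sigmaGrid,CGrid overrides for the plan's grids (defaults: the
#'   protocol grids, see [defaultSigmaGrid] in the source; C in 1, 2, 5).
#' @param epsilon SVR tube half-width.
#' @param distinctDomains forwarded to [apmScores()].
#' @param svrSolver forwarded to [svrFit()].
#' @return an [EvaluationReport-class].
#' @export
runProtocol <- function(dataset, mapping = c("dn", "spd", "apm"),
                        modelKind = c("svr", "rvm", "apm_baseline"),
                        k = 1, plan = NULL, seed = 1,
                        sigmaGrid = NULL, CGrid = NULL, epsilon = 0.1,
                        distinctDomains = FALSE, svrSolver = "auto") {
  modelKind <- match.arg(modelKind)
  mapping <- if (modelKind == "apm_baseline") "none" else match.arg(mapping)
  ord <- order(pairKey(dataset@pairs$protein_a, dataset@pairs$protein_b))
  dataset <- subsetPairs(dataset, ord)
  n <- nrow(dataset@pairs)
  if (is.null(sigmaGrid)) sigmaGrid <- defaultSigmaGrid(modelKind, mapping)
  if (is.null(CGrid)) CGrid <- c(1, 2, 5)
  if (is.null(plan)) plan <- makeCVPlan(n, seed, sigmaGrid, CGrid)
  else {
    if (sum(lengths(plan@outerFolds)) != n)
      stop("plan was built for a different number of pairs")
    plan@sigmaGrid <- as.numeric(sigmaGrid)
    plan@CGrid <- as.numeric(CGrid)
  }
  Cs <- if (modelKind == "svr") plan@CGrid else NA_real_

  results <- list(); preds <- list()
  for (f in 1:3) {
    testIdx <- plan@outerFolds[[f]]
    trainIdx <- sort(setdiff(seq_len(n), testIdx))
    trainSet <- subsetPairs(dataset, trainIdx)
    testPairs <- dataset@pairs[testIdx, , drop = FALSE]
    apmTable <- apmScores(trainSet, distinctDomains = distinctDomains)
    cov <- coverageFilter(testPairs, apmTable, dataset@proteins)
    kept <- cov$kept
    if (nrow(kept) == 0)
      stop("coverage filter kept no test pairs in fold ", f)
    yTrain <- trainSet@pairs$strength

    if (modelKind == "apm_baseline") {
      pTrain <- predictStrength(trainSet@pairs, apmTable, dataset@proteins)
      pTest <- predictStrength(kept, apmTable, dataset@proteins)
      results[[length(results) + 1]] <- data.frame(
        fold = f, C = NA_real_, sigma = NA_real_,
        trainRMSE = rmse(pTrain, yTrain),
        testRMSE = rmse(pTest, kept$strength),
        testRMSEUnfiltered = NA_real_,
        nKept = nrow(kept), nDropped = nrow(cov$dropped),
        nVectors = NA_integer_)
      preds[[length(preds) + 1]] <- rbind(
        data.frame(fold = f, C = NA_real_, protein_a = trainSet@pairs$protein_a,
                   protein_b = trainSet@pairs$protein_b, split = "train",
                   observed = yTrain, predicted = pTrain),
        data.frame(fold = f, C = NA_real_, protein_a = kept$protein_a,
                   protein_b = kept$protein_b, split = "test",
                   observed = kept$strength, predicted = pTest))
      next
    }

    feat <- switch(mapping,
      dn = function(p) dnFeatures(dataset, p),
      spd = function(p) spdFeatures(dataset, k, p),
      apm = function(p) apmFeatures(dataset, apmTable, p))
    Xtrain <- as.matrix(feat(trainSet@pairs))
    Xtest <- as.matrix(feat(kept))
    XtestAll <- if (mapping != "apm") as.matrix(feat(testPairs)) else NULL
    # inner-fold indices relative to the outer-training row order
    innerRel <- lapply(plan@innerFolds[[f]], function(v) match(v, trainIdx))

    for (C in Cs) {
      sel <- selectSigma(Xtrain, yTrain, modelKind, innerRel,
                         plan@sigmaGrid, C = C, epsilon = epsilon,
                         svrSolver = svrSolver)
      fit <- if (modelKind == "svr")
        svrFit(Xtrain, yTrain, sigma = sel$sigma, C = C, epsilon = epsilon,
               solver = svrSolver)
      else
        rvmFit(Xtrain, yTrain, sigma = sel$sigma)
      pTrain <- predict(fit, Xtrain)
      pTest <- predict(fit, Xtest)
      unf <- if (!is.null(XtestAll))
        rmse(predict(fit, XtestAll), testPairs$strength) else NA_real_
      results[[length(results) + 1]] <- data.frame(
        fold = f, C = C, sigma = sel$sigma,
        trainRMSE = rmse(pTrain, yTrain),
        testRMSE = rmse(pTest, kept$strength),
        testRMSEUnfiltered = unf,
        nKept = nrow(kept), nDropped = nrow(cov$dropped),
        nVectors = if (modelKind == "svr") fit@nSV else fit@nRV)
      preds[[length(preds) + 1]] <- rbind(
        data.frame(fold = f, C = C, protein_a = trainSet@pairs$protein_a,
                   protein_b = trainSet@pairs$protein_b, split = "train",
                   observed = yTrain, predicted = pTrain),
        data.frame(fold = f, C = C, protein_a = kept$protein_a,
                   protein_b = kept$protein_b, split = "test",
                   observed = kept$strength, predicted = pTest))
      if (modelKind == "rvm") break  # RVM has no C; one run per fold
    }
  }
  results <- do.call(rbind, results)
  preds <- do.call(rbind, preds)
  agg <- stats::aggregate(results[, c("trainRMSE", "testRMSE")],
                          by = list(C = results$C), FUN = mean)
  if (all(is.na(results$C)))
    agg <- data.frame(C = NA_real_,
                      trainRMSE = mean(results$trainRMSE),
                      testRMSE = mean(results$testRMSE))
  colnames(agg) <- c("C", "meanTrainRMSE", "meanTestRMSE")
  new("EvaluationReport", results = results, summary = agg,
      predictions = preds, plan = plan, mapping = mapping,
      modelKind = modelKind,
      k = if (mapping == "spd") as.numeric(k) else NA_real_)
}
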