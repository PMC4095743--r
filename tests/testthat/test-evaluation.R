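smallDataset <- function(seed = 21) {
  generateDataset(generatorConfig(n_proteins = 30, n_domains = 10,
                                  n_pairs = 60, zero_pair_count = 6,
                                  seed = seed))$dataset
}

test_that("rmse follows its definition", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.3, 0.4), c(0, 0)), sqrt(0.125))
  x <- runif(10)
  expect_equal(rmse(x + 0.2, x), 0.2)
  expect_error(rmse(numeric(0), numeric(0)), "length")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("CV plans balance folds and reproduce under the seed", {
  p15 <- makeCVPlan(15, seed = 5)
  expect_identical(sort(lengths(p15@outerFolds)), c(5L, 5L, 5L))
  p16 <- makeCVPlan(16, seed = 5)
  expect_identical(sort(lengths(p16@outerFolds), decreasing = TRUE),
                   c(6L, 5L, 5L))
  expect_identical(makeCVPlan(40, seed = 9), makeCVPlan(40, seed = 9))
  expect_false(identical(makeCVPlan(40, seed = 9), makeCVPlan(40, seed = 10)))
  expect_error(makeCVPlan(14, seed = 1), "15")
  # inner folds partition each outer training set (validity re-checked here
  # for one plan by hand)
  for (f in 1:3) {
    tr <- sort(setdiff(1:40, makeCVPlan(40, seed = 9)@outerFolds[[f]]))
    expect_identical(sort(unlist(makeCVPlan(40, seed = 9)@innerFolds[[f]])), tr)
  }
})

test_that("sigma selection minimises inner-CV RMSE with smallest-sigma ties", {
  d <- smallDataset()
  X <- as.matrix(dnFeatures(d))
  y <- strengths(d)
  plan <- makeCVPlan(length(y), seed = 3)
  inner <- plan@innerFolds[[1]]
  trainIdx <- sort(setdiff(seq_along(y), plan@outerFolds[[1]]))
  innerRel <- lapply(inner, function(v) match(v, trainIdx))
  Xt <- X[trainIdx, ]; yt <- y[trainIdx]
  grid <- c(0.02, 0.05, 0.1, 0.5)
  sel <- selectSigma(Xt, yt, "svr", innerRel, grid, C = 1)
  # exhaustive recomputation of the same inner-CV criterion
  means <- vapply(grid, function(sg) {
    mean(vapply(innerRel, function(fold) {
      tr <- setdiff(seq_along(yt), fold)
      m <- svrFit(Xt[tr, ], yt[tr], sigma = sg, C = 1)
      rmse(predict(m, Xt[fold, , drop = FALSE]), yt[fold])
    }, 0))
  }, 0)
  expect_equal(sel$rmse, means, tolerance = 1e-8)
  expect_identical(sel$sigma, grid[which.min(means)])
  # single-element grid returns that element
  expect_identical(selectSigma(Xt, yt, "svr", innerRel, 0.07)$sigma, 0.07)
  # exact ties resolve to the smallest sigma: constant targets make every
  # sigma equivalent (zero support vectors, constant prediction)
  sel2 <- selectSigma(Xt, rep(0.5, length(yt)), "svr", innerRel,
                      c(0.01, 0.02, 0.03))
  expect_identical(sel2$sigma, 0.01)
})

test_that("the protocol report is internally consistent and plan-determined", {
  d <- smallDataset()
  n <- nrow(pairTable(d))
  plan <- makeCVPlan(n, seed = 17, sigmaGrid = c(0.05, 0.1), CGrid = 1)
  rep1 <- runProtocol(d, mapping = "dn", modelKind = "svr", plan = plan,
                      sigmaGrid = c(0.05, 0.1), CGrid = 1)
  res <- reportResults(rep1)
  preds <- reportPredictions(rep1)
  # RMSEs recomputable from the per-pair prediction dump
  for (r in seq_len(nrow(res))) {
    tr <- preds[preds$fold == res$fold[r] & preds$split == "train", ]
    te <- preds[preds$fold == res$fold[r] & preds$split == "test", ]
    expect_equal(res$trainRMSE[r], rmse(tr$predicted, tr$observed))
    expect_equal(res$testRMSE[r], rmse(te$predicted, te$observed))
    expect_identical(res$nKept[r], nrow(te))
  }
  # averaged RMSE is the arithmetic mean over the 3 folds
  expect_equal(reportSummary(rep1)$meanTestRMSE, mean(res$testRMSE))
  expect_equal(reportSummary(rep1)$meanTrainRMSE, mean(res$trainRMSE))
  # kept + dropped = fold size
  expect_identical(res$nKept + res$nDropped,
                   vapply(res$fold, function(f)
                     length(plan@outerFolds[[f]]), 0L))
  # shuffling the pair rows changes nothing given the same plan
  d2 <- subsetPairs(d, withr::with_seed(1, sample(n)))
  rep2 <- runProtocol(d2, mapping = "dn", modelKind = "svr", plan = plan,
                      sigmaGrid = c(0.05, 0.1), CGrid = 1)
  expect_equal(reportResults(rep2), res)
})

test_that("the protocol never leaks test strengths into training", {
  d <- smallDataset(22)
  n <- nrow(pairTable(d))
  # pre-sort into canonical order so plan indices align with the
  # protocol's internal ordering
  key <- paste(pairTable(d)$protein_a, pairTable(d)$protein_b)
  d <- subsetPairs(d, order(key))
  plan <- makeCVPlan(n, seed = 8, sigmaGrid = c(0.05, 0.1), CGrid = 1)
  rep1 <- runProtocol(d, mapping = "dn", modelKind = "svr", plan = plan,
                      sigmaGrid = c(0.05, 0.1), CGrid = 1)
  # sentinel: perturb the strengths of fold-1 test pairs only
  d2 <- d
  idx <- plan@outerFolds[[1]]
  d2@pairs$strength[idx] <- withr::with_seed(2, runif(length(idx)))
  rep2 <- runProtocol(d2, mapping = "dn", modelKind = "svr", plan = plan,
                      sigmaGrid = c(0.05, 0.1), CGrid = 1)
  p1 <- reportPredictions(rep1); p2 <- reportPredictions(rep2)
  f1 <- p1[p1$fold == 1, ]; f2 <- p2[p2$fold == 1, ]
  # identical fitted model: identical predictions everywhere in fold 1
  expect_equal(f1$predicted, f2$predicted)
  expect_identical(reportResults(rep1)$sigma[1], reportResults(rep2)$sigma[1])
  expect_equal(reportResults(rep1)$trainRMSE[1], reportResults(rep2)$trainRMSE[1])
})

test_that("the APM baseline is exact on noise-free single-domain data", {
  g <- generateDataset(generatorConfig(n_proteins = 25, n_domains = 6,
                                       n_pairs = 40, zero_pair_count = 0,
                                       domains_per_protein = c(1, 1),
                                       ddi_density = 1, noise_sd = 0,
                                       seed = 31))
  rep <- runProtocol(g$dataset, modelKind = "apm_baseline", seed = 5)
  expect_lt(reportSummary(rep)$meanTestRMSE, 1e-9)
  expect_lt(reportSummary(rep)$meanTrainRMSE, 1e-9)
})

test_that("default sigma grids follow the protocol conventions", {
  d <- smallDataset(23)
  # RVM with the scalar APM feature uses the coarse large-bandwidth grid
  rep <- runProtocol(d, mapping = "apm", modelKind = "rvm", seed = 2,
                     sigmaGrid = seq(3, 9, by = 1))
  expect_true(all(reportResults(rep)$sigma >= 3))
  expect_identical(ppistrength:::defaultSigmaGrid("rvm", "apm"),
                   seq(3, 9, by = 0.1))
  expect_identical(ppistrength:::defaultSigmaGrid("svr", "apm"),
                   seq(0.01, 0.1, by = 0.01))
  expect_identical(ppistrength:::defaultSigmaGrid("rvm", "dn"),
                   seq(0.01, 0.1, by = 0.01))
})
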