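test_that("domain pair enumeration collapses duplicates and allows self pairs", {
  ps <- tinyProteins()
  # {D1,D2} x {D2,D3,D4} -> 6 unordered pairs, the classic worked example
  dp <- enumerateDomainPairs("pA", "pB", ps)
  got <- sort(paste(dp$domain_a, dp$domain_b))
  expect_identical(got, sort(c("D1 D2", "D1 D3", "D1 D4",
                               "D2 D2", "D2 D3", "D2 D4")))
  # a domain-free protein enumerates nothing
  expect_identical(nrow(enumerateDomainPairs("pD", "pA", ps)), 0L)
  # same single domain on both sides -> one self pair
  dp2 <- enumerateDomainPairs("pC", "pC", ps)
  expect_identical(dp2, data.frame(domain_a = "D1", domain_b = "D1",
                                   stringsAsFactors = FALSE))
})

test_that("ASSOC computes interacting fractions and demands binary data", {
  ps <- tinyProteins()
  # three pairs support (D1,D2) [pA-pB via D1xD2; pA-pC via D2xD1;
  # pB-pC via D2xD1]; two of them interact
  d <- makePairDataset(ps, data.frame(
    protein_a = c("pA", "pA", "pB"),
    protein_b = c("pB", "pC", "pC"),
    strength = c(1, 1, 0)))
  tb <- scoreTable(assocScores(d))
  row <- tb[tb$domain_a == "D1" & tb$domain_b == "D2", ]
  expect_equal(row$score, 2 / 3)
  expect_identical(row$support, 3L)
  # all supporting pairs interacting -> 1; unsupported pairs absent
  expect_equal(tb$score[tb$domain_a == "D1" & tb$domain_b == "D1"], 1)
  expect_false(any(tb$domain_a == "D3" & tb$domain_b == "D3"))
  d2 <- makePairDataset(ps, data.frame(protein_a = "pA", protein_b = "pB",
                                       strength = 0.5))
  expect_error(assocScores(d2), "binary")
})

test_that("ASNM averages strengths and reduces to ASSOC on binary data", {
  ps <- tinyProteins()
  d <- makePairDataset(ps, data.frame(
    protein_a = c("pA", "pA"), protein_b = c("pB", "pC"),
    strength = c(0.2, 0.4)))
  tb <- scoreTable(asnmScores(d))
  expect_equal(tb$score[tb$domain_a == "D1" & tb$domain_b == "D2"], 0.3)
  # single supporting pair: the strength itself
  d1 <- makePairDataset(ps, data.frame(protein_a = "pB", protein_b = "pC",
                                       strength = 0.7))
  expect_true(all(scoreTable(asnmScores(d1))$score == 0.7))
  for (s in 1:5) {
    db <- randomToyDataset(s, binary = TRUE)
    expect_identical(scoreTable(asnmScores(db)), scoreTable(assocScores(db)))
  }
})

test_that("APM applies the per-domain-pair exponent", {
  ps <- tinyProteins()
  # pB-pC: |P_B| = 3 instances, |P_C| = 2 instances
  d <- makePairDataset(ps, data.frame(protein_a = "pB", protein_b = "pC",
                                      strength = 0.75))
  tb <- scoreTable(apmScores(d))
  expect_equal(tb$score, rep(1 - 0.25^(1 / 6), nrow(tb)), tolerance = 1e-12)
  # distinct-domain variant: |P_C| counts D1 once
  tb2 <- scoreTable(apmScores(d, distinctDomains = TRUE))
  expect_equal(tb2$score, rep(1 - 0.25^(1 / 3), nrow(tb2)), tolerance = 1e-12)
  # exponent 1 reduces to rho; zero strength maps to zero
  d1 <- makePairDataset(ps, data.frame(protein_a = "pA", protein_b = "pA",
                                       strength = 0.5))
  # self pair of pA: |P_A| = 2 -> exponent 1/4
  expect_equal(scoreTable(apmScores(d1))$score[1], 1 - 0.5^(1 / 4))
  d0 <- makePairDataset(ps, data.frame(protein_a = "pB", protein_b = "pC",
                                       strength = 0))
  expect_true(all(scoreTable(apmScores(d0))$score == 0))
})

test_that("the three estimators agree on which domain pairs have support", {
  for (s in 1:5) {
    d <- randomToyDataset(s)
    db <- randomToyDataset(s, binary = TRUE)
    keyOf <- function(t) paste(scoreTable(t)$domain_a, scoreTable(t)$domain_b)
    expect_identical(keyOf(asnmScores(d)), keyOf(apmScores(d)))
    expect_identical(keyOf(asnmScores(db)), keyOf(assocScores(db)))
    # supports too
    expect_identical(scoreTable(asnmScores(d))$support,
                     scoreTable(apmScores(d))$support)
  }
})

test_that("APM scores never exceed ASNM scores", {
  for (s in 1:8) {
    d <- randomToyDataset(s, n_pairs = 15)
    expect_true(all(scoreTable(apmScores(d))$score <=
                    scoreTable(asnmScores(d))$score + 1e-12))
  }
})

test_that("noisy-OR prediction combines instance pairs with multiplicity", {
  ps <- tinyProteins()
  mkTable <- function(keys, scores) {
    parts <- strsplit(keys, " ")
    new("DDIScoreTable",
        table = data.frame(domain_a = vapply(parts, `[`, "", 1),
                           domain_b = vapply(parts, `[`, "", 2),
                           score = scores,
                           support = 1L, stringsAsFactors = FALSE),
        method = "ASNM")
  }
  pr <- data.frame(protein_a = "pA", protein_b = "pC")
  # pA = {D1, D2}, pC = {D1, D1}: instance pairs D1D1 x2, D1D2 x2
  t0 <- mkTable(c("D1 D1", "D1 D2"), c(0, 0))
  expect_equal(predictStrength(pr, t0, ps), 0)
  t1 <- mkTable(c("D1 D1", "D1 D2"), c(1, 0))
  expect_equal(predictStrength(pr, t1, ps), 1)
  th <- mkTable(c("D1 D1", "D1 D2"), c(0.5, 0))
  # two D1xD1 instance factors: 1 - 0.5^2
  expect_equal(predictStrength(pr, th, ps), 0.75)
  tmiss <- mkTable("D1 D1", 0.5)
  expect_error(predictStrength(pr, tmiss, ps), "D1|D2", fixed = TRUE)
})

test_that("prediction is monotone in every table entry", {
  for (s in 1:4) {
    d <- randomToyDataset(s)
    tb <- asnmScores(d)
    base <- predictStrength(d, tb)
    t2 <- tb
    for (r in seq_len(nrow(scoreTable(tb)))) {
      t2@table$score[r] <- min(1, tb@table$score[r] + 0.1)
      expect_true(all(predictStrength(d, t2) >= base - 1e-12))
      t2@table$score[r] <- tb@table$score[r]
    }
  }
})

test_that("coverage filter partitions by complete score coverage", {
  ps <- tinyProteins()
  train <- makePairDataset(ps, data.frame(protein_a = "pA", protein_b = "pC",
                                          strength = 0.4))
  tb <- apmScores(train)  # scores only D1D1, D1D2
  test <- data.frame(protein_a = c("pA", "pA", "pA"),
                     protein_b = c("pC", "pB", "pD"),
                     stringsAsFactors = FALSE)
  cv <- coverageFilter(test, tb, ps)
  # pA-pC fully covered; pA-pB needs D2D2 etc (unscored); pA-pD empty
  expect_identical(cv$kept$protein_b, "pC")
  expect_identical(sort(cv$dropped$protein_b), c("pB", "pD"))
  expect_identical(nrow(cv$kept) + nrow(cv$dropped), nrow(test))
})

test_that("scores and combined strengths match the brute-force oracle", {
  for (s in 1:4) {
    d <- randomToyDataset(s, n_prot = 8, n_pairs = 10)
    for (m in c("asnm", "apm")) {
      got <- scoreTable(switch(m, asnm = asnmScores(d), apm = apmScores(d)))
      want <- oracleScores(d, m)
      expect_identical(nrow(got), length(want))
      for (r in seq_len(nrow(got))) {
        key <- paste(got$domain_a[r], got$domain_b[r], sep = "|")
        expect_equal(got$score[r], unname(want[[key]]["score"]),
                     tolerance = 1e-9)
        expect_identical(got$support[r], as.integer(want[[key]]["support"]))
      }
    }
    tb <- asnmScores(d)
    sc <- as.list(scoreTable(tb)$score)
    names(sc) <- paste(scoreTable(tb)$domain_a, scoreTable(tb)$domain_b,
                       sep = "|")
    cov <- coverageFilter(d, tb)
    pred <- predictStrength(cov$kept, tb, d@proteins)
    for (i in seq_len(nrow(cov$kept)))
      expect_equal(pred[i],
                   oraclePredict(d@proteins, cov$kept$protein_a[i],
                                 cov$kept$protein_b[i], sc),
                   tolerance = 1e-9)
  }
})
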