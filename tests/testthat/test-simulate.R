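test_that("noise-free generation emits exactly the planted clean strengths", {
  g <- generateDataset(generatorConfig(n_proteins = 20, n_domains = 8,
                                       n_pairs = 30, zero_pair_count = 0,
                                       noise_sd = 0, seed = 51))
  pr <- pairTable(g$dataset)
  cl <- g$truth$clean
  key <- paste(cl$protein_a, cl$protein_b)
  expect_identical(pr$strength,
                   cl$clean[match(paste(pr$protein_a, pr$protein_b), key)])
})

test_that("clean strengths satisfy the noisy-OR model against planted truth", {
  g <- generateDataset(generatorConfig(n_proteins = 20, n_domains = 8,
                                       n_pairs = 30, zero_pair_count = 5,
                                       noise_sd = 0.05, seed = 52))
  truthTable <- new("DDIScoreTable",
                    table = data.frame(domain_a = g$truth$ddi$domain_a,
                                       domain_b = g$truth$ddi$domain_b,
                                       score = g$truth$ddi$prob,
                                       support = 1L, stringsAsFactors = FALSE),
                    method = "APM")
  # complete the table with the zero-probability pairs for lookup
  u <- domainUniverse(g$dataset)
  all_dd <- expand.grid(a = u, b = u, stringsAsFactors = FALSE)
  all_dd <- all_dd[all_dd$a <= all_dd$b, ]
  key <- paste(all_dd$a, all_dd$b)
  have <- paste(g$truth$ddi$domain_a, g$truth$ddi$domain_b)
  miss <- all_dd[!key %in% have, ]
  truthTable@table <- rbind(truthTable@table,
                            data.frame(domain_a = miss$a, domain_b = miss$b,
                                       score = 0, support = 1L))
  pred <- predictStrength(g$truth$clean[, c("protein_a", "protein_b")],
                          truthTable, g$dataset@proteins)
  expect_equal(pred, g$truth$clean$clean, tolerance = 1e-12)
})

test_that("generation is byte-identical under the same seed", {
  cfg <- generatorConfig(n_proteins = 15, n_domains = 6, n_pairs = 18,
                         zero_pair_count = 3, seed = 53)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeGeneratedDataset(generateDataset(cfg), d1)
  writeGeneratedDataset(generateDataset(cfg), d2)
  for (f in c("seq.fa", "dom.tsv", "pairs.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # different seed differs
  cfg2 <- generatorConfig(n_proteins = 15, n_domains = 6, n_pairs = 18,
                          zero_pair_count = 3, seed = 54)
  d3 <- withr::local_tempdir()
  writeGeneratedDataset(generateDataset(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "pairs.tsv")),
                         readLines(file.path(d3, "pairs.tsv"))))
})

test_that("every universe domain is instantiated and structure is exercised", {
  g <- generateDataset(generatorConfig(n_proteins = 40, n_domains = 30,
                                       n_pairs = 50, seed = 55))
  d <- g$dataset
  expect_identical(length(domainUniverse(d)), 30L)
  # multiplicity path: at least one protein repeats a domain
  inst <- split(domainTable(d)$domain_id, domainTable(d)$protein_id)
  expect_true(any(vapply(inst, function(v) anyDuplicated(v) > 0, TRUE)))
  # ambiguity codes appear and land in domain regions or linkers
  expect_true(any(grepl("[XBZUOJ]", proteinSequences(d))))
  # all strengths in range; zero pairs present at strength exactly 0
  expect_true(all(strengths(d) >= 0 & strengths(d) <= 1))
  expect_gte(sum(strengths(d) == 0), 10L)
})

test_that("raising a planted probability never lowers a clean strength", {
  g <- generateDataset(generatorConfig(n_proteins = 15, n_domains = 5,
                                       n_pairs = 20, zero_pair_count = 0,
                                       ddi_density = 0.5, noise_sd = 0,
                                       seed = 56))
  u <- domainUniverse(g$dataset)
  mkTable <- function(ddi) {
    all_dd <- expand.grid(a = u, b = u, stringsAsFactors = FALSE)
    all_dd <- all_dd[all_dd$a <= all_dd$b, ]
    key <- paste(all_dd$a, all_dd$b)
    sc <- setNames(rep(0, length(key)), key)
    sc[paste(ddi$domain_a, ddi$domain_b)] <- ddi$prob
    new("DDIScoreTable",
        table = data.frame(domain_a = all_dd$a, domain_b = all_dd$b,
                           score = unname(sc), support = 1L,
                           stringsAsFactors = FALSE),
        method = "APM")
  }
  base <- predictStrength(pairTable(g$dataset), mkTable(g$truth$ddi),
                          g$dataset@proteins)
  for (r in seq_len(min(5, nrow(g$truth$ddi)))) {
    ddi2 <- g$truth$ddi
    ddi2$prob[r] <- min(1, ddi2$prob[r] + 0.2)
    up <- predictStrength(pairTable(g$dataset), mkTable(ddi2),
                          g$dataset@proteins)
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("the benchmark-shape configuration matches its published shape", {
  cfg <- paperShapeConfig()
  expect_identical(cfg$n_proteins, 758L)
  expect_identical(cfg$n_domains, 327L)
  expect_identical(cfg$n_pairs, 1387L)
  expect_identical(cfg$zero_pair_count, 100L)
})

test_that("invalid configurations are rejected", {
  expect_error(generatorConfig(n_proteins = 0))
  expect_error(generatorConfig(ddi_density = 1.5))
  expect_error(generatorConfig(noise_sd = -1))
  # universe larger than total instance capacity
  cfg <- generatorConfig(n_proteins = 3, n_domains = 50,
                         domains_per_protein = c(1, 2), n_pairs = 3)
  expect_error(generateDataset(cfg), "universe")
})
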