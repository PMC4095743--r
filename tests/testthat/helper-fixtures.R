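# In-code fixtures: everything is generated programmatically.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randSeq <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# a small hand-wired protein set used across IO and association tests:
#   pA: D1 at 1-4, D2 at 11-18
#   pB: D2 at 3-10, D3 at 21-28, D4 at 31-38
#   pC: D1 at 1-4 twice (multiplicity 2)
#   pD: no domains
tinyProteins <- function() {
  seqs <- c(pA = "ACDEFGHIKLMNPQRSTVWY",
            pB = "MNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKL",
            pC = "ACDEACDEACDEACDEACDE",
            pD = "WYWYWYWYWY")
  dm <- data.frame(
    protein_id = c("pA", "pA", "pB", "pB", "pB", "pC", "pC"),
    domain_id  = c("D1", "D2", "D2", "D3", "D4", "D1", "D1"),
    start      = c(1L, 11L, 3L, 21L, 31L, 1L, 9L),
    end        = c(4L, 18L, 10L, 28L, 38L, 4L, 12L),
    stringsAsFactors = FALSE)
  new("ProteinSet", sequences = seqs, domains = dm)
}

# random small dataset built directly (independent of the generator):
# each protein gets 1-3 non-overlapping domain instances from a small
# universe; strengths are uniform (or binary on request)
randomToyDataset <- function(seed, n_prot = 10, n_dom = 6, n_pairs = 12,
                             binary = FALSE) {
  withr::with_seed(seed, {
    ids <- sprintf("q%02d", seq_len(n_prot))
    doms <- sprintf("E%d", seq_len(n_dom))
    seqs <- vapply(ids, function(i) randSeq(60), "")
    rows <- list()
    for (p in ids) {
      k <- sample.int(3, 1)
      for (j in seq_len(k)) {
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = p, domain_id = sample(doms, 1),
          start = (j - 1L) * 15L + 1L, end = (j - 1L) * 15L + 10L,
          stringsAsFactors = FALSE)
      }
    }
    dm <- do.call(rbind, rows)
    dm <- dm[order(dm$protein_id, dm$start), ]
    rownames(dm) <- NULL
    ps <- new("ProteinSet", sequences = seqs, domains = dm)
    cmb <- t(combn(ids, 2))
    take <- sample.int(nrow(cmb), n_pairs)
    s <- if (binary) sample(0:1, n_pairs, replace = TRUE) else runif(n_pairs)
    makePairDataset(ps, data.frame(protein_a = cmb[take, 1],
                                   protein_b = cmb[take, 2],
                                   strength = s, stringsAsFactors = FALSE))
  })
}
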