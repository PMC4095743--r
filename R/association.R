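# Association-style estimators of domain-domain interaction (DDI)
# probabilities from observed protein-pair strengths, and the noisy-OR
# combiner mapping DDI scores back to pair strengths.
#
# The underlying generative model: two proteins interact iff at least one
# pair of their domains interacts, hence
#   Pr(P_ij = 1) = 1 - prod_{Dm in Pi, Dn in Pj} (1 - Pr(Dmn = 1)).

# per-protein instance lists (domain ids in start order, multiplicity kept)
instanceList <- function(proteins) {
  dm <- proteins@domains
  out <- split(dm$domain_id, dm$protein_id)
  missing <- setdiff(names(proteins@sequences), names(out))
  if (length(missing)) {
    out[missing] <- list(character(0))
  }
  out
}

#' Enumerate the unordered domain pairs of a protein pair
#'
#' Returns the set of distinct unordered domain-id pairs \{Dm, Dn\} with
#' Dm a domain of the first protein and Dn a domain of the second.
#' Duplicates collapse; (D, D) is a legal pair. The classic example: a
#' protein with domains \{D1, D2\} against one with \{D2, D3, D4\} yields
#' the six pairs (D1,D2), (D1,D3), (D1,D4), (D2,D2), (D2,D3), (D2,D4).
#'
#' @param proteinA,proteinB protein ids.
#' @param proteins a [ProteinSet-class] or [PairDataset-class].
#' @return data.frame with columns domain_a, domain_b (sorted within row);
#'   zero rows if either protein has no domains.
#' @export
enumerateDomainPairs <- function(proteinA, proteinB, proteins) {
  if (is(proteins, "PairDataset")) proteins <- proteins@proteins
  da <- unique(domainInstances(proteins, proteinA))
  db <- unique(domainInstances(proteins, proteinB))
  if (length(da) == 0 || length(db) == 0)
    return(data.frame(domain_a = character(0), domain_b = character(0),
                      stringsAsFactors = FALSE))
  g <- expand.grid(a = da, b = db, stringsAsFactors = FALSE)
  key_a <- pmin(g$a, g$b); key_b <- pmax(g$a, g$b)
  keep <- !duplicated(paste(key_a, key_b, sep = "|"))
  data.frame(domain_a = key_a[keep], domain_b = key_b[keep],
             stringsAsFactors = FALSE)
}

# shared support machinery: for every pair of the dataset, its enumerated
# domain-pair keys; returns long vectors (pair index, key)
supportLong <- function(dataset) {
  inst <- instanceList(dataset@proteins)
  pr <- dataset@pairs
  keys <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    da <- unique(inst[[pr$protein_a[i]]])
    db <- unique(inst[[pr$protein_b[i]]])
    if (length(da) == 0 || length(db) == 0) next
    a <- rep(da, times = length(db))
    b <- rep(db, each = length(da))
    k <- unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
    keys[[i]] <- k
  }
  data.frame(pair = rep(seq_len(nrow(pr)), lengths(keys)),
             key = unlist(keys), stringsAsFactors = FALSE)
}

scoresFromContrib <- function(long, contrib, method) {
  v <- contrib[long$pair]
  s <- rowsum(v, long$key)
  n <- rowsum(rep(1L, nrow(long)), long$key)
  key <- rownames(s)
  parts <- strsplit(key, "|", fixed = TRUE)
  tb <- data.frame(domain_a = vapply(parts, `[`, "", 1),
                   domain_b = vapply(parts, `[`, "", 2),
                   score = as.numeric(s / n),
                   support = as.integer(n),
                   stringsAsFactors = FALSE)
  tb <- tb[order(tb$domain_a, tb$domain_b), , drop = FALSE]
  rownames(tb) <- NULL
  # guard against tiny negative round-off
  tb$score <- pmin(pmax(tb$score, 0), 1)
  new("DDIScoreTable", table = tb, method = method)
}

#' ASSOC: association scores from binary interaction data
#'
#' For every unordered domain pair with at least one supporting protein
#' pair, the score is the fraction of supporting pairs that interact:
#' the number of interacting pairs containing the two domains (one on
#' each protein, either orientation) over the total number of pairs
#' containing them. Requires binary strengths.
#'
#' @param dataset a [PairDataset-class] with strengths in \{0, 1\}.
#' @return a [DDIScoreTable-class] with method "ASSOC".
#' @export
assocScores <- function(dataset) {
  s <- dataset@pairs$strength
  if (any(s != 0 & s != 1))
    stop("ASSOC requires binary strengths (0/1); use asnmScores for real-valued data")
  scoresFromContrib(supportLong(dataset), s, "ASSOC")
}

#' ASNM: association scores for numerical interaction data
#'
#' The score of a domain pair is the mean interaction strength over all
#' supporting protein pairs. On binary strengths this reduces exactly to
#' [assocScores()].
#'
#' @param dataset a [PairDataset-class] with strengths in [0, 1].
#' @return a [DDIScoreTable-class] with method "ASNM".
#' @export
asnmScores <- function(dataset) {
  scoresFromContrib(supportLong(dataset), dataset@pairs$strength, "ASNM")
}

#' APM: association probabilistic method scores
#'
#' Refines ASNM by converting each pair strength into a per-domain-pair
#' probability before averaging: assuming all domain pairs of a protein
#' pair contribute equally under the noisy-OR model, a pair with strength
#' rho and domain counts |Pi|, |Pj| contributes
#' 1 - (1 - rho)^(1 / (|Pi| |Pj|)). The score is the mean contribution
#' over supporting pairs.
#'
#' @param dataset a [PairDataset-class] with strengths in [0, 1].
#' @param distinctDomains if TRUE, |Pi| counts distinct domain ids; by
#'   default it counts domain instances (multiset cardinality), matching
#'   the multiplicity-aware domain-count feature.
#' @return a [DDIScoreTable-class] with method "APM".
#' @export
apmScores <- function(dataset, distinctDomains = FALSE) {
  inst <- instanceList(dataset@proteins)
  sizes <- if (distinctDomains) {
    vapply(inst, function(v) length(unique(v)), 0L)
  } else {
    lengths(inst)
  }
  pr <- dataset@pairs
  ni <- sizes[pr$protein_a]; nj <- sizes[pr$protein_b]
  # a domain-free protein yields no enumerable domain pair, so its pairs
  # support nothing; neutralise their (undefined) exponent instead of
  # letting 1/0 propagate
  bad <- ni == 0 | nj == 0
  ni[bad] <- 1L; nj[bad] <- 1L
  contrib <- -expm1(log1p(-pr$strength) / (as.numeric(ni) * as.numeric(nj)))
  scoresFromContrib(supportLong(dataset), contrib, "APM")
}

scoreLookup <- function(table) {
  v <- table@table$score
  names(v) <- paste(table@table$domain_a, table@table$domain_b, sep = "|")
  v
}

#' Predict pair strengths by noisy-OR combination of DDI scores
#'
#' For each protein pair, combines the DDI scores of all domain
#' \emph{instance} pairs (a domain occurring twice contributes two
#' factors): predicted strength
#' = 1 - prod (1 - score(Dm, Dn)). The product is accumulated in log1p
#' space, so factors arbitrarily close to 0 do not underflow. Every
#' enumerated domain pair must be present in the table; missing keys are
#' an error (use [coverageFilter()] first).
#'
#' @param pairs data.frame with columns protein_a, protein_b (a
#'   [PairDataset-class] is also accepted, its pair table is used).
#' @param table a [DDIScoreTable-class].
#' @param proteins a [ProteinSet-class] (defaulted from \code{pairs} when
#'   it is a dataset).
#' @return numeric vector of predicted strengths in [0, 1].
#' @export
predictStrength <- function(pairs, table, proteins = NULL) {
  if (is(pairs, "PairDataset")) {
    if (is.null(proteins)) proteins <- pairs@proteins
    pairs <- pairs@pairs
  }
  stopifnot(is(proteins, "ProteinSet"), is(table, "DDIScoreTable"))
  lk <- scoreLookup(table)
  inst <- instanceList(proteins)
  n <- nrow(pairs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- inst[[pairs$protein_a[i]]]
    b <- inst[[pairs$protein_b[i]]]
    if (length(a) == 0 || length(b) == 0) { out[i] <- 0; next }
    ka <- rep(a, times = length(b)); kb <- rep(b, each = length(a))
    key <- paste(pmin(ka, kb), pmax(ka, kb), sep = "|")
    s <- lk[key]
    if (anyNA(s))
      stop("no DDI score for domain pair(s): ",
           paste(unique(key[is.na(s)]), collapse = ", "),
           " (pair ", pairs$protein_a[i], " - ", pairs$protein_b[i], ")")
    out[i] <- -expm1(sum(log1p(-s)))
  }
  pmin(pmax(out, 0), 1)
}

#' Split test pairs by DDI-score coverage
#'
#' A pair is kept iff every one of its enumerated domain pairs has a
#' score in the table (built from a disjoint training split), so the
#' noisy-OR prediction is fully determined by training evidence. Pairs
#' with no enumerable domain pair (a domain-free protein) are dropped.
#'
#' @param pairs data.frame with columns protein_a, protein_b, or a
#'   [PairDataset-class].
#' @param table a [DDIScoreTable-class].
#' @param proteins a [ProteinSet-class] (defaulted from a dataset).
#' @return list with data.frames \code{kept} and \code{dropped}; the two
#'   partition the input exactly.
#' @export
coverageFilter <- function(pairs, table, proteins = NULL) {
  if (is(pairs, "PairDataset")) {
    if (is.null(proteins)) proteins <- pairs@proteins
    pairs <- pairs@pairs
  }
  lk <- scoreLookup(table)
  inst <- instanceList(proteins)
  n <- nrow(pairs)
  covered <- logical(n)
  for (i in seq_len(n)) {
    a <- unique(inst[[pairs$protein_a[i]]])
    b <- unique(inst[[pairs$protein_b[i]]])
    if (length(a) == 0 || length(b) == 0) { covered[i] <- FALSE; next }
    ka <- rep(a, times = length(b)); kb <- rep(b, each = length(a))
    key <- paste(pmin(ka, kb), pmax(ka, kb), sep = "|")
    covered[i] <- all(key %in% names(lk))
  }
  list(kept = pairs[covered, , drop = FALSE],
       dropped = pairs[!covered, , drop = FALSE])
}
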