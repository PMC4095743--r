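# Feature space mappings from a protein pair to a numeric vector:
#   DN  - domain multiplicities, dimension 2T
#   SPD - k-spectrum counts over the domain-restricted sequence, 2 * 21^k
#   APM - the scalar noisy-OR combination of APM domain-pair scores
# Pairs are canonically ordered (lexicographic by protein id) before
# mapping, so swapping the two proteins yields the same vector.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 21-letter amino-acid alphabet
#'
#' The 20 standard amino acids plus a single catch-all symbol
#' (\code{"x"}) onto which every ambiguity or non-standard code (B, Z, J,
#' X, U, O, ...) is mapped. SPD features are indexed over words from this
#' alphabet, so their dimension is 21^k per protein.
#'
#' @return character vector of length 21 (fixed order; the catch-all is
#'   last).
#' @export
alphabet21 <- function() c(.AA20, "x")

# map an amino-acid string to integer codes 1..21 (21 = catch-all)
.alphaCodes <- local({
  codes <- rep(21L, 128L)
  codes[utf8ToInt(paste(.AA20, collapse = "")) + 1L] <- seq_len(20L)
  codes
})

aaCodes <- function(s) {
  if (nchar(s) == 0) return(integer(0))
  raw <- utf8ToInt(toupper(s))
  raw[raw > 127L] <- 1L  # any non-ASCII byte is "other"
  .alphaCodes[raw + 1L]
}

#' All k-mers over the 21-letter alphabet
#' @param k word length.
#' @return character vector of length 21^k in the canonical index order
#'   used by [kmerCounts()].
#' @export
kmerNames <- function(k) {
  ab <- alphabet21()
  out <- ab
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, ab, paste0)))
  out
}

#' Count overlapping k-mers of a string over the 21-letter alphabet
#'
#' Entry t is the number of (overlapping) occurrences of k-mer t in the
#' alphabet-mapped string; the total mass is max(0, nchar(s) - k + 1).
#'
#' @param s an amino-acid string.
#' @param k word length (>= 1).
#' @return numeric vector of length 21^k, named by [kmerNames()] for
#'   k <= 3.
#' @export
kmerCounts <- function(s, k) {
  stopifnot(k >= 1)
  dim <- 21^k
  cnt <- numeric(dim)
  code <- aaCodes(s)
  n <- length(code)
  if (n >= k) {
    idx <- code[seq_len(n - k + 1L)]
    if (k > 1) for (j in 2:k) {
      idx <- (idx - 1L) * 21L + code[j:(n - k + j)]
    }
    tab <- tabulate(idx, nbins = dim)
    cnt <- as.numeric(tab)
  }
  if (k <= 3) names(cnt) <- kmerNames(k)
  cnt
}

#' Restrict a protein sequence to its domain regions
#'
#' Extracts the subsequence of every domain instance and concatenates
#' them in order of appearance. Overlapping regions are extracted
#' independently (shared residues appear once per instance). Proteins
#' without domains yield the empty string.
#'
#' @param proteins a [ProteinSet-class] or [PairDataset-class].
#' @param ids protein ids (default: all).
#' @return named character vector of restricted sequences.
#' @export
restrictToDomains <- function(proteins, ids = NULL) {
  if (is(proteins, "PairDataset")) proteins <- proteins@proteins
  if (is.null(ids)) ids <- names(proteins@sequences)
  dm <- proteins@domains
  out <- vapply(ids, function(p) {
    rows <- dm[dm$protein_id == p, , drop = FALSE]
    if (nrow(rows) == 0) return("")
    paste(substring(proteins@sequences[[p]], rows$start, rows$end),
          collapse = "")
  }, "")
  names(out) <- ids
  out
}

canonicalPairs <- function(pairs) {
  if (is(pairs, "PairDataset")) pairs <- pairs@pairs
  a <- pairs$protein_a; b <- pairs$protein_b
  swap <- a > b
  data.frame(protein_a = ifelse(swap, b, a), protein_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' DN: domain-count feature vectors
#'
#' For a canonically ordered pair (Pi, Pj) and domain universe of size T,
#' the first T entries are the multiplicities M(Dm, Pi) of every universe
#' domain in Pi, the next T entries those of Pj; all other entries are 0.
#' Dimension 2T.
#'
#' @param dataset a [PairDataset-class] (fixes the domain universe).
#' @param pairs data.frame of pairs to map (default: the dataset's own).
#' @return a [FeatureMatrix-class] with mapping "DN".
#' @export
dnFeatures <- function(dataset, pairs = NULL) {
  if (is.null(pairs)) pairs <- dataset@pairs
  pairs <- canonicalPairs(pairs)
  universe <- dataset@domainUniverse
  T <- length(universe)
  inst <- instanceList(dataset@proteins)
  counts <- function(p) {
    v <- inst[[p]]
    if (is.null(v)) stop("unknown protein id: ", p)
    bad <- setdiff(v, universe)
    if (length(bad))
      stop("domain id(s) outside universe: ", paste(bad, collapse = ", "))
    tabulate(match(v, universe), nbins = T)
  }
  uniq <- unique(c(pairs$protein_a, pairs$protein_b))
  cmap <- lapply(uniq, counts)
  names(cmap) <- uniq
  n <- nrow(pairs)
  rows <- matrix(0, n, 2L * T)
  for (i in seq_len(n)) {
    rows[i, ] <- c(cmap[[pairs$protein_a[i]]], cmap[[pairs$protein_b[i]]])
  }
  new("FeatureMatrix",
      matrix = methods::as(methods::as(Matrix::Matrix(rows, sparse = TRUE),
                                       "CsparseMatrix"), "generalMatrix"),
      mapping = "DN", k = NA_real_,
      pairIds = pairKey(pairs$protein_a, pairs$protein_b))
}

#' SPD: domain-restricted spectrum feature vectors
#'
#' For a canonically ordered pair (Pi, Pj), the vector is the
#' concatenation of the k-mer counts of the two domain-restricted
#' sequences ([restrictToDomains()]): dimension 2 * 21^k. Words spanning
#' the junction between concatenated domain subsequences are counted,
#' since the spectrum is taken over the concatenated string.
#'
#' @param dataset a [PairDataset-class].
#' @param k spectrum word length (>= 1).
#' @param pairs data.frame of pairs to map (default: the dataset's own).
#' @return a [FeatureMatrix-class] with mapping "SPD".
#' @export
spdFeatures <- function(dataset, k = 1, pairs = NULL) {
  stopifnot(k >= 1)
  if (is.null(pairs)) pairs <- dataset@pairs
  pairs <- canonicalPairs(pairs)
  uniq <- unique(c(pairs$protein_a, pairs$protein_b))
  restricted <- restrictToDomains(dataset, uniq)
  spec <- lapply(restricted, kmerCounts, k = k)
  dim1 <- 21^k
  n <- nrow(pairs)
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  for (i in seq_len(n)) {
    va <- spec[[pairs$protein_a[i]]]
    vb <- spec[[pairs$protein_b[i]]]
    nza <- which(va != 0); nzb <- which(vb != 0)
    jj[[i]] <- c(nza, dim1 + nzb)
    xx[[i]] <- c(va[nza], vb[nzb])
    ii[[i]] <- rep(i, length(nza) + length(nzb))
  }
  m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, 2L * dim1))
  new("FeatureMatrix", matrix = m, mapping = "SPD", k = as.numeric(k),
      pairIds = pairKey(pairs$protein_a, pairs$protein_b))
}

#' APM-score feature vectors
#'
#' The single feature entry of a pair is its noisy-OR combination of APM
#' domain-pair scores ([predictStrength()]); every pair must pass
#' [coverageFilter()] against the table first.
#'
#' @param dataset a [PairDataset-class].
#' @param table a [DDIScoreTable-class], typically from [apmScores()] on
#'   a training split.
#' @param pairs data.frame of pairs to map (default: the dataset's own).
#' @return a [FeatureMatrix-class] with mapping "APM", dimension 1.
#' @export
apmFeatures <- function(dataset, table, pairs = NULL) {
  if (is.null(pairs)) pairs <- dataset@pairs
  pairs <- canonicalPairs(pairs)
  v <- predictStrength(pairs, table, dataset@proteins)
  m <- Matrix::Matrix(matrix(v, ncol = 1), sparse = TRUE)
  new("FeatureMatrix",
      matrix = methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix"),
      mapping = "APM", k = NA_real_,
      pairIds = pairKey(pairs$protein_a, pairs$protein_b))
}

#' @rdname accessors
#' @export
setMethod("as.matrix", "FeatureMatrix", function(x, ...) as.matrix(x@matrix))
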