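# Pair-level dataset assembly: strength normalisation, canonicalisation,
# zero-pair augmentation.

#' Normalise pair weights to interaction strengths
#'
#' Divides every weight by the maximum weight, so strengths lie in
#' [0, 1] and the maximum is exactly 1. This is how raw interactome edge
#' weights (e.g. interactome edge reliability scores) become strength labels.
#'
#' @param weights data.frame with columns protein_a, protein_b, weight
#'   (from [readPairWeights()]).
#' @return data.frame with columns protein_a, protein_b, strength.
#' @export
normalizeStrengths <- function(weights) {
  if (nrow(weights) == 0) stop("no weights to normalise")
  mx <- max(weights$weight)
  if (mx <= 0) stop("all weights are zero; cannot normalise")
  data.frame(protein_a = weights$protein_a, protein_b = weights$protein_b,
             strength = weights$weight / mx, stringsAsFactors = FALSE)
}

#' Assemble a PairDataset
#'
#' Canonicalises each pair to sorted id order, flags self pairs, and
#' derives the domain universe from the protein annotations.
#'
#' @param proteins a [ProteinSet-class].
#' @param pairs data.frame with columns protein_a, protein_b, strength.
#' @return a [PairDataset-class].
#' @export
makePairDataset <- function(proteins, pairs) {
  stopifnot(is(proteins, "ProteinSet"))
  a <- pairs$protein_a; b <- pairs$protein_b
  swap <- a > b
  pr <- data.frame(protein_a = ifelse(swap, b, a),
                   protein_b = ifelse(swap, a, b),
                   strength = pairs$strength,
                   stringsAsFactors = FALSE)
  pr$is_self <- pr$protein_a == pr$protein_b
  rownames(pr) <- NULL
  new("PairDataset", proteins = proteins, pairs = pr,
      domainUniverse = sort(unique(proteins@domains$domain_id)))
}

#' Add randomly sampled zero-strength pairs
#'
#' Samples \code{n} unordered protein pairs absent from the dataset,
#' uniformly without replacement among all absent pairs over the
#' dataset's protein universe, and appends them with strength 0. This
#' mirrors augmenting an interactome-derived dataset (which contains only
#' weighted, i.e. interacting, pairs) with non-interacting pairs.
#'
#' @param dataset a [PairDataset-class].
#' @param n number of zero pairs to add.
#' @param seed integer seed making the sampling reproducible.
#' @param includeSelf should self pairs be eligible? Default FALSE.
#' @return the augmented [PairDataset-class].
#' @export
addZeroPairs <- function(dataset, n, seed, includeSelf = FALSE) {
  if (n == 0) return(dataset)
  ids <- proteinIds(dataset)
  np <- length(ids)
  existing <- pairKey(dataset@pairs$protein_a, dataset@pairs$protein_b)
  total <- np * (np - 1) / 2 + if (includeSelf) np else 0
  # existing keys all lie within the universe and are distinct
  n_absent <- total - length(existing)
  if (n_absent < n)
    stop(sprintf("only %d absent pair(s) available, %d requested", n_absent, n))
  picked <- withr::with_seed(seed, samplePairIndices(ids, n, existing, includeSelf))
  add <- data.frame(protein_a = picked$a, protein_b = picked$b,
                    strength = 0, stringsAsFactors = FALSE)
  add$is_self <- add$protein_a == add$protein_b
  out <- dataset
  out@pairs <- rbind(dataset@pairs, add)
  rownames(out@pairs) <- NULL
  validObject(out)
  out
}

# rejection-sample n absent unordered pairs (uniform over absent pairs);
# falls back to full enumeration when the absent set is a small fraction.
samplePairIndices <- function(ids, n, existingKeys, includeSelf) {
  np <- length(ids)
  total <- np * (np - 1) / 2 + if (includeSelf) np else 0
  dense <- (total - length(existingKeys)) < 4 * n || total < 1e5
  if (dense) {
    cmb <- t(utils::combn(sort(ids), 2))
    if (includeSelf) cmb <- rbind(cmb, cbind(sort(ids), sort(ids)))
    keys <- pairKey(cmb[, 1], cmb[, 2])
    absent <- which(!(keys %in% existingKeys))
    take <- sample(absent, n)
    return(list(a = cmb[take, 1], b = cmb[take, 2]))
  }
  seen <- existingKeys
  out_a <- character(0); out_b <- character(0)
  while (length(out_a) < n) {
    m <- 2 * (n - length(out_a)) + 10
    i <- sample.int(np, m, replace = TRUE)
    j <- sample.int(np, m, replace = TRUE)
    if (!includeSelf) {
      keep <- i != j
      i <- i[keep]; j <- j[keep]
    }
    a <- pmin(ids[i], ids[j]); b <- pmax(ids[i], ids[j])
    key <- paste(a, b, sep = "|")
    keep <- !(key %in% seen) & !duplicated(key)
    a <- a[keep]; b <- b[keep]; key <- key[keep]
    take <- seq_len(min(length(a), n - length(out_a)))
    out_a <- c(out_a, a[take]); out_b <- c(out_b, b[take])
    seen <- c(seen, key[take])
  }
  list(a = out_a, b = out_b)
}

#' Subset the pair list of a dataset
#'
#' Returns the same proteins and domain universe with only the selected
#' pairs; used to carve training and test splits.
#'
#' @param dataset a [PairDataset-class].
#' @param idx integer indices into the pair table.
#' @return a [PairDataset-class].
#' @export
subsetPairs <- function(dataset, idx) {
  out <- dataset
  out@pairs <- dataset@pairs[idx, , drop = FALSE]
  rownames(out@pairs) <- NULL
  validObject(out)
  out
}

#' Drop pairs involving proteins without domain annotations
#'
#' Proteins without any annotated domain carry no domain evidence; their
#' pairs get all-zero DN/SPD features and cannot be scored by the
#' association methods. They are retained by default and removed only on
#' request via this helper.
#'
#' @param dataset a [PairDataset-class].
#' @return a [PairDataset-class] with only fully annotated pairs.
#' @export
dropUnannotatedPairs <- function(dataset) {
  annotated <- unique(dataset@proteins@domains$protein_id)
  keep <- dataset@pairs$protein_a %in% annotated &
    dataset@pairs$protein_b %in% annotated
  subsetPairs(dataset, which(keep))
}
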