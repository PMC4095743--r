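# Accessors and show methods for the core classes.

#' @name accessors
#' @title Accessors for ppistrength objects
#' @description Slot accessors: prefer these over direct \code{@} access.
#' @param x an object of the documented class.
#' @param protein a protein id.
#' @return the corresponding slot contents (see individual functions).
NULL

#' @rdname accessors
#' @export
proteinIds <- function(x) {
  if (is(x, "PairDataset")) x <- x@proteins
  names(x@sequences)
}

#' @rdname accessors
#' @export
proteinSequences <- function(x) {
  if (is(x, "PairDataset")) x <- x@proteins
  x@sequences
}

#' @rdname accessors
#' @export
domainTable <- function(x) {
  if (is(x, "PairDataset")) x <- x@proteins
  x@domains
}

#' @rdname accessors
#' @details \code{domainUniverse} returns the sorted distinct domain ids;
#'   its length T fixes the DN feature dimension 2T.
#' @export
domainUniverse <- function(x) {
  if (is(x, "PairDataset")) return(x@domainUniverse)
  sort(unique(x@domains$domain_id))
}

#' @rdname accessors
#' @details \code{domainInstances} returns the domain ids of one protein
#'   in order of appearance, one entry per instance (multiplicity kept).
#' @export
domainInstances <- function(x, protein) {
  if (is(x, "PairDataset")) x <- x@proteins
  dm <- x@domains
  dm$domain_id[dm$protein_id == protein]
}

#' @rdname accessors
#' @export
pairTable <- function(x) x@pairs

#' @rdname accessors
#' @export
strengths <- function(x) x@pairs$strength

#' @rdname accessors
#' @export
scoreTable <- function(x) x@table

#' @rdname accessors
#' @export
scoreMethod <- function(x) x@method

#' @rdname accessors
#' @export
featureMatrix <- function(x) x@matrix

#' @rdname accessors
#' @export
pairIds <- function(x) x@pairIds

# canonical unordered-pair key
pairKey <- function(a, b) {
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "|")
}

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet: %d proteins, %d domain instances, %d distinct domains\n",
              length(object@sequences), nrow(object@domains),
              length(unique(object@domains$domain_id))))
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf("PairDataset: %d pairs over %d proteins (T = %d domains)\n",
              nrow(object@pairs), length(object@proteins@sequences),
              length(object@domainUniverse)))
  s <- object@pairs$strength
  if (length(s))
    cat(sprintf("  strengths: %d zero, mean %.4f, max %.4f\n",
                sum(s == 0), mean(s), max(s)))
})

setMethod("show", "DDIScoreTable", function(object) {
  cat(sprintf("DDIScoreTable (%s): %d domain pairs\n",
              object@method, nrow(object@table)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s%s): %d pairs x %d features, %.1f%% nonzero\n",
              object@mapping,
              if (object@mapping == "SPD") sprintf(", k=%d", object@k) else "",
              nrow(object@matrix), ncol(object@matrix),
              100 * Matrix::nnzero(object@matrix) /
                max(1, prod(dim(object@matrix)))))
})

setMethod("show", "SVRModel", function(object) {
  cat(sprintf("SVRModel: %d support vectors, C=%g, epsilon=%g, sigma=%g\n",
              object@nSV, object@C, object@epsilon, object@kernel@sigma))
})

setMethod("show", "RVMModel", function(object) {
  cat(sprintf("RVMModel: %d relevance vectors%s, sigma=%g, beta=%.4g\n",
              object@nRV, if (object@biasIncluded) " (+bias)" else "",
              object@kernel@sigma, object@beta))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: n=%d, 3 outer x 5 inner folds, seed=%d\n",
              sum(lengths(object@outerFolds)), object@seed))
  cat(sprintf("  sigma grid: %s\n  C grid: %s\n",
              paste(object@sigmaGrid, collapse = " "),
              paste(object@CGrid, collapse = " ")))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %s + %s%s\n", object@modelKind,
              object@mapping,
              if (!is.na(object@k)) sprintf(" (k=%d)", object@k) else ""))
  print(object@summary, row.names = FALSE)
})

#' @rdname accessors
#' @export
reportResults <- function(x) x@results

#' @rdname accessors
#' @export
reportSummary <- function(x) x@summary

#' @rdname accessors
#' @export
reportPredictions <- function(x) x@predictions
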