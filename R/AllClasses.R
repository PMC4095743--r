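#' @import methods
#' @importFrom stats predict rnorm runif sd var
#' @importFrom utils head read.delim write.table
NULL

#' ProteinSet: annotated protein sequences
#'
#' Holds amino-acid sequences together with their domain annotations.
#' Each domain instance is a record (protein id, domain id, start, end)
#' with 1-based inclusive coordinates into the owning protein's sequence.
#' A protein may carry zero, one or several instances of the same domain;
#' multiplicity is meaningful throughout (domain-count features and the
#' noisy-OR combiner both count instances).
#'
#' @slot sequences named character vector of upper-cased amino-acid
#'   sequences; names are protein ids.
#' @slot domains data.frame with columns \code{protein_id},
#'   \code{domain_id}, \code{start}, \code{end}; rows are sorted by
#'   protein id then start position.
#'
#' @seealso [readDomainAnnotations()], [domainUniverse()], [domainInstances()]
#' @export
setClass("ProteinSet",
  representation(sequences = "character", domains = "data.frame"))

setValidity("ProteinSet", function(object) {
  msgs <- character()
  sq <- object@sequences
  dm <- object@domains
  if (is.null(names(sq)) || anyNA(names(sq)) || any(names(sq) == ""))
    msgs <- c(msgs, "sequences must be named by protein id")
  if (anyDuplicated(names(sq)))
    msgs <- c(msgs, "duplicate protein ids in sequences")
  need <- c("protein_id", "domain_id", "start", "end")
  if (!all(need %in% colnames(dm))) {
    msgs <- c(msgs, sprintf("domains must have columns %s",
                            paste(need, collapse = ", ")))
  } else if (nrow(dm) > 0) {
    if (!all(dm$protein_id %in% names(sq)))
      msgs <- c(msgs, "domain annotation refers to unknown protein id")
    else {
      len <- nchar(sq)[dm$protein_id]
      bad <- dm$start < 1L | dm$start > dm$end | dm$end > len
      if (any(bad))
        msgs <- c(msgs, sprintf(
          "domain region out of bounds for protein(s): %s",
          paste(unique(dm$protein_id[bad]), collapse = ", ")))
    }
    ord <- order(dm$protein_id, dm$start)
    if (!identical(ord, seq_len(nrow(dm))))
      msgs <- c(msgs, "domain rows must be sorted by protein id then start")
  }
  if (length(msgs)) msgs else TRUE
})

#' PairDataset: protein pairs with interaction strengths
#'
#' A set of unordered protein pairs, each with a real-valued interaction
#' strength in [0, 1], together with the annotated proteins they refer to.
#' Pairs are stored under canonical (lexicographically sorted) id order,
#' self pairs (homodimers) are allowed and flagged. The domain universe is
#' the sorted set of distinct domain ids occurring across the proteins; its
#' size T fixes the dimension 2T of the domain-count feature space.
#'
#' @slot proteins a [ProteinSet].
#' @slot pairs data.frame with columns \code{protein_a}, \code{protein_b}
#'   (canonical order, \code{protein_a <= protein_b}), \code{strength} in
#'   [0, 1], and logical \code{is_self}.
#' @slot domainUniverse sorted character vector of distinct domain ids.
#'
#' @seealso [makePairDataset()], [addZeroPairs()], [generateDataset()]
#' @export
setClass("PairDataset",
  representation(proteins = "ProteinSet", pairs = "data.frame",
                 domainUniverse = "character"))

setValidity("PairDataset", function(object) {
  msgs <- character()
  pr <- object@pairs
  need <- c("protein_a", "protein_b", "strength", "is_self")
  if (!all(need %in% colnames(pr)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (nrow(pr) > 0) {
    known <- names(object@proteins@sequences)
    if (!all(c(pr$protein_a, pr$protein_b) %in% known))
      msgs <- c(msgs, "pair endpoint not in protein set")
    if (any(pr$protein_a > pr$protein_b))
      msgs <- c(msgs, "pairs must be in canonical (sorted) id order")
    if (anyDuplicated(paste(pr$protein_a, pr$protein_b, sep = "\r")))
      msgs <- c(msgs, "duplicate unordered protein pair")
    if (any(pr$strength < 0 | pr$strength > 1 | is.na(pr$strength)))
      msgs <- c(msgs, "strengths must lie in [0, 1]")
  }
  u <- sort(unique(object@proteins@domains$domain_id))
  if (!identical(object@domainUniverse, u))
    msgs <- c(msgs,
      "domainUniverse must equal the sorted distinct domain ids of the proteins")
  if (length(msgs)) msgs else TRUE
})

#' DDIScoreTable: estimated domain-domain interaction probabilities
#'
#' A map from unordered domain pairs to an estimated interaction
#' probability in [0, 1], produced by one of the association-style
#' estimators (ASSOC, ASNM, APM). Only domain pairs with at least one
#' supporting protein pair are present; absence of a key means "no
#' evidence", not probability zero.
#'
#' @slot table data.frame with columns \code{domain_a}, \code{domain_b}
#'   (sorted within row), \code{score} in [0, 1], integer \code{support}
#'   (>= 1, the number of contributing protein pairs).
#' @slot method one of \code{"ASSOC"}, \code{"ASNM"}, \code{"APM"}.
#'
#' @seealso [assocScores()], [asnmScores()], [apmScores()],
#'   [predictStrength()]
#' @export
setClass("DDIScoreTable",
  representation(table = "data.frame", method = "character"))

setValidity("DDIScoreTable", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("domain_a", "domain_b", "score", "support")
  if (!all(need %in% colnames(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (!object@method %in% c("ASSOC", "ASNM", "APM"))
    msgs <- c(msgs, "method must be ASSOC, ASNM or APM")
  if (nrow(tb) > 0) {
    if (any(tb$domain_a > tb$domain_b))
      msgs <- c(msgs, "domain pairs must be sorted within row")
    if (any(tb$score < -1e-12 | tb$score > 1 + 1e-12 | is.na(tb$score)))
      msgs <- c(msgs, "scores must lie in [0, 1]")
    if (any(tb$support < 1))
      msgs <- c(msgs, "every stored key needs support >= 1")
    if (anyDuplicated(paste(tb$domain_a, tb$domain_b, sep = "\r")))
      msgs <- c(msgs, "duplicate domain pair key")
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: per-pair feature vectors
#'
#' One numeric feature vector per protein pair, stored sparsely. The
#' mapping determines the dimension: DN has 2T entries (T = domain
#' universe size), SPD with word length k has 2 * 21^k, and the scalar
#' APM-score feature has 1.
#'
#' @slot matrix a \code{dgCMatrix}; rows are pairs, columns features.
#' @slot mapping one of \code{"DN"}, \code{"SPD"}, \code{"APM"}.
#' @slot k spectrum word length (NA unless mapping is SPD).
#' @slot pairIds character vector of canonical pair keys, aligned to rows.
#'
#' @seealso [dnFeatures()], [spdFeatures()], [apmFeatures()]
#' @export
setClass("FeatureMatrix",
  representation(matrix = "Matrix", mapping = "character", k = "numeric",
                 pairIds = "character"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (!object@mapping %in% c("DN", "SPD", "APM"))
    msgs <- c(msgs, "mapping must be DN, SPD or APM")
  if (nrow(object@matrix) != length(object@pairIds))
    msgs <- c(msgs, "pairIds must align with matrix rows")
  if (object@mapping == "SPD") {
    if (is.na(object@k) || object@k < 1)
      msgs <- c(msgs, "SPD requires k >= 1")
    else if (ncol(object@matrix) != 2 * 21^object@k)
      msgs <- c(msgs, "SPD dimension must be 2 * 21^k")
  }
  if (object@mapping == "APM" && ncol(object@matrix) != 1)
    msgs <- c(msgs, "APM feature dimension must be 1")
  if (length(msgs)) msgs else TRUE
})

#' KernelSpec: Laplacian kernel specification
#'
#' The kernel used throughout: K(x, y) = exp(-sigma * ||x - y||) with the
#' Euclidean norm.
#'
#' @slot name kernel name, currently only \code{"laplacian"}.
#' @slot sigma positive bandwidth parameter.
#' @export
setClass("KernelSpec", representation(name = "character", sigma = "numeric"))

setValidity("KernelSpec", function(object) {
  if (!identical(object@name, "laplacian")) return("only the laplacian kernel is supported")
  if (length(object@sigma) != 1 || is.na(object@sigma) || object@sigma <= 0)
    return("sigma must be a single positive number")
  TRUE
})

#' Create a Laplacian kernel specification
#' @param sigma positive bandwidth; K(x, y) = exp(-sigma * ||x - y||).
#' @return a [KernelSpec-class] object.
#' @export
laplacianSpec <- function(sigma) new("KernelSpec", name = "laplacian", sigma = sigma)

#' SVRModel: fitted epsilon-insensitive support vector regressor
#'
#' Kernel SVR fitted in the dual; predictions are
#' f(x) = sum_i beta_i K(x_i, x) + b over the retained support vectors.
#'
#' @slot supportVectors matrix of retained training feature vectors.
#' @slot coefficients dual coefficients beta_i (alpha_i - alpha_i'),
#'   bounded by C in absolute value.
#' @slot bias intercept b.
#' @slot C box constraint.
#' @slot epsilon insensitivity tube half-width.
#' @slot kernel a [KernelSpec-class].
#' @slot dualObjective value of the dual objective attained at the fit.
#' @slot nSV number of support vectors (|beta| > 1e-8).
#' @seealso [svrFit()]
#' @export
setClass("SVRModel",
  representation(supportVectors = "matrix", coefficients = "numeric",
                 bias = "numeric", C = "numeric", epsilon = "numeric",
                 kernel = "KernelSpec", dualObjective = "numeric",
                 nSV = "integer"))

#' RVMModel: fitted relevance vector machine regressor
#'
#' Sparse Bayesian kernel regression fitted by evidence maximisation over
#' per-weight precisions alpha and noise precision beta. The design matrix
#' has one kernel basis per training point plus a constant bias column;
#' bases whose alpha diverges are pruned, leaving the relevance vectors.
#'
#' @slot relevanceVectors matrix of retained training feature vectors
#'   (kernel bases only, bias excluded).
#' @slot weights posterior mean weights, aligned with (bias if retained,
#'   then relevance vectors).
#' @slot alpha retained per-weight precisions, same alignment as weights.
#' @slot beta noise precision (model variance is 1/beta).
#' @slot biasIncluded whether the constant basis survived pruning.
#' @slot kernel a [KernelSpec-class].
#' @slot evidence log marginal likelihood trace, one entry per iteration.
#' @slot nRV number of retained kernel bases (relevance vectors).
#' @slot converged whether the alpha fixed point converged within maxIter.
#' @seealso [rvmFit()]
#' @export
setClass("RVMModel",
  representation(relevanceVectors = "matrix", weights = "numeric",
                 alpha = "numeric", beta = "numeric",
                 biasIncluded = "logical", kernel = "KernelSpec",
                 evidence = "numeric", nRV = "integer",
                 converged = "logical"))

#' CVPlan: nested cross-validation plan
#'
#' A reproducible assignment of pairs to 3 outer folds, each outer
#' training set further split into 5 inner folds for kernel-parameter
#' selection. Indices refer to the canonically ordered pair list of the
#' dataset the plan was built for.
#'
#' @slot outerFolds list of 3 disjoint integer index vectors partitioning
#'   1..n.
#' @slot innerFolds list of 3 lists, each of 5 disjoint index vectors
#'   partitioning the corresponding outer training set.
#' @slot seed integer seed the plan was drawn under.
#' @slot sigmaGrid strictly increasing candidate kernel bandwidths.
#' @slot CGrid strictly increasing candidate SVR box constraints.
#' @seealso [makeCVPlan()], [runProtocol()]
#' @export
setClass("CVPlan",
  representation(outerFolds = "list", innerFolds = "list", seed = "integer",
                 sigmaGrid = "numeric", CGrid = "numeric"))

setValidity("CVPlan", function(object) {
  msgs <- character()
  n <- sum(lengths(object@outerFolds))
  if (length(object@outerFolds) != 3)
    msgs <- c(msgs, "need exactly 3 outer folds")
  all_idx <- sort(unname(unlist(object@outerFolds)))
  if (!identical(all_idx, seq_len(n)))
    msgs <- c(msgs, "outer folds must partition 1..n")
  if (length(object@innerFolds) != 3)
    msgs <- c(msgs, "need inner folds for each outer fold")
  else for (f in seq_len(3)) {
    tr <- sort(setdiff(seq_len(n), object@outerFolds[[f]]))
    if (length(object@innerFolds[[f]]) != 5)
      msgs <- c(msgs, "need 5 inner folds per outer training set")
    else if (!identical(sort(unname(unlist(object@innerFolds[[f]]))), tr))
      msgs <- c(msgs, "inner folds must partition the outer training set")
  }
  if (length(object@sigmaGrid) == 0 || is.unsorted(object@sigmaGrid, strictly = TRUE))
    msgs <- c(msgs, "sigmaGrid must be non-empty and strictly increasing")
  if (length(object@CGrid) == 0 || is.unsorted(object@CGrid, strictly = TRUE))
    msgs <- c(msgs, "CGrid must be non-empty and strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: results of the cross-validated protocol
#'
#' Per-fold and averaged training/test RMSEs, selected kernel bandwidths,
#' support/relevance vector counts, coverage-filter bookkeeping, and the
#' full per-pair prediction dump the RMSEs are computed from.
#'
#' @slot results data.frame, one row per (fold, C): selected sigma,
#'   training RMSE, coverage-filtered test RMSE, unfiltered test RMSE for
#'   feature models, kept/dropped counts, SV/RV counts.
#' @slot summary data.frame, per-C means over folds.
#' @slot predictions data.frame with fold, C, pair ids, split
#'   (train/test), observed and predicted strengths.
#' @slot plan the [CVPlan-class] used.
#' @slot mapping feature mapping used ("dn", "spd", "apm" or "none").
#' @slot modelKind "svr", "rvm" or "apm_baseline".
#' @slot k spectrum word length (NA unless mapping is "spd").
#' @seealso [runProtocol()]
#' @export
setClass("EvaluationReport",
  representation(results = "data.frame", summary = "data.frame",
                 predictions = "data.frame", plan = "CVPlan",
                 mapping = "character", modelKind = "character",
                 k = "numeric"))
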