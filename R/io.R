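# Readers and writers for the three plain-text interface formats:
# FASTA sequences, 4-column domain-annotation TSV, 3-column pair TSV.

#' Read protein sequences from a FASTA file
#'
#' The record id is the header token before the first whitespace.
#' Sequences are upper-cased; wrapped lines are concatenated.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) stop("empty FASTA file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s) in FASTA: ", paste(dup, collapse = ", "))
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read domain annotations into a ProteinSet
#'
#' Expects a tab-separated file with header line and columns
#' \code{protein_id}, \code{domain_id}, \code{start}, \code{end}
#' (1-based inclusive coordinates). Proteins present in \code{sequences}
#' but absent from the file get an empty domain list.
#'
#' @param path path to the annotation TSV.
#' @param sequences named character vector of sequences (from
#'   [readFasta()]); defines the protein universe.
#' @return a [ProteinSet-class].
#' @export
readDomainAnnotations <- function(path, sequences) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dm <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer", "integer"),
                   stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_id", "start", "end")
  if (!identical(colnames(dm)[seq_along(need)], need))
    stop("annotation file must have header columns: ",
         paste(need, collapse = ", "))
  if (nrow(dm) > 0) {
    unknown <- setdiff(dm$protein_id, names(sequences))
    if (length(unknown))
      stop("annotation refers to protein(s) without sequence: ",
           paste(unknown, collapse = ", "))
    bad <- which(dm$start > dm$end)
    if (length(bad))
      stop("start > end at annotation row ", bad[1])
    bad <- which(dm$end > nchar(sequences)[dm$protein_id] | dm$start < 1L)
    if (length(bad))
      stop("domain region out of sequence bounds at annotation row ", bad[1])
    dm <- dm[order(dm$protein_id, dm$start), , drop = FALSE]
    rownames(dm) <- NULL
  }
  new("ProteinSet", sequences = toupper(sequences), domains = dm)
}

#' Write domain annotations to TSV
#' @param proteins a [ProteinSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDomainAnnotations <- function(proteins, path) {
  write.table(proteins@domains, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a weighted protein-pair list
#'
#' Tab-separated, three columns (protein_a, protein_b, weight), header
#' line required. Input order is preserved. Weights must be non-negative
#' reals; duplicate unordered pairs are an error.
#'
#' @param path path to the pair TSV.
#' @return data.frame with columns protein_a, protein_b, weight.
#' @export
readPairWeights <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  pw <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "character"),
                   stringsAsFactors = FALSE)
  if (ncol(pw) < 3)
    stop("pair file must have 3 columns: protein_a, protein_b, weight")
  colnames(pw)[1:3] <- c("protein_a", "protein_b", "weight")
  if (nrow(pw) == 0)
    return(data.frame(protein_a = character(), protein_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  w <- suppressWarnings(as.numeric(pw$weight))
  if (anyNA(w))
    stop("unparsable weight at row ", which(is.na(w))[1])
  if (any(w < 0))
    stop("negative weight at row ", which(w < 0)[1])
  key <- pairKey(pw$protein_a, pw$protein_b)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate unordered pair(s): ", paste(unique(dup), collapse = ", "))
  data.frame(protein_a = pw$protein_a, protein_b = pw$protein_b,
             weight = w, stringsAsFactors = FALSE)
}

#' Write a DDI score table to TSV
#' @param table a [DDIScoreTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeScoreTable <- function(table, path) {
  tb <- table@table
  tb$score <- sprintf("%.17g", tb$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s", table@method), con)
  write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DDI score table from TSV
#' @param path path written by [writeScoreTable()].
#' @return a [DDIScoreTable-class].
#' @export
readScoreTable <- function(path) {
  first <- readLines(path, n = 1)
  method <- sub("^# method=", "", first)
  tb <- read.delim(path, sep = "\t", header = TRUE, skip = 1,
                   colClasses = c("character", "character", "numeric", "integer"),
                   stringsAsFactors = FALSE)
  new("DDIScoreTable", table = tb, method = method)
}

#' Write a PairDataset to its three interface files
#'
#' Emits \code{seq.fa}, \code{dom.tsv} and \code{pairs.tsv} (the latter
#' with a \code{strength} column at full precision, so that
#' [readPairDataset()] round-trips exactly).
#'
#' @param dataset a [PairDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writePairDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFasta(dataset@proteins@sequences, file.path(dir, "seq.fa"))
  writeDomainAnnotations(dataset@proteins, file.path(dir, "dom.tsv"))
  pr <- dataset@pairs[, c("protein_a", "protein_b", "strength")]
  pr$strength <- sprintf("%.17g", pr$strength)
  write.table(pr, file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a PairDataset from its three interface files
#'
#' Inverse of [writePairDataset()]; strengths are read as-is, without
#' re-normalisation.
#'
#' @param dir directory containing seq.fa, dom.tsv, pairs.tsv.
#' @return a [PairDataset-class].
#' @export
readPairDataset <- function(dir) {
  sq <- readFasta(file.path(dir, "seq.fa"))
  ps <- readDomainAnnotations(file.path(dir, "dom.tsv"), sq)
  pr <- read.delim(file.path(dir, "pairs.tsv"), sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "numeric"),
                   stringsAsFactors = FALSE)
  colnames(pr) <- c("protein_a", "protein_b", "strength")
  makePairDataset(ps, pr)
}
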