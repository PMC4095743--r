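# Synthetic benchmark generator: proteins built from a domain universe
# with planted domain-domain interaction probabilities, pair strengths
# generated by the noisy-OR model, optional truncated-Gaussian noise and
# zero-strength augmentation. Everything every other module needs is
# produced here, reproducibly, without external databases.

#' Build a generator configuration
#'
#' Defaults describe a small but realistic interactome-style benchmark:
#' proteins composed of 1-4 domain instances (a 10\% chance per extra
#' instance slot of repeating an already-chosen domain, so multiplicity
#' paths are exercised), domain regions of 40-80 residues separated by
#' 5-30 residue linkers, i.i.d. sequences over the 20 standard residues
#' with a 2\% ambiguity-code rate, and a sparse planted DDI probability
#' matrix (5\% of domain pairs interact, with probabilities uniform on
#' [0.1, 0.9]).
#'
#' @param n_proteins number of proteins.
#' @param n_domains size of the domain universe.
#' @param n_pairs number of weighted pairs to emit (interacting pairs
#'   are preferred while available; see [generateDataset()]).
#' @param domains_per_protein integer range (length-2) of instances per
#'   protein.
#' @param domain_length integer range of domain region lengths.
#' @param linker_length integer range of inter-domain linker lengths.
#' @param ddi_density fraction of unordered domain pairs with nonzero
#'   planted probability.
#' @param noise_sd standard deviation of the truncated Gaussian noise
#'   added to clean strengths (0 = noise-free).
#' @param zero_pair_count number of absent pairs appended at strength 0.
#' @param repeat_prob per-slot probability of repeating a domain already
#'   present in the protein.
#' @param ambiguity_rate per-residue probability of an ambiguity code.
#' @param mutation_rate per-residue substitution rate applied to each
#'   domain's prototype sequence in each instance (domains are conserved
#'   but not identical across proteins).
#' @param seed integer seed.
#' @return a list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(n_proteins = 60, n_domains = 20, n_pairs = 120,
                            domains_per_protein = c(1L, 4L),
                            domain_length = c(40L, 80L),
                            linker_length = c(5L, 30L),
                            ddi_density = 0.05, noise_sd = 0.02,
                            zero_pair_count = 10, repeat_prob = 0.1,
                            ambiguity_rate = 0.02, mutation_rate = 0.05,
                            seed = 1) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_domains = as.integer(n_domains),
              n_pairs = as.integer(n_pairs),
              domains_per_protein = as.integer(domains_per_protein),
              domain_length = as.integer(domain_length),
              linker_length = as.integer(linker_length),
              ddi_density = ddi_density, noise_sd = noise_sd,
              zero_pair_count = as.integer(zero_pair_count),
              repeat_prob = repeat_prob, ambiguity_rate = ambiguity_rate,
              mutation_rate = mutation_rate, seed = as.integer(seed))
  stopifnot(cfg$n_proteins > 0, cfg$n_domains > 0, cfg$n_pairs > 0,
            cfg$noise_sd >= 0, cfg$ddi_density >= 0, cfg$ddi_density <= 1,
            cfg$zero_pair_count >= 0,
            length(cfg$domains_per_protein) == 2,
            cfg$domains_per_protein[1] >= 1)
  class(cfg) <- c("GeneratorConfig", "list")
  cfg
}

#' Configuration matching the shape of the reference benchmark
#'
#' A shape-alike (not value-alike) of the yeast interactome dataset the
#' method was originally evaluated on: 758 proteins, 327 domains, 1387
#' weighted pairs plus 100 added zero-strength pairs (1487 in total).
#'
#' @param ... overrides passed through to [generatorConfig()].
#' @return a \code{GeneratorConfig}.
#' @export
paperShapeConfig <- function(...) {
  generatorConfig(n_proteins = 758, n_domains = 327, n_pairs = 1387,
                  zero_pair_count = 100, ...)
}

.AMBIG <- c("X", "B", "Z", "U", "O", "J")

# sample n integers uniformly from [lo, hi]; safe when lo == hi
# (base::sample(x, ...) would misread a scalar x as 1:x)
rint <- function(lo, hi, n = 1) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

randResidues <- function(n, ambiguity_rate) {
  r <- sample(.AA20, n, replace = TRUE)
  amb <- runif(n) < ambiguity_rate
  if (any(amb)) r[amb] <- sample(.AMBIG, sum(amb), replace = TRUE)
  r
}

#' Generate a synthetic PairDataset with planted DDI structure
#'
#' Proteins are assembled from domain instances (each domain has a
#' prototype sequence; instances are point-mutated copies) separated by
#' random linkers; every universe domain is guaranteed at least one
#' instance. Clean pair strengths follow the noisy-OR model over the
#' planted DDI probabilities exactly; emitted strengths are
#' clamp(clean + N(0, noise_sd), 0, 1). Interacting (clean > 0) pairs
#' are preferred when sampling the weighted pair list, mimicking an
#' interactome edge list; absent pairs are appended at strength 0 via
#' [addZeroPairs()].
#'
#' @param config a \code{GeneratorConfig} from [generatorConfig()].
#' @return list with elements \code{dataset} (a [PairDataset-class]) and
#'   \code{truth}: a list with \code{ddi} (data.frame domain_a,
#'   domain_b, prob over all planted nonzero pairs) and \code{clean}
#'   (data.frame protein_a, protein_b, clean with the pre-noise
#'   strengths of the emitted weighted pairs).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed, .generate(config))
}

.generate <- function(cfg) {
  dom_ids <- sprintf("D%04d", seq_len(cfg$n_domains))
  prot_ids <- sprintf("P%05d", seq_len(cfg$n_proteins))

  # per-protein instance counts; guarantee every domain appears at least
  # once by dealing the universe round-robin into the first slots
  n_inst <- rint(cfg$domains_per_protein[1], cfg$domains_per_protein[2],
                 cfg$n_proteins)
  if (sum(n_inst) < cfg$n_domains)
    stop("domain universe larger than total instance slots; ",
         "increase n_proteins or domains_per_protein")
  slots <- vector("list", cfg$n_proteins)
  deal <- rep(seq_len(cfg$n_proteins), times = n_inst)
  for (p in seq_len(cfg$n_proteins)) slots[[p]] <- character(n_inst[p])
  fixed <- deal[seq_len(cfg$n_domains)]
  fill_pos <- integer(cfg$n_proteins)
  for (d in seq_len(cfg$n_domains)) {
    p <- fixed[d]
    fill_pos[p] <- fill_pos[p] + 1L
    slots[[p]][fill_pos[p]] <- dom_ids[d]
  }
  for (p in seq_len(cfg$n_proteins)) {
    for (s in seq_len(n_inst[p])) {
      if (slots[[p]][s] != "") next
      prev <- slots[[p]][seq_len(s - 1)]
      prev <- prev[prev != ""]
      slots[[p]][s] <- if (length(prev) && runif(1) < cfg$repeat_prob)
        sample(prev, 1) else sample(dom_ids, 1)
    }
  }

  # conserved prototype sequence per domain
  proto_len <- rint(cfg$domain_length[1], cfg$domain_length[2],
                    cfg$n_domains)
  names(proto_len) <- dom_ids
  proto <- lapply(proto_len, randResidues, ambiguity_rate = cfg$ambiguity_rate)
  names(proto) <- dom_ids

  seqs <- character(cfg$n_proteins)
  ann <- vector("list", cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    parts <- character(0)
    pos <- 0L
    rows <- list()
    for (d in slots[[p]]) {
      linker <- randResidues(rint(cfg$linker_length[1], cfg$linker_length[2]),
                             cfg$ambiguity_rate)
      region <- proto[[d]]
      mut <- runif(length(region)) < cfg$mutation_rate
      if (any(mut)) region[mut] <- sample(.AA20, sum(mut), replace = TRUE)
      parts <- c(parts, paste(linker, collapse = ""),
                 paste(region, collapse = ""))
      start <- pos + length(linker) + 1L
      end <- start + length(region) - 1L
      pos <- end
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = prot_ids[p], domain_id = d,
        start = start, end = end, stringsAsFactors = FALSE)
    }
    tail_linker <- randResidues(rint(cfg$linker_length[1], cfg$linker_length[2]),
                                cfg$ambiguity_rate)
    seqs[p] <- paste(c(parts, paste(tail_linker, collapse = "")),
                     collapse = "")
    ann[[p]] <- do.call(rbind, rows)
  }
  names(seqs) <- prot_ids
  dm <- do.call(rbind, ann)
  dm <- dm[order(dm$protein_id, dm$start), , drop = FALSE]
  rownames(dm) <- NULL
  proteins <- new("ProteinSet", sequences = seqs, domains = dm)

  # planted DDI probabilities over unordered domain pairs (incl. self)
  all_dd <- expand.grid(a = seq_len(cfg$n_domains), b = seq_len(cfg$n_domains))
  all_dd <- all_dd[all_dd$a <= all_dd$b, , drop = FALSE]
  on <- runif(nrow(all_dd)) < cfg$ddi_density
  prob <- numeric(nrow(all_dd))
  prob[on] <- runif(sum(on), 0.1, 0.9)
  ddKey <- paste(dom_ids[all_dd$a], dom_ids[all_dd$b], sep = "|")
  probLookup <- prob
  names(probLookup) <- ddKey
  ddi <- data.frame(domain_a = dom_ids[all_dd$a][on],
                    domain_b = dom_ids[all_dd$b][on],
                    prob = prob[on], stringsAsFactors = FALSE)

  inst <- split(dm$domain_id, dm$protein_id)
  cleanStrength <- function(pa, pb) {
    a <- inst[[pa]]; b <- inst[[pb]]
    ka <- rep(a, times = length(b)); kb <- rep(b, each = length(a))
    s <- probLookup[paste(pmin(ka, kb), pmax(ka, kb), sep = "|")]
    -expm1(sum(log1p(-s)))
  }

  # sample candidate pairs, preferring interacting (clean > 0) ones
  total_pairs <- cfg$n_proteins * (cfg$n_proteins - 1) / 2
  if (cfg$n_pairs + cfg$zero_pair_count > total_pairs)
    stop("not enough distinct protein pairs for the requested counts")
  want <- cfg$n_pairs
  chosen_a <- character(0); chosen_b <- character(0); chosen_clean <- numeric(0)
  spare_a <- character(0); spare_b <- character(0); spare_clean <- numeric(0)
  seen <- character(0)
  while (length(chosen_a) < want &&
         length(seen) < total_pairs) {
    m <- max(4L * (want - length(chosen_a)), 64L)
    i <- sample.int(cfg$n_proteins, m, replace = TRUE)
    j <- sample.int(cfg$n_proteins, m, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    a <- pmin(prot_ids[i], prot_ids[j]); b <- pmax(prot_ids[i], prot_ids[j])
    key <- paste(a, b, sep = "|")
    keep <- !duplicated(key) & !(key %in% seen)
    a <- a[keep]; b <- b[keep]
    if (!length(a)) next
    seen <- c(seen, paste(a, b, sep = "|"))
    cl <- mapply(cleanStrength, a, b)
    pos <- cl > 0
    take <- which(pos)[seq_len(min(sum(pos), want - length(chosen_a)))]
    chosen_a <- c(chosen_a, a[take]); chosen_b <- c(chosen_b, b[take])
    chosen_clean <- c(chosen_clean, cl[take])
    rest <- setdiff(seq_along(a), take)
    spare_a <- c(spare_a, a[rest]); spare_b <- c(spare_b, b[rest])
    spare_clean <- c(spare_clean, cl[rest])
  }
  short <- want - length(chosen_a)
  if (short > 0) {  # not enough interacting pairs exist; pad with others
    take <- seq_len(min(short, length(spare_a)))
    chosen_a <- c(chosen_a, spare_a[take]); chosen_b <- c(chosen_b, spare_b[take])
    chosen_clean <- c(chosen_clean, spare_clean[take])
  }
  if (length(chosen_a) < want)
    stop("could not assemble the requested number of pairs")

  strength <- chosen_clean
  if (cfg$noise_sd > 0)
    strength <- strength + rnorm(length(strength), 0, cfg$noise_sd)
  strength <- pmin(pmax(strength, 0), 1)
  pairs <- data.frame(protein_a = chosen_a, protein_b = chosen_b,
                      strength = strength, stringsAsFactors = FALSE)
  dataset <- makePairDataset(proteins, pairs)
  if (cfg$zero_pair_count > 0)
    dataset <- addZeroPairs(dataset, cfg$zero_pair_count,
                            seed = sample.int(.Machine$integer.max, 1))
  truth <- list(ddi = ddi,
                clean = data.frame(protein_a = chosen_a,
                                   protein_b = chosen_b,
                                   clean = chosen_clean,
                                   stringsAsFactors = FALSE))
  list(dataset = dataset, truth = truth)
}

#' Write a generated dataset and its planted truth to a directory
#'
#' Emits the three interface files via [writePairDataset()] plus
#' \code{truth.tsv} holding the planted DDI probabilities in the score
#' table format.
#'
#' @param generated output of [generateDataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeGeneratedDataset <- function(generated, dir) {
  writePairDataset(generated$dataset, dir)
  tb <- generated$truth$ddi
  tt <- new("DDIScoreTable",
            table = data.frame(domain_a = tb$domain_a, domain_b = tb$domain_b,
                               score = tb$prob,
                               support = rep(1L, nrow(tb)),
                               stringsAsFactors = FALSE),
            method = "APM")
  writeScoreTable(tt, file.path(dir, "truth.tsv"))
  invisible(dir)
}
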