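#' Specification for the synthetic genome-collection generator
#'
#' Describes how to emulate a complete-genome collection: per-genome
#' plasmid-type counts drawn from a Wright-Fisher stationary distribution
#' (or an explicit probability vector), replicon tables with one chromosome
#' and one row per plasmid, genus labels, a configurable fraction of
#' "incomplete" genomes whose chromosome falls below the 0.5 Mb
#' completeness threshold, and cas-gene carriage for hit-table generation.
#'
#' Replicon lengths are plausibility dressing only: nothing downstream
#' depends on them except the completeness filter.
#'
#' @param n_genomes Number of genomes to generate (default 17725, the scale
#'   of a complete-genome snapshot; reduce for fast tests).
#' @param source A `wf_stationary` object or a probability vector over
#'   `0..i_max` from which per-genome plasmid-type counts are drawn.
#' @param fraction_incomplete Fraction of genomes emitted with a
#'   sub-threshold (100-450 kb) "chromosome", in `[0, 1)`.
#' @param genus_pool Named numeric vector of genus sampling weights.
#' @param cas_carriage Probability that a genome carries a cas gene; either
#'   a scalar or a function of the plasmid count.
#' @param decoy_fraction Fraction of cas-negative genomes that still get a
#'   weak decoy hit (E-value above threshold), exercising the E-value
#'   filter.
#' @param chromosome_range,plasmid_range,incomplete_range Length ranges in
#'   bp (chromosomes uniform, plasmids log-uniform).
#' @return An object of class `generator_spec`.
#' @export
#' @examples
#' st <- stationary_distribution(epistasis_spec("positive", 0.01), q = 0.005)
#' generator_spec(n_genomes = 100, source = st)
generator_spec <- function(n_genomes = 17725, source,
                           fraction_incomplete = 0,
                           genus_pool = c(Escherichia = 3, Klebsiella = 2,
                                          Bacillus = 2, Pseudomonas = 2,
                                          Streptomyces = 1, Lactobacillus = 1,
                                          Synechocystis = 1, Vibrio = 1),
                           cas_carriage = 0.4, decoy_fraction = 0.2,
                           chromosome_range = c(1e6, 6e6),
                           plasmid_range = c(2e3, 2e5),
                           incomplete_range = c(1e5, 4.5e5)) {
  if (n_genomes < 1) stop("'n_genomes' must be >= 1", call. = FALSE)
  probs <- if (inherits(source, "wf_stationary")) source$f else source
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("'source' must be a wf_stationary or a probability vector",
         call. = FALSE)
  if (fraction_incomplete < 0 || fraction_incomplete >= 1)
    stop("'fraction_incomplete' must lie in [0, 1)", call. = FALSE)
  if (is.numeric(cas_carriage) &&
      (cas_carriage < 0 || cas_carriage > 1))
    stop("'cas_carriage' must lie in [0, 1]", call. = FALSE)
  structure(list(n_genomes = as.integer(n_genomes), probs = probs,
                 fraction_incomplete = fraction_incomplete,
                 genus_pool = genus_pool, cas_carriage = cas_carriage,
                 decoy_fraction = decoy_fraction,
                 chromosome_range = chromosome_range,
                 plasmid_range = plasmid_range,
                 incomplete_range = incomplete_range),
            class = "generator_spec")
}

#' Draw per-genome plasmid-type counts
#'
#' @param spec A [generator_spec()].
#' @param seed Seed (local to this call); required for reproducibility.
#' @return List with `counts` (integer vector, one per genome) and
#'   `histogram` (their exact tally as a histogram data.frame).
#' @export
sample_plasmid_counts <- function(spec, seed) {
  stopifnot(inherits(spec, "generator_spec"))
  local_seed(seed)
  support <- seq_along(spec$probs) - 1L
  counts <- sample(support, spec$n_genomes, replace = TRUE,
                   prob = spec$probs)
  list(counts = as.integer(counts), histogram = tally_counts(counts))
}

#' Generate an assembly-summary-like replicon table
#'
#' Emits one chromosome row per genome (sub-threshold length for the
#' incomplete fraction) plus one plasmid row per carried type, with genus
#' labels sampled from the spec's pool. A ground-truth sidecar records the
#' generating count, genus and completeness of every genome.
#'
#' @param counts Integer vector of per-genome plasmid-type counts (e.g.
#'   from [sample_plasmid_counts()]).
#' @param spec A [generator_spec()].
#' @param seed Seed (local to this call).
#' @param path Optional output stem: writes `<path>.tsv` (table) and
#'   `<path>_truth.json` (sidecar).
#' @return List with `table` (assembly table data.frame) and `truth`
#'   (data.frame: `assembly_accession`, `true_count`, `genus`, `complete`).
#' @export
generate_assembly_table <- function(counts, spec, seed, path = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  local_seed(seed)
  n <- length(counts)
  ids <- sprintf("SYN_%06d.1", seq_len(n))
  genus <- sample(names(spec$genus_pool), n, replace = TRUE,
                  prob = spec$genus_pool)
  incomplete <- stats::runif(n) < spec$fraction_incomplete
  chrom_len <- ifelse(incomplete,
                      round(stats::runif(n, spec$incomplete_range[1],
                                         spec$incomplete_range[2])),
                      round(stats::runif(n, spec$chromosome_range[1],
                                         spec$chromosome_range[2])))
  rows_per <- 1L + counts
  idx <- rep(seq_len(n), rows_per)
  is_chrom <- unlist(lapply(counts, function(k) c(TRUE, rep(FALSE, k))),
                     use.names = FALSE)
  n_plasmids <- sum(counts)
  pl_len <- round(exp(stats::runif(n_plasmids,
                                   log(spec$plasmid_range[1]),
                                   log(spec$plasmid_range[2]))))
  lengths <- integer(length(idx))
  lengths[is_chrom] <- chrom_len
  lengths[!is_chrom] <- pl_len
  plasmid_no <- unlist(lapply(counts, function(k) if (k > 0) seq_len(k)),
                       use.names = FALSE)
  name <- character(length(idx))
  name[is_chrom] <- "chromosome_1"
  name[!is_chrom] <- paste0("plasmid_", plasmid_no)
  tab <- data.frame(assembly_accession = ids[idx],
                    replicon_name = name,
                    replicon_role = ifelse(is_chrom, "Chromosome",
                                           "Plasmid"),
                    length_bp = lengths,
                    genus = genus[idx],
                    stringsAsFactors = FALSE)
  tab <- as_assembly_table(tab)
  truth <- data.frame(assembly_accession = ids, true_count = counts,
                      genus = genus, complete = !incomplete,
                      stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, paste0(path, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, paste0(path, "_truth.json"),
                         dataframe = "columns", auto_unbox = FALSE)
  }
  list(table = tab, truth = truth)
}

#' Generate a cas hit table for synthetic genomes
#'
#' Each cas-positive genome receives at least one hit row with an E-value
#' sampled log-uniformly in `[1e-60, 1e-31]` (below the 1e-30 validity
#' threshold); a configurable fraction of cas-negative genomes receive
#' decoy rows with E-values in `[1e-29, 1e-5]`, which a strict threshold
#' must reject.
#'
#' @param truth Ground-truth sidecar from [generate_assembly_table()] (needs
#'   columns `assembly_accession` and `true_count`).
#' @param spec A [generator_spec()] (uses `cas_carriage` and
#'   `decoy_fraction`).
#' @param seed Seed (local to this call).
#' @param path Optional path for a TSV of the hits.
#' @return List with `hits` (data.frame `assembly_accession`, `model_name`,
#'   `evalue`) and `cas_truth` (logical vector named by accession).
#' @export
generate_cas_tables <- function(truth, spec, seed, path = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  local_seed(seed)
  n <- nrow(truth)
  p_cas <- if (is.function(spec$cas_carriage))
    spec$cas_carriage(truth$true_count) else rep(spec$cas_carriage, n)
  cas_pos <- stats::runif(n) < p_cas
  models <- c("cas1", "cas2", "cas3", "cas9", "cas12")
  make_rows <- function(ids, lo, hi) {
    if (!length(ids)) return(NULL)
    k <- sample(1:3, length(ids), replace = TRUE)
    data.frame(assembly_accession = rep(ids, k),
               model_name = sample(models, sum(k), replace = TRUE),
               evalue = exp(stats::runif(sum(k), log(lo), log(hi))),
               stringsAsFactors = FALSE)
  }
  pos_rows <- make_rows(truth$assembly_accession[cas_pos], 1e-60, 1e-31)
  neg_ids <- truth$assembly_accession[!cas_pos]
  decoy_ids <- neg_ids[stats::runif(length(neg_ids)) < spec$decoy_fraction]
  decoy_rows <- make_rows(decoy_ids, 1e-29, 1e-5)
  hits <- rbind(pos_rows, decoy_rows)
  if (is.null(hits))
    hits <- data.frame(assembly_accession = character(0),
                       model_name = character(0), evalue = numeric(0))
  if (!is.null(path))
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cas_truth <- stats::setNames(cas_pos, truth$assembly_accession)
  list(hits = hits, cas_truth = cas_truth)
}
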