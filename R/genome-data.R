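#' Load an assembly-summary-like replicon table
#'
#' Reads a tab-separated table with one row per replicon and header columns
#' `assembly_accession`, `replicon_name`, `replicon_role`, `length_bp`,
#' `genus` — a flattened surrogate for per-assembly sequence reports. Role
#' labels are matched case-insensitively downstream.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `assembly_table` (one row per replicon).
#'   An empty table (header only) is returned with a warning.
#' @export
load_assembly_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("assembly_accession", "replicon_name", "replicon_role",
                "length_bp", "genus")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("assembly table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in setdiff(required, "length_bp"))
    tab[[col]] <- as.character(tab[[col]])
  tab$length_bp <- as.numeric(tab$length_bp)
  if (nrow(tab) == 0) {
    warning("assembly table is empty", call. = FALSE)
    return(structure(tab[required], class = c("assembly_table",
                                              "data.frame")))
  }
  bad <- which(!is.finite(tab$length_bp) | tab$length_bp <= 0 |
                 is.na(tab$assembly_accession) |
                 tab$assembly_accession == "")
  if (length(bad))
    stop("malformed assembly rows (zero/missing length or accession) at ",
         "line(s): ", paste(bad + 1L, collapse = ", "), call. = FALSE)
  key <- paste(tab$assembly_accession, tab$replicon_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (assembly, replicon) rows at line(s): ",
         paste(which(duplicated(key)) + 1L, collapse = ", "),
         call. = FALSE)
  structure(tab[required], class = c("assembly_table", "data.frame"))
}

as_assembly_table <- function(tab) {
  required <- c("assembly_accession", "replicon_name", "replicon_role",
                "length_bp", "genus")
  if (!all(required %in% names(tab)))
    stop("not an assembly table: needs columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (!inherits(tab, "assembly_table"))
    class(tab) <- c("assembly_table", class(tab))
  tab
}

#' Completeness filter on assembled genomes
#'
#' Retains only assemblies having at least one chromosome-role replicon
#' strictly longer than 0.5 Mb (500,000 bp), dropping draft or misassembled
#' genomes mislabeled as complete.
#'
#' @param tab An assembly table (see [load_assembly_table()]).
#' @return The table restricted to retained assemblies (all their rows).
#' @export
completeness_filter <- function(tab) {
  tab <- as_assembly_table(tab)
  is_chrom <- tolower(tab$replicon_role) == "chromosome" &
    tab$length_bp > 5e5
  keep <- unique(tab$assembly_accession[is_chrom])
  tab[tab$assembly_accession %in% keep, , drop = FALSE]
}

#' Plasmid-count histogram of an assembly table
#'
#' Counts, per assembly, the replicons whose role label is "plasmid"
#' (case-insensitive) and tallies assemblies by that count into a
#' two-column histogram covering `0..max`.
#'
#' @param tab An assembly table (normally after [completeness_filter()]).
#' @param by_genus Tally separately per genus; assemblies with an empty
#'   genus are collected under `"unassigned"` with a warning.
#' @return A histogram data.frame (`types`, `count`), or a named list of
#'   them when `by_genus = TRUE`.
#' @export
plasmid_count_histogram <- function(tab, by_genus = FALSE) {
  tab <- as_assembly_table(tab)
  ids <- unique(tab$assembly_accession)
  if (!length(ids))
    return(data.frame(types = 0L, count = 0L)[0, ])
  is_plasmid <- tolower(tab$replicon_role) == "plasmid"
  counts <- table(factor(tab$assembly_accession[is_plasmid], levels = ids))
  per_genome <- as.integer(counts)  # zero for plasmid-free assemblies
  if (!by_genus) return(tally_counts(per_genome))
  genus <- tab$genus[match(ids, tab$assembly_accession)]
  genus[is.na(genus) | genus == ""] <- "unassigned"
  if (any(genus == "unassigned"))
    warning("assemblies with empty genus collected under 'unassigned'",
            call. = FALSE)
  lapply(split(per_genome, genus), tally_counts)
}

tally_counts <- function(per_genome) {
  mx <- max(per_genome, 0L)
  tab <- tabulate(per_genome + 1L, nbins = mx + 1L)
  data.frame(types = 0:mx, count = tab)
}

#' Exclude genera from an assembly table
#'
#' Removes assemblies whose genus matches any entry of `genera`
#' (case-insensitive exact match); used e.g. to drop clinically
#' over-sampled genera before distribution analysis.
#'
#' @param tab An assembly table.
#' @param genera Nonempty character vector of genus names.
#' @return The filtered table.
#' @export
exclude_genera <- function(tab, genera) {
  tab <- as_assembly_table(tab)
  if (!length(genera)) stop("'genera' must be nonempty", call. = FALSE)
  drop <- tolower(tab$genus) %in% tolower(genera)
  tab[!drop, , drop = FALSE]
}

#' Assemblies with a valid cas-gene hit
#'
#' Reads profile-HMM search results (columns `assembly_accession`,
#' `model_name`, `evalue`) and returns the assemblies having at least one
#' hit with E-value strictly below the threshold.
#'
#' @param hits A data.frame of hits, or a path to a TSV of them.
#' @param threshold E-value cutoff (strict `<`; default 1e-30).
#' @return Character vector of cas-positive assembly accessions.
#' @export
cas_positive_assemblies <- function(hits, threshold = 1e-30) {
  if (is.character(hits) && length(hits) == 1L)
    hits <- utils::read.delim(hits, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  required <- c("assembly_accession", "model_name", "evalue")
  if (!all(required %in% names(hits)))
    stop("cas hit table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (nrow(hits) == 0) return(character(0))
  if (any(!is.finite(hits$evalue) | hits$evalue < 0))
    stop("E-values must be finite and nonnegative", call. = FALSE)
  unique(hits$assembly_accession[hits$evalue < threshold])
}

#' Split plasmid-count histograms by cas status
#'
#' @param tab An assembly table (after filtering).
#' @param cas_set Character vector of cas-positive assembly accessions
#'   (see [cas_positive_assemblies()]).
#' @return List of two histograms, `cas_pos` and `cas_neg`; their totals
#'   sum to the number of assemblies in `tab`.
#' @export
split_by_cas <- function(tab, cas_set) {
  tab <- as_assembly_table(tab)
  pos <- tab[tab$assembly_accession %in% cas_set, , drop = FALSE]
  neg <- tab[!tab$assembly_accession %in% cas_set, , drop = FALSE]
  list(cas_pos = if (nrow(pos)) plasmid_count_histogram(pos)
                 else data.frame(types = integer(0), count = integer(0)),
       cas_neg = if (nrow(neg)) plasmid_count_histogram(neg)
                 else data.frame(types = integer(0), count = integer(0)))
}
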