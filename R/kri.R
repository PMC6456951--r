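#' Construct a genome set (one genome per species)
#'
#' A genome set is the species-level collection of distinct genomes used for
#' k-mer redundancy index (KRI) estimation: one genome per `species_id`
#' (supplying two genomes under the same species id is rejected — strains of
#' one species are not distinct genomes at the species-level convention).
#' Each genome may consist of several contigs.
#'
#' @param genomes Named list mapping `species_id` to a character vector of
#'   contig sequences (or a single sequence); or a named character vector
#'   (one contig per species); or a `DNAStringSet`.
#' @return An object of class `genome_set` (list with `genomes`; KRI fields
#'   are filled by [kri_of_genome_set()]).
#' @export
genome_set <- function(genomes) {
  if (inherits(genomes, "genome_set")) return(genomes)
  if (inherits(genomes, "XStringSet") || is.character(genomes)) {
    genomes <- as_sequence_set(genomes, "genome")
    genomes <- as.list(genomes)
  }
  if (!is.list(genomes) || length(genomes) == 0)
    stop("`genomes` must be a non-empty named list of sequences",
         call. = FALSE)
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every genome needs a species_id (list names)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate species_id (one genome per species): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (id in ids) {
    s <- genomes[[id]]
    if (!is.character(s) || length(s) == 0 || any(nchar(s) == 0))
      stop("species '", id, "': sequences must be non-empty strings",
           call. = FALSE)
  }
  structure(list(genomes = genomes, k = NULL, canonical = NULL,
                 tkc_union = NULL, dkc_union = NULL, kri = NULL),
            class = "genome_set")
}

# flatten a genome set into one named character vector of contigs
flatten_genomes <- function(gs) {
  seqs <- unlist(gs$genomes, use.names = FALSE)
  nm <- rep(names(gs$genomes), lengths(gs$genomes))
  names(seqs) <- make.unique(nm, sep = "__contig")
  seqs
}

#' K-mer redundancy index of a genome set
#'
#' Computes union-level k-mer statistics of the pooled set of genomes:
#' `tkc_union` (all k-length windows summed across genomes), `dkc_union`
#' (distinct k-mers of the union — duplicates across genomes collapse), and
#' `kri = tkc_union / dkc_union`. The KRI converts distinct k-mer counts to
#' total genome length (total length ~ TKC = DKC * KRI for L >> k). The
#' counting convention must match the spectrum used for DKC estimation.
#'
#' @param genomes A [genome_set], named list, named character vector or
#'   `DNAStringSet` of genome sequences.
#' @param k k-mer size (default 20).
#' @param canonical Collapse reverse complements (default `TRUE`).
#' @return The [genome_set] with `k`, `canonical`, `tkc_union`, `dkc_union`
#'   and `kri` filled in.
#' @examples
#' gs <- kri_of_genome_set(c(sp1 = "AAAAAAAAAAAA"), k = 6, canonical = FALSE)
#' gs$kri  # 7: a single 6-mer repeated across all 7 windows
#' @export
kri_of_genome_set <- function(genomes, k = 20, canonical = TRUE) {
  gs <- genome_set(genomes)
  k <- check_count(k, "k")
  canonical <- check_flag(canonical, "canonical")
  spec <- count_kmers(flatten_genomes(gs), k = k, canonical = canonical)
  st <- spectrum_stats(spec)
  gs$k <- k
  gs$canonical <- canonical
  gs$tkc_union <- st$tkc
  gs$dkc_union <- st$dkc
  gs$kri <- st$kri
  gs
}

#' @export
print.genome_set <- function(x, ...) {
  cat("Genome set:", length(x$genomes), "species\n")
  if (!is.null(x$kri))
    cat(sprintf("  k = %d (%s)  TKC = %.0f  DKC = %.0f  KRI = %.4f\n",
                x$k, if (x$canonical) "canonical" else "stranded",
                x$tkc_union, x$dkc_union, x$kri))
  invisible(x)
}

#' Estimate KRI from a random subset of genomes
#'
#' In real data only the detected (known) species contribute genomes, so the
#' community KRI must be estimated from a partial genome set. This helper
#' quantifies how well that works: it computes KRI on a seeded random subset
#' of `ceiling(fraction * G)` genomes and returns it alongside the full-set
#' KRI.
#'
#' @param full A [genome_set] with KRI computed (or computable: `k` and
#'   `canonical` may be supplied).
#' @param fraction Fraction of genomes to keep, in (0, 1].
#' @param seed RNG seed for the subset draw.
#' @inheritParams kri_of_genome_set
#' @return List with `kri_subset`, `kri_full`, `abs_diff`, `species_used`.
#' @export
kri_from_subset <- function(full, fraction, seed = 1L, k = NULL,
                            canonical = NULL) {
  gs <- genome_set(full)
  if (is.null(gs$kri)) {
    if (is.null(k)) k <- 20
    if (is.null(canonical)) canonical <- TRUE
    gs <- kri_of_genome_set(gs, k = k, canonical = canonical)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  G <- length(gs$genomes)
  n_keep <- ceiling(fraction * G)
  idx <- with_seed(seed, sort(sample.int(G, n_keep)))
  sub <- kri_of_genome_set(gs$genomes[idx], k = gs$k, canonical = gs$canonical)
  list(kri_subset = sub$kri, kri_full = gs$kri,
       abs_diff = abs(sub$kri - gs$kri),
       species_used = names(gs$genomes)[idx])
}

#' Convert a distinct k-mer estimate into total genome length
#'
#' `total_length = dkc_total * kri`: the total k-mer count of the distinct
#' genome set, which approximates total genome length when genome lengths far
#' exceed k. Confidence-interval endpoints of the DKC estimate are scaled by
#' the same KRI point estimate (KRI estimation uncertainty is not
#' propagated).
#'
#' @param estimate An [estimate_total_dkc()] result (`unseen_estimate`), or a
#'   single numeric DKC value.
#' @param kri K-mer redundancy index (>= 1), e.g. from
#'   [kri_of_genome_set()] or [kri_from_subset()].
#' @return Object of class `total_length_estimate`: list with `dkc_total`,
#'   `kri_estimate`, `total_length`, `ci_lower`, `ci_upper`.
#' @export
total_length <- function(estimate, kri) {
  if (!is.numeric(kri) || length(kri) != 1 || is.na(kri))
    stop("`kri` must be a single number", call. = FALSE)
  if (kri < 1)
    stop("kri < 1 is impossible (TKC >= DKC by construction)", call. = FALSE)
  if (is.numeric(estimate)) {
    dkc_total <- estimate
    ci <- c(NA_real_, NA_real_)
  } else if (inherits(estimate, "unseen_estimate")) {
    dkc_total <- estimate$dkc_total
    ci <- c(estimate$ci_lower, estimate$ci_upper)
  } else {
    stop("`estimate` must be an unseen_estimate or a number", call. = FALSE)
  }
  structure(list(
    dkc_total = dkc_total,
    kri_estimate = kri,
    total_length = dkc_total * kri,
    ci_lower = ci[1] * kri,
    ci_upper = ci[2] * kri
  ), class = "total_length_estimate")
}

#' @export
print.total_length_estimate <- function(x, ...) {
  cat("Total genome length estimate\n")
  cat(sprintf("  DKC total    : %.0f\n", x$dkc_total))
  cat(sprintf("  KRI          : %.4f\n", x$kri_estimate))
  cat(sprintf("  total length : %.0f bp\n", x$total_length))
  if (!is.na(x$ci_lower))
    cat(sprintf("  CI           : [%.0f, %.0f]\n", x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Read a genome set from multi-FASTA file(s)
#'
#' Each FASTA record becomes one species (record id = species_id) unless a
#' two-column TSV mapping (`record_id<TAB>species_id`) is given, in which
#' case records are grouped into multi-contig genomes by species.
#'
#' @param paths Character vector of FASTA paths (plain or gzipped).
#' @param species_map Optional path to a two-column TSV mapping record ids to
#'   species ids.
#' @return A [genome_set].
#' @export
read_genome_set <- function(paths, species_map = NULL) {
  seqs <- unlist(lapply(paths, read_sequences))
  if (is.null(species_map)) {
    gl <- as.list(seqs)
  } else {
    map <- utils::read.table(species_map, sep = "\t", header = FALSE,
                             col.names = c("record", "species"),
                             colClasses = "character")
    missing <- setdiff(names(seqs), map$record)
    if (length(missing) > 0)
      stop("records not in species map: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    sp <- map$species[match(names(seqs), map$record)]
    gl <- split(unname(seqs), sp)
  }
  genome_set(gl)
}
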