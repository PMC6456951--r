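#' Simulate a set of genomes with internal repeats
#'
#' Generates one synthetic genome per species: a random uniform-ACGT core of
#' length `genome_length * (1 - repeat_fraction)` followed by duplicated
#' segments copied from random positions of the core until the genome reaches
#' `genome_length`. Duplications make the genome's k-mer redundancy index
#' exceed 1 (roughly `1 / (1 - repeat_fraction)` up to segment-junction
#' effects); at `repeat_fraction = 0` random k-mers at k = 20 are essentially
#' unique (collision probability ~ L^2 / 4^20) so KRI is ~1.
#'
#' @param n_species Number of genomes (>= 1).
#' @param genome_length Length of each genome in bp.
#' @param repeat_fraction Fraction of each genome made of internal repeats,
#'   in `[0, 0.9]`. Default 0.1.
#' @param seed RNG seed; identical inputs give identical genomes.
#' @param segment_range Length range (min, max) of individual duplicated
#'   segments. Default c(500, 2000).
#' @return A [genome_set] with species ids `sp01`, `sp02`, ...
#' @export
simulate_genomes <- function(n_species, genome_length, repeat_fraction = 0.1,
                             seed = 1L, segment_range = c(500, 2000)) {
  n_species <- check_count(n_species, "n_species")
  genome_length <- check_count(genome_length, "genome_length", min = 2)
  if (!is.numeric(repeat_fraction) || repeat_fraction < 0 ||
      repeat_fraction > 0.9)
    stop("`repeat_fraction` must be in [0, 0.9]", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    genomes <- lapply(seq_len(n_species), function(i) {
      core_len <- max(round(genome_length * (1 - repeat_fraction)), 1)
      core <- paste(sample(bases, core_len, replace = TRUE), collapse = "")
      g <- core
      while (nchar(g) < genome_length) {
        want <- genome_length - nchar(g)
        len <- min(want, sample(segment_range[1]:segment_range[2], 1),
                   core_len)
        start <- sample.int(core_len - len + 1, 1)
        g <- paste0(g, substr(core, start, start + len - 1))
      }
      g
    })
    names(genomes) <- sprintf("sp%02d", seq_len(n_species))
    genome_set(genomes)
  })
}

#' Assign relative abundances by community complexity
#'
#' Three abundance profiles, defined by the number of dominant species:
#' \describe{
#'   \item{LC (low complexity)}{one dominant species at relative abundance
#'     0.6; the rest share 0.4 with geometric decay (ratio 0.7).}
#'   \item{MC (medium complexity)}{two dominant species at 0.45 and 0.30
#'     (jointly 0.75 > 0.7); the rest share 0.25 with geometric decay.}
#'   \item{HC (high complexity)}{no dominant species: symmetric
#'     Dirichlet(alpha = 5) draw, resampled (bounded) until the maximum
#'     abundance is below 3/G.}
#' }
#' Dominant species are chosen at random. Abundances are strictly positive
#' and sum to 1.
#'
#' @param n_species Number of species (>= 2; >= 3 for MC).
#' @param complexity One of `"LC"`, `"MC"`, `"HC"`.
#' @param seed RNG seed.
#' @return Numeric abundance vector of length `n_species` summing to 1.
#' @export
assign_abundances <- function(n_species, complexity = c("HC", "LC", "MC"),
                              seed = 1L) {
  n_species <- check_count(n_species, "n_species", min = 2)
  complexity <- match.arg(toupper(complexity), c("HC", "LC", "MC"))
  geom_tail <- function(n, total, ratio = 0.7) {
    w <- ratio^(seq_len(n) - 1)
    total * w / sum(w)
  }
  with_seed(seed, {
    ab <- switch(complexity,
      LC = {
        ab <- numeric(n_species)
        dom <- sample.int(n_species, 1)
        ab[dom] <- 0.6
        ab[-dom] <- sample(geom_tail(n_species - 1, 0.4))
        ab
      },
      MC = {
        if (n_species < 3) stop("MC needs n_species >= 3", call. = FALSE)
        ab <- numeric(n_species)
        dom <- sample.int(n_species, 2)
        ab[dom] <- c(0.45, 0.30)
        ab[-dom] <- sample(geom_tail(n_species - 2, 0.25))
        ab
      },
      HC = {
        limit <- 3 / n_species
        for (attempt in 1:100) {
          g <- rgamma(n_species, shape = 5)
          ab <- g / sum(g)
          if (max(ab) < limit) break
        }
        if (max(ab) >= limit)
          stop("could not draw an HC profile with max abundance < 3/G",
               call. = FALSE)
        ab
      })
    ab / sum(ab)
  })
}

#' Simulate a microbial community
#'
#' Bundles simulated genomes ([simulate_genomes()]) and abundances
#' ([assign_abundances()]) into a community object that serves as ground
#' truth for validating the estimator.
#'
#' @inheritParams simulate_genomes
#' @inheritParams assign_abundances
#' @return Object of class `community`: list with `genomes` (a
#'   [genome_set]), `abundances`, `complexity`, `seed`.
#' @export
simulate_community <- function(n_species, genome_length,
                               complexity = c("HC", "LC", "MC"),
                               repeat_fraction = 0.1, seed = 1L,
                               segment_range = c(500, 2000)) {
  complexity <- match.arg(toupper(complexity), c("HC", "LC", "MC"))
  gs <- simulate_genomes(n_species, genome_length, repeat_fraction,
                         seed = seed, segment_range = segment_range)
  ab <- assign_abundances(n_species, complexity, seed = seed + 1L)
  names(ab) <- names(gs$genomes)
  structure(list(genomes = gs, abundances = ab, complexity = complexity,
                 seed = as.integer(seed)),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat("Simulated community:", length(x$abundances), "species,",
      x$complexity, "complexity\n")
  cat("  abundances:", paste(sprintf("%.3f", sort(x$abundances,
                                                  decreasing = TRUE)[1:min(5, length(x$abundances))]),
                             collapse = " "),
      if (length(x$abundances) > 5) "..." else "", "\n")
  invisible(x)
}

#' Sample shotgun reads from a community
#'
#' Single-end, fixed-length reads. Each read's genome of origin is drawn with
#' probability proportional to abundance x genome length (the standard
#' shotgun model), its start position uniformly within the genome, from the
#' forward strand. Each base is independently substituted to a different base
#' with probability `error_rate`. Deterministic given `seed`.
#'
#' @param community A [simulate_community()] object.
#' @param n_reads Number of reads (>= 0).
#' @param read_length Read length in bp; every genome must be at least this
#'   long.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param seed RNG seed.
#' @return Object of class `read_sample`: list with `reads` (named character
#'   vector), `n_reads`, `read_length`, `error_rate`, `seed`, `community`.
#' @export
simulate_reads <- function(community, n_reads, read_length = 100,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(community, "community"))
  n_reads <- check_count(n_reads, "n_reads", min = 0)
  read_length <- check_count(read_length, "read_length")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.1)
    stop("`error_rate` must be in [0, 0.1]", call. = FALSE)
  seqs <- vapply(community$genomes$genomes, paste, character(1), collapse = "")
  lens <- nchar(seqs)
  if (any(lens < read_length))
    stop("genome(s) shorter than read_length: ",
         paste(names(seqs)[lens < read_length], collapse = ", "),
         call. = FALSE)
  if (n_reads == 0) {
    return(structure(list(reads = character(0), n_reads = 0L,
                          read_length = read_length, error_rate = error_rate,
                          seed = as.integer(seed), community = community),
                     class = "read_sample"))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    w <- community$abundances * lens
    gidx <- sample.int(length(seqs), n_reads, replace = TRUE,
                       prob = w / sum(w))
    starts <- floor(runif(n_reads) * (lens[gidx] - read_length + 1)) + 1
    reads <- character(n_reads)
    for (g in unique(gidx)) {
      sel <- gidx == g
      reads[sel] <- substring(seqs[g], starts[sel],
                              starts[sel] + read_length - 1)
    }
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(read_length, n_err[i])
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
        reads[i] <- paste(chars, collapse = "")
      }
    }
    names(reads) <- sprintf("read_%d", seq_len(n_reads))
    structure(list(reads = reads, n_reads = as.integer(n_reads),
                   read_length = read_length, error_rate = error_rate,
                   seed = as.integer(seed), community = community),
              class = "read_sample")
  })
}

#' @export
print.read_sample <- function(x, ...) {
  cat("Read sample:", x$n_reads, "reads x", x$read_length, "bp, error rate",
      x$error_rate, "\n")
  invisible(x)
}

#' Initial coverage of a community by a sample
#'
#' The fraction of distinct k-mers of the community's distinct genome set
#' that appear in the sequencing sample:
#' `|distinct(sample) ∩ distinct(genomes)| / dkc_union`. Both sides must use
#' the same k and canonicalization; a convention mismatch with an annotated
#' genome set is an error.
#'
#' @param sample A `read_sample`, named character vector, or `DNAStringSet`.
#' @param genomes A [genome_set] or [simulate_community()] object.
#' @param k,canonical Counting convention.
#' @return Fraction in `[0, 1]` (0 for an empty sample).
#' @export
initial_coverage <- function(sample, genomes, k = 20, canonical = TRUE) {
  k <- check_count(k, "k")
  canonical <- check_flag(canonical, "canonical")
  if (inherits(genomes, "community")) genomes <- genomes$genomes
  gs <- genome_set(genomes)
  if (!is.null(gs$k) && (gs$k != k || gs$canonical != canonical))
    stop("counting convention mismatch: genome set was computed with k = ",
         gs$k, ", canonical = ", gs$canonical, call. = FALSE)
  if (inherits(sample, "read_sample")) sample <- sample$reads
  if (length(sample) == 0) return(0)
  sample <- as_sequence_set(sample, "read")
  ov <- cpp_kmer_overlap(unname(sample), unname(flatten_genomes(gs)),
                         k, canonical)
  if (ov$genome_dkc == 0) stop("genome set has no valid k-mers", call. = FALSE)
  ov$shared / ov$genome_dkc
}

#' Ground-truth quantities of a simulated community
#'
#' @param community A [simulate_community()] object.
#' @param k,canonical Counting convention for the truth values.
#' @return List with `dkc_true` (distinct k-mers of the genome union),
#'   `tkc_true` (total windows, `sum(L_g - k + 1)`), `total_length_true`
#'   (= `tkc_true`, the quantity the estimator targets), `kri_true`,
#'   `genome_lengths`, `abundances`.
#' @export
community_truth <- function(community, k = 20, canonical = TRUE) {
  stopifnot(inherits(community, "community"))
  gs <- kri_of_genome_set(community$genomes, k = k, canonical = canonical)
  list(dkc_true = gs$dkc_union,
       tkc_true = gs$tkc_union,
       total_length_true = gs$tkc_union,
       kri_true = gs$kri,
       genome_lengths = vapply(gs$genomes, function(s) sum(nchar(s)),
                               numeric(1)),
       abundances = community$abundances)
}

#' Signed relative error
#'
#' `(estimate - truth) / truth`; positive means overestimation.
#'
#' @param estimate Estimated value(s).
#' @param truth True value(s), all > 0.
#' @return Signed fraction(s).
#' @export
relative_error <- function(estimate, truth) {
  if (any(!is.finite(truth)) || any(truth <= 0))
    stop("`truth` must be positive", call. = FALSE)
  (estimate - truth) / truth
}

#' Write a simulated community and sample to disk
#'
#' Writes `genomes.fasta`, `reads.fastq` (constant quality 'I') and
#' `truth.json` (true DKC, true total length, KRI, abundances, achieved
#' initial coverage) into `out_dir`.
#'
#' @param community A [simulate_community()] object.
#' @param sample A [simulate_reads()] object.
#' @param out_dir Output directory (created if missing).
#' @param k,canonical Convention used for the truth values.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(community, sample, out_dir, k = 20,
                             canonical = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- flatten_genomes(community$genomes)
  writeLines(as.vector(rbind(paste0(">", names(genomes)), unname(genomes))),
             file.path(out_dir, "genomes.fasta"))
  fq <- as.vector(rbind(paste0("@", names(sample$reads)),
                        unname(sample$reads),
                        "+",
                        strrep("I", nchar(sample$reads))))
  writeLines(fq, file.path(out_dir, "reads.fastq"))
  truth <- community_truth(community, k = k, canonical = canonical)
  truth$initial_coverage <- initial_coverage(sample, community, k = k,
                                             canonical = canonical)
  truth$k <- k
  truth$canonical <- canonical
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
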