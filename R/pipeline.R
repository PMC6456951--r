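#' Run the full estimation pipeline
#'
#' Orchestrates spectrum -> total-DKC estimate -> KRI -> total length. Input
#' is either raw reads (FASTA/FASTQ path, character vector, `DNAStringSet`,
#' or `read_sample`) or a precomputed histogram (path to a jellyfish-style
#' `histo` file or a [kmer_spectrum]). A genome set is required only for the
#' KRI/total-length stages; without one, a partial (estimate-only) report is
#' produced with a warning. All stages share one k and one canonicalization
#' setting; mismatches abort before computation.
#'
#' @param reads Reads input (path or sequences), or `NULL`.
#' @param histo Histogram input (path or [kmer_spectrum]), or `NULL`.
#'   Exactly one of `reads`/`histo` must be given.
#' @param genomes Optional genome set input (path(s) to FASTA, named
#'   list/vector, or [genome_set]).
#' @param k,canonical Counting convention (defaults 20, `TRUE`).
#' @param max_points,n_bootstrap,ci_level,seed Estimator options, see
#'   [estimate_total_dkc()].
#' @param out Optional path: write the report as JSON.
#' @return Object of class `metaglen_report`: list with `spectrum_summary`,
#'   `estimate`, `genome_set_summary`, `kri`, `total_length`, `warnings`,
#'   `config`.
#' @export
run_pipeline <- function(reads = NULL, histo = NULL, genomes = NULL,
                         k = 20, canonical = TRUE, max_points = 10,
                         n_bootstrap = 0, ci_level = 0.95, seed = 1L,
                         out = NULL) {
  if (is.null(reads) == is.null(histo))
    stop("pipeline input error: supply exactly one of `reads` or `histo`",
         call. = FALSE)
  k <- check_count(k, "k")
  canonical <- check_flag(canonical, "canonical")
  warnings <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  spectrum <- stage("spectrum", {
    if (!is.null(histo)) {
      sp <- if (inherits(histo, "kmer_spectrum")) histo else
        read_histo(histo, k = k, canonical = canonical)
      if (sp$k != k || sp$canonical != canonical)
        stop("histogram convention (k = ", sp$k, ", canonical = ",
             sp$canonical, ") does not match the run config")
      sp
    } else {
      seqs <- if (is.character(reads) && length(reads) == 1 &&
                  file.exists(reads)) read_sequences(reads) else reads
      count_kmers(seqs, k = k, canonical = canonical)
    }
  })
  st <- spectrum_stats(spectrum)

  estimate <- stage("estimate", withCallingHandlers(
    estimate_total_dkc(spectrum, max_points = max_points,
                       n_bootstrap = n_bootstrap, ci_level = ci_level,
                       seed = seed),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }))

  gs <- NULL
  tl <- NULL
  if (!is.null(genomes)) {
    gs <- stage("kri", {
      g <- if (is.character(genomes) && all(file.exists(genomes)))
        read_genome_set(genomes) else genome_set(genomes)
      if (!is.null(g$k) && (g$k != k || g$canonical != canonical))
        stop("genome set convention (k = ", g$k, ") does not match the run")
      kri_of_genome_set(g, k = k, canonical = canonical)
    })
    tl <- stage("length", total_length(estimate, gs$kri))
  } else {
    warnings <- c(warnings,
                  "no genome set supplied: KRI and total length not computed")
  }

  report <- structure(list(
    spectrum_summary = list(tkc = st$tkc, dkc = st$dkc, kri = st$kri,
                            max_freq = max(spectrum$freq)),
    estimate = estimate,
    genome_set_summary = if (!is.null(gs))
      list(n_species = length(gs$genomes), tkc_union = gs$tkc_union,
           dkc_union = gs$dkc_union),
    kri = if (!is.null(gs)) gs$kri,
    total_length = tl,
    warnings = warnings,
    version = as.character(utils::packageVersion("metaglen")),
    config = list(k = k, canonical = canonical, max_points = max_points,
                  n_bootstrap = n_bootstrap, ci_level = ci_level,
                  seed = as.integer(seed))
  ), class = "metaglen_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass_report(report), out, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  report
}

# strip S3 classes so jsonlite serializes cleanly
unclass_report <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_report) else x
}

#' @export
print.metaglen_report <- function(x, ...) {
  cat("metaglen report (k = ", x$config$k, ", ",
      if (x$config$canonical) "canonical" else "stranded", ")\n", sep = "")
  cat(sprintf("  sample: TKC = %.0f, DKC = %.0f\n",
              x$spectrum_summary$tkc, x$spectrum_summary$dkc))
  cat(sprintf("  estimated total DKC: %.0f (uncaptured %.0f)\n",
              x$estimate$dkc_total, x$estimate$uncaptured))
  if (!is.null(x$total_length))
    cat(sprintf("  KRI = %.4f  =>  total genome length ~ %.0f bp\n",
                x$kri, x$total_length$total_length))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run a simulation validation grid
#'
#' Drives the simulator + estimator over a grid of
#' species-count x complexity x depth x seed cells. Each (species,
#' complexity, seed) triple defines one community; each depth (number of
#' reads) defines one sample from it. One row per cell reports the
#' parameters, the achieved initial coverage, true and estimated total DKC,
#' bootstrap CI bounds (if requested) and the signed relative error. Cell
#' failures are recorded in the `error` column and the grid continues.
#'
#' @param n_species Vector of species counts.
#' @param complexities Vector of complexity labels (`"LC"`, `"MC"`, `"HC"`).
#' @param n_reads Vector of per-sample read counts (depth levels).
#' @param seeds Vector of integer seeds.
#' @param genome_length,repeat_fraction,read_length,error_rate Simulator
#'   settings (shared across the grid).
#' @param k,canonical,max_points,n_bootstrap Estimator settings.
#' @param out Optional path: write the table as TSV.
#' @return A data.frame, one row per grid cell.
#' @export
run_validation_grid <- function(n_species, complexities, n_reads, seeds,
                                genome_length = 1e5, repeat_fraction = 0.1,
                                read_length = 100, error_rate = 0,
                                k = 20, canonical = TRUE, max_points = 10,
                                n_bootstrap = 0, out = NULL) {
  cells <- expand.grid(n_species = n_species, complexity = complexities,
                       n_reads = n_reads, seed = seeds,
                       stringsAsFactors = FALSE)
  if (nrow(cells) == 0) stop("empty grid", call. = FALSE)
  rows <- vector("list", nrow(cells))
  cache <- new.env()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows[[i]] <- tryCatch({
      key <- paste(cell$n_species, cell$complexity, cell$seed, sep = "_")
      if (is.null(cache[[key]])) {
        comm <- simulate_community(cell$n_species, genome_length,
                                   cell$complexity,
                                   repeat_fraction = repeat_fraction,
                                   seed = cell$seed)
        cache[[key]] <- list(comm = comm,
                             truth = community_truth(comm, k = k,
                                                     canonical = canonical))
      }
      comm <- cache[[key]]$comm
      truth <- cache[[key]]$truth
      sample <- simulate_reads(comm, cell$n_reads, read_length = read_length,
                               error_rate = error_rate,
                               seed = cell$seed + 1000L)
      cov <- initial_coverage(sample, comm, k = k, canonical = canonical)
      spec <- count_kmers(sample, k = k, canonical = canonical)
      est <- suppressWarnings(
        estimate_total_dkc(spec, max_points = max_points,
                           n_bootstrap = n_bootstrap, seed = cell$seed))
      data.frame(cell,
                 initial_coverage = cov,
                 dkc_true = truth$dkc_true,
                 dkc_observed = est$dkc_observed,
                 dkc_estimated = est$dkc_total,
                 ci_lower = est$ci_lower, ci_upper = est$ci_upper,
                 rel_error = relative_error(est$dkc_total, truth$dkc_true),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(cell, initial_coverage = NA, dkc_true = NA,
                 dkc_observed = NA, dkc_estimated = NA,
                 ci_lower = NA, ci_upper = NA, rel_error = NA,
                 error = conditionMessage(e))
    })
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
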