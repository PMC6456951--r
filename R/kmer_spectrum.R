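#' Construct a k-mer frequency spectrum
#'
#' A k-mer frequency spectrum records, for each multiplicity `j >= 1`, the
#' number `n_j` of distinct k-mers observed exactly `j` times in a sample.
#' The spectrum carries the k-mer size `k` and the counting convention
#' (`canonical`: whether a k-mer and its reverse complement are collapsed to
#' one key). Two summary statistics derive from it: the total k-mer count
#' TKC = sum(j * n_j) (the number of k-length windows counted) and the
#' distinct k-mer count DKC = sum(n_j).
#'
#' Counts are usually integers (from [count_kmers()]), but fractional counts
#' are accepted so that exact *expected* spectra of known Poisson mixtures can
#' be analysed directly.
#'
#' @param freq Integer vector of multiplicities `j` (strictly increasing,
#'   all `>= 1`).
#' @param count Numeric vector of counts `n_j >= 0`, same length as `freq`.
#'   Zero-count classes are dropped.
#' @param k k-mer size.
#' @param canonical Logical; reverse-complement collapsing convention.
#' @return An object of class `kmer_spectrum`: a list with elements `freq`,
#'   `count`, `k`, `canonical`.
#' @seealso [count_kmers()], [spectrum_stats()], [read_histo()]
#' @export
kmer_spectrum <- function(freq, count, k, canonical = TRUE) {
  k <- check_count(k, "k")
  canonical <- check_flag(canonical, "canonical")
  if (length(freq) != length(count))
    stop("`freq` and `count` must have the same length", call. = FALSE)
  if (length(freq) == 0) stop("empty spectrum", call. = FALSE)
  if (any(is.na(freq)) || any(freq < 1) || any(freq != as.integer(freq)))
    stop("`freq` must contain positive integers", call. = FALSE)
  if (is.unsorted(freq, strictly = TRUE))
    stop("`freq` must be strictly increasing", call. = FALSE)
  if (any(is.na(count)) || any(count < 0))
    stop("`count` must be non-negative", call. = FALSE)
  keep <- count > 0
  if (!any(keep)) stop("empty spectrum (all counts zero)", call. = FALSE)
  structure(
    list(freq = as.integer(freq[keep]), count = as.numeric(count[keep]),
         k = k, canonical = canonical),
    class = "kmer_spectrum"
  )
}

#' Count k-mers in a set of sequences
#'
#' Slides a window of length `k` over every sequence and tabulates the
#' multiplicity of each k-mer, returning the frequency spectrum. Windows
#' containing `N` are skipped entirely; lowercase bases are counted
#' (case-insensitive); any symbol other than A, C, G, T, N is an error naming
#' the offending record. With `canonical = TRUE` a k-mer and its reverse
#' complement count as the same key (the convention for unstranded read
#' data); genome-set KRI computation and metagenome DKC estimation must use
#' the same convention.
#'
#' @param sequences Named character vector of DNA sequences, a
#'   `DNAStringSet`, or a `read_sample` from [simulate_reads()].
#' @param k k-mer size, between 1 and 31 (2-bit packed counting). Default 20.
#' @param canonical Collapse reverse complements? Default `TRUE`.
#' @return A [kmer_spectrum].
#' @examples
#' s <- count_kmers(c(seq1 = "ACGTACGTACGT"), k = 6, canonical = FALSE)
#' spectrum_stats(s)  # TKC 7, DKC 4, KRI 1.75
#' @export
count_kmers <- function(sequences, k = 20, canonical = TRUE) {
  k <- check_count(k, "k")
  if (k > 31) stop("k must be <= 31", call. = FALSE)
  canonical <- check_flag(canonical, "canonical")
  seqs <- as_sequence_set(sequences)
  if (max(nchar(seqs)) < k)
    stop("k = ", k, " is too large: no sequence of length >= k", call. = FALSE)
  res <- cpp_count_kmers(unname(seqs), names(seqs), k, canonical)
  if (length(res$freq) == 0)
    stop("no valid k-mer windows (all windows contain N?)", call. = FALSE)
  kmer_spectrum(res$freq, res$count, k = k, canonical = canonical)
}

#' Summary statistics of a k-mer spectrum
#'
#' @param spectrum A [kmer_spectrum].
#' @return A list with `tkc` (total k-mer count, sum of j*n_j), `dkc`
#'   (distinct k-mer count, sum of n_j) and `kri` (k-mer redundancy index,
#'   TKC/DKC, always >= 1; equals 1 exactly when every k-mer is unique).
#' @export
spectrum_stats <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  dkc <- sum(spectrum$count)
  tkc <- sum(spectrum$freq * spectrum$count)
  if (dkc <= 0) stop("empty spectrum", call. = FALSE)
  list(tkc = tkc, dkc = dkc, kri = tkc / dkc)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  st <- spectrum_stats(x)
  cat("k-mer frequency spectrum (k = ", x$k, ", ",
      if (x$canonical) "canonical" else "stranded", ")\n", sep = "")
  cat("  frequency classes:", length(x$freq),
      " max multiplicity:", max(x$freq), "\n")
  cat(sprintf("  TKC = %.0f  DKC = %.0f  KRI = %.4f\n",
              st$tkc, st$dkc, st$kri))
  invisible(x)
}

#' Import / export jellyfish-style k-mer histograms
#'
#' The `histo` format is two whitespace-separated columns per line: the
#' multiplicity `j` (strictly increasing) and the count `n_j`. On write, the
#' k-mer size and counting convention are recorded in a comment header line
#' (`# k=<k> canonical=<TRUE|FALSE>`); on read the header is optional, in
#' which case `k` must be supplied. Round-trips are lossless.
#'
#' @param path File path.
#' @param k,canonical Counting convention; required on read when the file has
#'   no metadata header, ignored (with a warning on mismatch) otherwise.
#' @return `read_histo()` returns a [kmer_spectrum]; `write_histo()` returns
#'   `path` invisibly.
#' @export
read_histo <- function(path, k = NULL, canonical = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  header_k <- NULL
  header_canon <- NULL
  freq <- numeric(0)
  count <- numeric(0)
  last_j <- 0
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      mk <- regmatches(ln, regexec("k=([0-9]+)", ln))[[1]]
      if (length(mk) == 2) header_k <- as.integer(mk[2])
      mc <- regmatches(ln, regexec("canonical=(TRUE|FALSE|true|false)", ln))[[1]]
      if (length(mc) == 2) header_canon <- toupper(mc[2]) == "TRUE"
      next
    }
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop("histo parse error at line ", i, ": expected two columns",
           call. = FALSE)
    j <- suppressWarnings(as.numeric(parts[1]))
    n <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(j) || is.na(n) || j != round(j) || j < 1)
      stop("histo parse error at line ", i, ": bad frequency '", parts[1], "'",
           call. = FALSE)
    if (n < 0)
      stop("histo parse error at line ", i, ": negative count", call. = FALSE)
    if (j <= last_j)
      stop("histo parse error at line ", i,
           ": frequencies must be strictly increasing", call. = FALSE)
    last_j <- j
    freq <- c(freq, j)
    count <- c(count, n)
  }
  if (length(freq) == 0) stop("no data lines in histo file", call. = FALSE)
  k_use <- if (!is.null(header_k)) header_k else k
  if (is.null(k_use))
    stop("histo file has no k= header; supply `k`", call. = FALSE)
  if (!is.null(header_k) && !is.null(k) && header_k != k)
    stop("k mismatch: file header says k=", header_k, " but k=", k,
         " was requested", call. = FALSE)
  canon_use <- if (!is.null(header_canon)) header_canon else canonical
  if (is.null(canon_use)) canon_use <- TRUE
  if (!is.null(header_canon) && !is.null(canonical) &&
      header_canon != canonical)
    stop("canonicalization mismatch between file header and request",
         call. = FALSE)
  kmer_spectrum(freq, count, k = k_use, canonical = canon_use)
}

#' @rdname read_histo
#' @param spectrum A [kmer_spectrum] to write.
#' @export
write_histo <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# metaglen histo k=%d canonical=%s",
                     spectrum$k, spectrum$canonical), con)
  writeLines(sprintf("%d %.10g", spectrum$freq, spectrum$count), con)
  invisible(path)
}
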