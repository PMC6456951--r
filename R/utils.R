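# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce reads/genomes input to a named character vector of sequences.
# Accepts a character vector, a Biostrings::DNAStringSet/XStringSet, or a
# read_sample object. Enforces the sequence-set invariants: non-empty
# sequences, unique identifiers.
as_sequence_set <- function(x, what = "sequence") {
  if (inherits(x, "read_sample")) x <- x$reads
  if (inherits(x, "XStringSet")) {
    nms <- names(x)
    x <- as.character(x)
    names(x) <- nms
  }
  if (!is.character(x))
    stop("expected a character vector or DNAStringSet of ", what, "s",
         call. = FALSE)
  if (length(x) == 0) stop("empty ", what, " set", call. = FALSE)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- ifelse(is.null(names(x)) | names(x) == "" | is.na(names(x)),
                       paste0(what, "_", seq_along(x)),
                       names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate ", what, " identifiers: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (any(nchar(x) == 0)) {
    bad <- names(x)[nchar(x) == 0][1]
    stop("empty sequence in record '", bad, "'", call. = FALSE)
  }
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x))
    stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x))
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that autodetects
#' FASTA vs FASTQ (by first non-empty character, `>` vs `@`), handles gzipped
#' input, and returns a named character vector of sequences. FASTQ qualities
#' are ignored.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @param format `"auto"` (default), `"fasta"`, or `"fastq"`.
#' @return Named character vector of DNA sequences.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    first <- ""
    while (!nzchar(first)) {
      line <- readLines(con, n = 1)
      if (length(line) == 0) stop("empty sequence file: ", path, call. = FALSE)
      first <- trimws(line)
    }
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  dss <- Biostrings::readDNAStringSet(path, format = format)
  # keep only the first whitespace token of the header, like most tools
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  as_sequence_set(out, "read")
}
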