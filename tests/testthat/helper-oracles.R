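# Independent brute-force oracles used across the suite.

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Naive k-mer counter: enumerate every substring, drop windows with N,
# optionally canonicalize, then tabulate. Independent of the C++ path.
naive_kmer_table <- function(seqs, k, canonical) {
  kmers <- unlist(lapply(toupper(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("N", w, fixed = TRUE)]
  }))
  if (length(kmers) == 0) return(table(character(0)))
  if (canonical) kmers <- pmin(kmers, revcomp_chr(kmers))
  table(kmers)
}

naive_spectrum <- function(seqs, k, canonical) {
  tab <- naive_kmer_table(seqs, k, canonical)
  mult <- table(as.integer(tab))
  list(freq = as.integer(names(mult)), count = as.numeric(mult),
       tkc = sum(tab), dkc = length(tab))
}

random_dna <- function(n, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  paste(sample(alphabet, n, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}

# Raw moments of a discrete measure sum_i mass_i * delta(atom_i)
discrete_moments <- function(atoms, masses, n_moments) {
  vapply(0:(n_moments - 1), function(j) sum(masses * atoms^j), numeric(1))
}

# Exact expected k-mer frequency spectrum of a Poisson mixture:
# each of the N_i k-mers of component i is seen Poisson(lambda_i) times.
poisson_mixture_spectrum <- function(N, lambda, max_j = 30, k = 20) {
  counts <- vapply(1:max_j, function(j)
    sum(N * exp(-lambda) * lambda^j / factorial(j)), numeric(1))
  kmer_spectrum(1:max_j, counts, k = k)
}
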