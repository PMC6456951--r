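Package: metaglen
Title: Total Genome Length Estimation for Metagenomes from k-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the total length of all distinct genomes in a shotgun
    metagenomic sample. The number of distinct k-mers in the underlying
    metagenome (observed plus uncaptured) is estimated by treating per-k-mer
    sequencing counts as a Poisson mixture and solving the resulting moment
    problem with Gaussian quadrature (Golub-Welsch), with bootstrap confidence
    intervals. A k-mer redundancy index (KRI), computed from a set of detected
    or reference genomes, converts the distinct k-mer count into total genome
    length. Includes a native k-mer counter, jellyfish 'histo' import/export,
    and a metagenome community simulator (low/medium/high complexity abundance
    profiles, substitution errors, genomes with internal repeats) used to
    validate the method end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
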