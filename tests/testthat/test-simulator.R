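test_that("genome simulation is seeded and repeat-aware", {
  g1 <- simulate_genomes(3, 5000, repeat_fraction = 0.2, seed = 4)
  g2 <- simulate_genomes(3, 5000, repeat_fraction = 0.2, seed = 4)
  expect_identical(g1$genomes, g2$genomes)
  g3 <- simulate_genomes(3, 5000, repeat_fraction = 0.2, seed = 5)
  expect_false(identical(g1$genomes, g3$genomes))
  expect_true(all(nchar(unlist(g1$genomes)) == 5000))

  # repeat-free random genomes have KRI ~ 1 at k = 20 (4^20 birthday bound)
  flat <- kri_of_genome_set(simulate_genomes(2, 5e4, 0, seed = 1), k = 20)
  expect_equal(flat$kri, 1, tolerance = 1e-4)

  # one exact full duplication of the core doubles TKC over DKC
  core_dup <- simulate_genomes(1, 1e5, repeat_fraction = 0.5, seed = 8,
                               segment_range = c(50000, 50000))
  dup <- kri_of_genome_set(core_dup, k = 20)
  expect_equal(dup$kri, 2, tolerance = 0.01)

  # repeats push KRI strictly above 1
  rep_gs <- kri_of_genome_set(simulate_genomes(2, 2e4, 0.3, seed = 1), k = 20)
  expect_gt(rep_gs$kri, 1.2)

  expect_error(simulate_genomes(2, 1000, repeat_fraction = 0.95), "0.9")
})

test_that("abundance profiles satisfy the complexity definitions", {
  for (seed in 1:20) {
    lc <- assign_abundances(10, "LC", seed = seed)
    expect_equal(sum(lc), 1, tolerance = 1e-9)
    expect_true(all(lc > 0))
    expect_equal(max(lc), 0.6)              # exactly one dominant species
    expect_equal(sum(lc > 0.5), 1)

    mc <- assign_abundances(10, "MC", seed = seed)
    expect_equal(sum(mc), 1, tolerance = 1e-9)
    top2 <- sum(sort(mc, decreasing = TRUE)[1:2])
    expect_gt(top2, 0.70)                   # two dominants above 70% jointly
    expect_equal(top2, 0.75, tolerance = 1e-9)

    hc <- assign_abundances(50, "HC", seed = seed)
    expect_equal(sum(hc), 1, tolerance = 1e-9)
    expect_lt(max(hc), 3 / 50)              # no dominant species
  }
  expect_error(assign_abundances(2, "MC"), "n_species >= 3")
  expect_error(assign_abundances(10, "XX"), "arg")
})

test_that("HC draws stay below 3/G across many seeds", {
  maxima <- vapply(1:100, function(s) max(assign_abundances(50, "HC", s)),
                   numeric(1))
  expect_true(all(maxima < 0.06))
})

test_that("read simulation honors the shotgun model", {
  comm <- simulate_community(4, 8000, "HC", repeat_fraction = 0, seed = 21)
  s1 <- simulate_reads(comm, 500, 90, 0, seed = 3)
  s2 <- simulate_reads(comm, 500, 90, 0, seed = 3)
  expect_identical(s1$reads, s2$reads)
  expect_true(all(nchar(s1$reads) == 90))

  # error-free reads are exact substrings of some genome
  genomes <- vapply(comm$genomes$genomes, paste, character(1), collapse = "")
  hits <- vapply(s1$reads[1:50], function(r)
    any(vapply(genomes, function(g) grepl(r, g, fixed = TRUE), logical(1))),
    logical(1))
  expect_true(all(hits))

  expect_equal(simulate_reads(comm, 0, 90, 0, seed = 1)$n_reads, 0L)
  expect_error(simulate_reads(comm, 10, 10000, 0, seed = 1), "shorter")
  expect_error(simulate_reads(comm, 10, 90, 0.5, seed = 1), "error_rate")
})

test_that("substitution errors hit the binomial mean", {
  comm <- simulate_community(2, 5000, "HC", repeat_fraction = 0, seed = 30)
  clean <- simulate_reads(comm, 10000, 100, 0, seed = 12)
  noisy <- simulate_reads(comm, 10000, 100, 0.01, seed = 12)
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$reads, noisy$reads)
  expect_equal(mean(mism), 1.0, tolerance = 0.05)  # 100 bp x 0.01
})

test_that("initial coverage behaves at its extremes and is monotone", {
  comm <- simulate_community(3, 6000, "HC", repeat_fraction = 0.1, seed = 40)
  genomes <- vapply(comm$genomes$genomes, paste, character(1), collapse = "")

  expect_equal(initial_coverage(genomes, comm, k = 20), 1.0)
  expect_equal(initial_coverage(character(0), comm, k = 20), 0)

  # deep error-free sample covers nearly everything
  deep <- simulate_reads(comm, 6000, 100, 0, seed = 41)  # ~33x depth
  expect_gte(initial_coverage(deep, comm, k = 20), 0.99)

  # nested samples: coverage is non-decreasing as reads are appended
  all_reads <- simulate_reads(comm, 900, 100, 0, seed = 42)$reads
  covs <- vapply(c(100, 300, 900), function(n)
    initial_coverage(all_reads[seq_len(n)], comm, k = 20), numeric(1))
  expect_true(all(diff(covs) >= 0))

  # convention mismatch against an annotated genome set
  gs <- kri_of_genome_set(comm$genomes, k = 15)
  expect_error(initial_coverage(deep, gs, k = 20), "mismatch")
})

test_that("evenness helps: HC communities are estimated better than MC", {
  # with two species hogging 75% of the reads, the rare-species tail of an
  # MC community is poorly covered and the estimate degrades relative to HC
  err <- sapply(c("MC", "HC"), function(cx) {
    vapply(1:6, function(seed) {
      comm <- simulate_community(10, 5e4, cx, repeat_fraction = 0.1,
                                 seed = seed)
      truth <- community_truth(comm, k = 20)
      s <- simulate_reads(comm, 5000, 100, 0, seed = seed + 500)
      est <- suppressWarnings(estimate_total_dkc(count_kmers(s, 20, TRUE)))
      abs(relative_error(est$dkc_total, truth$dkc_true))
    }, numeric(1))
  })
  expect_lte(mean(err[, "HC"]), mean(err[, "MC"]))
})

test_that("relative error is the signed fraction", {
  expect_equal(relative_error(110, 100), 0.10)
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(95, 100), -0.05)
  expect_error(relative_error(1, 0), "positive")
})

test_that("simulation output files are deterministic and self-consistent", {
  comm <- simulate_community(3, 4000, "LC", repeat_fraction = 0.1, seed = 50)
  s <- simulate_reads(comm, 200, 80, 0, seed = 51)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(comm, s, d1, k = 15)
  write_simulation(comm, s, d2, k = 15)
  expect_identical(readLines(file.path(d1, "genomes.fasta")),
                   readLines(file.path(d2, "genomes.fasta")))
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  gs <- kri_of_genome_set(comm$genomes, k = 15)
  expect_equal(truth$dkc_true, gs$dkc_union)
  expect_equal(truth$total_length_true, gs$tkc_union)
  # reads round-trip through the FASTQ reader
  back <- read_sequences(file.path(d1, "reads.fastq"))
  expect_identical(unname(back), unname(s$reads))
})
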