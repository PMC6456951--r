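test_that("moments follow m_j = (j+1)! n_{j+1}", {
  m <- moments_from_spectrum(kmer_spectrum(c(1, 2), c(10, 5), k = 20))
  expect_equal(m$values, c(10, 10))  # 1!*10, 2!*5

  m <- moments_from_spectrum(kmer_spectrum(1:3, c(6, 3, 1), k = 20))
  expect_equal(m$values, c(6, 6, 6))

  # truncation: multiplicities above max_moments contribute no moments
  m <- moments_from_spectrum(kmer_spectrum(c(1, 2, 30), c(6, 3, 99), k = 20),
                             max_moments = 4)
  expect_equal(m$values, c(6, 6))

  expect_error(
    moments_from_spectrum(kmer_spectrum(5, 1000, k = 20)),
    "no singletons")
})

test_that("Poisson sample moments match the closed-form expectation", {
  # spectrum sampled from N distinct k-mers with rate lambda = 2;
  # E m_j = (j+1)! E n_{j+1} = N e^{-2} 2^{j+1}
  N <- 1e5
  lambda <- 2
  set.seed(99)
  x <- rpois(N, lambda)
  tab <- table(x[x > 0])
  spec <- kmer_spectrum(as.integer(names(tab)), as.numeric(tab), k = 20)
  m <- moments_from_spectrum(spec, max_moments = 6)
  expected <- N * exp(-lambda) * lambda^(1:6)
  expect_equal(m$values, expected, tolerance = 0.05)
})

test_that("golub_welsch recovers known discrete measures", {
  # one-point measure alpha * delta_lambda, moments alpha * lambda^j
  alpha <- 367.879441
  r <- golub_welsch(alpha * 1.0^(0:1), n_points = 1)
  expect_equal(r$nodes, 1.0, tolerance = 1e-12)
  expect_equal(r$weights, alpha, tolerance = 1e-12)

  r <- golub_welsch(c(6, 6, 6), n_points = 1)
  expect_equal(r$nodes, 1.0)     # m_1 / m_0
  expect_equal(r$weights, 6.0)

  # two-point measure 100 delta_0.5 + 50 delta_3, recovered to >= 8 digits
  m <- discrete_moments(c(0.5, 3), c(100, 50), 4)
  r <- golub_welsch(m, n_points = 2)
  expect_equal(r$nodes, c(0.5, 3.0), tolerance = 1e-9)
  expect_equal(r$weights, c(100, 50), tolerance = 1e-9)
})

test_that("quadrature exactness holds for random discrete measures", {
  set.seed(5)
  for (rep in 1:20) {
    P <- sample(1:5, 1)
    atoms <- sort(runif(P, 0.2, 8))
    # keep atoms separated so the measure is honestly P-atomic
    if (P > 1 && min(diff(atoms)) < 0.1) next
    masses <- runif(P, 10, 1000)
    m <- discrete_moments(atoms, masses, 2 * P)
    r <- golub_welsch(m, n_points = P)
    expect_equal(r$n_points, P)
    expect_equal(r$nodes, atoms, tolerance = 1e-7)
    expect_equal(r$weights, masses, tolerance = 1e-7)
    # weights sum to the zeroth moment; rule reproduces all input moments
    expect_equal(sum(r$weights), m[1], tolerance = 1e-8)
    repro <- vapply(0:(2 * P - 1), function(j) sum(r$weights * r$nodes^j),
                    numeric(1))
    expect_equal(repro, m, tolerance = 1e-6)
    # and the harmonic-moment estimate matches the closed form
    expect_equal(sum(r$weights / r$nodes), sum(masses / atoms),
                 tolerance = 1e-8)
  }
})

test_that("golub_welsch enforces its preconditions and fails loudly", {
  expect_error(golub_welsch(c(6, 6, 6), n_points = 2), "2\\*n_points")
  # m_1 = 0 forces a node at zero at every P: no valid rule exists
  expect_error(golub_welsch(c(1, 0, 5, 0), n_points = 2, allow_fewer = TRUE),
               "positive measure")
})

test_that("closed-form Poisson mixtures are recovered within 1%", {
  # homogeneous: N = 1e5 k-mers at lambda = 1 -> uncaptured = N e^{-1}
  spec <- poisson_mixture_spectrum(1e5, 1)
  est <- estimate_uncaptured(spec)
  expect_equal(est$value, 1e5 * exp(-1), tolerance = 0.01)

  # two-point mixture
  spec2 <- poisson_mixture_spectrum(c(1e4, 1e4), c(0.5, 4))
  est2 <- estimate_uncaptured(spec2)
  expect_equal(est2$value, 1e4 * (exp(-0.5) + exp(-4)), tolerance = 0.01)

  # total DKC adds the observed part: observed ~ N(1 - e^{-1})
  tot <- estimate_total_dkc(spec)
  expect_equal(tot$dkc_total, 1e5, tolerance = 0.01)
  expect_gte(tot$uncaptured, 0)
  expect_gte(tot$dkc_total, tot$dkc_observed)

  # degenerate: single frequency class with no singletons
  expect_error(estimate_uncaptured(kmer_spectrum(5, 1000, k = 20)),
               "no singletons")
})

test_that("deeply covered spectra yield negligible uncaptured counts", {
  spec <- kmer_spectrum(c(1, 2, 29, 30, 31), c(1, 1, 200, 600, 200), k = 20)
  est <- suppressWarnings(estimate_total_dkc(spec))
  expect_lt(est$uncaptured / est$dkc_observed, 0.05)
})

test_that("the estimate is linear in the spectrum scale", {
  spec <- poisson_mixture_spectrum(c(2e4, 1e4), c(0.8, 3))
  base <- estimate_uncaptured(spec)$value
  for (c_scale in c(0.5, 3, 10)) {
    scaled <- kmer_spectrum(spec$freq, spec$count * c_scale, k = spec$k)
    expect_equal(estimate_uncaptured(scaled)$value, c_scale * base,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap intervals are seeded, ordered, and calibrated", {
  set.seed(31)
  x <- rpois(5e4, 1.2)
  tab <- table(x[x > 0])
  spec <- kmer_spectrum(as.integer(names(tab)), as.numeric(tab), k = 20)

  ci1 <- bootstrap_ci(spec, n_bootstrap = 50, seed = 7)
  ci2 <- bootstrap_ci(spec, n_bootstrap = 50, seed = 7)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  expect_lt(ci1$lower, ci1$upper)

  est <- estimate_total_dkc(spec, n_bootstrap = 50, seed = 7)
  expect_equal(est$ci_level, 0.95)
  expect_lte(est$ci_lower, est$dkc_total)
  expect_gte(est$ci_upper, est$dkc_total)
  # clear-signal regime: interval contains the truth (5e4 distinct k-mers)
  expect_gte(5e4, est$ci_lower * 0.999)
  expect_lte(5e4, est$ci_upper * 1.2)
})

test_that("the point estimate trends below the true DKC on simulations", {
  # Gaussian quadrature underestimates integrals of the convex 1/lambda,
  # so the estimator is a lower bound in tendency
  below <- 0
  n_runs <- 0
  for (cx in c("LC", "MC", "HC")) {
    for (seed in 1:10) {
      comm <- simulate_community(10, 5e4, cx, repeat_fraction = 0.1,
                                 seed = seed)
      truth <- community_truth(comm, k = 20)
      s <- simulate_reads(comm, 5000, 100, 0, seed = seed + 500)
      est <- suppressWarnings(
        estimate_total_dkc(count_kmers(s, 20, TRUE)))
      n_runs <- n_runs + 1
      if (est$dkc_total <= truth$dkc_true) below <- below + 1
    }
  }
  expect_gte(below / n_runs, 0.8)
})
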