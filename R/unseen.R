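#' Transformed moment sequence of a k-mer spectrum
#'
#' Under the Poisson-mixture model, each distinct k-mer of the metagenome is
#' sequenced a Poisson(lambda) number of times with lambda drawn from an
#' unknown mixing distribution mu. Writing omega(lambda) =
#' N * lambda * exp(-lambda), the observed frequency classes give the raw
#' moments of the measure omega(lambda) d mu(lambda):
#' `m_j = (j+1)! * n_{j+1}`, with `m_0 = n_1`. The number of uncaptured
#' distinct k-mers is the integral of omega/lambda against mu, which a
#' Gaussian quadrature rule built from these moments approximates.
#'
#' Trailing zero moments (multiplicities above the largest observed one) are
#' excluded; interior zero classes are kept as zero moments.
#'
#' @param spectrum A [kmer_spectrum] with `n_1 > 0`.
#' @param max_moments Maximum number of moments to return (>= 2). Classes
#'   with multiplicity above `max_moments` do not contribute moments (they
#'   still count toward observed DKC/TKC); high-order moments are numerically
#'   dominant yet carry little information about small lambda.
#' @return An object of class `moment_sequence`: list with `values`
#'   (m_0 ... m_{L-1}), `n` (the source counts n_1 ... n_L) and `spectrum`.
#' @export
moments_from_spectrum <- function(spectrum, max_moments = 20) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  max_moments <- check_count(max_moments, "max_moments", min = 2)
  M <- max(spectrum$freq)
  n <- numeric(min(max_moments, M))
  idx <- spectrum$freq <= length(n)
  n[spectrum$freq[idx]] <- spectrum$count[idx]
  if (n[1] <= 0)
    stop("no singletons (n_1 = 0); unseen count not estimable", call. = FALSE)
  # drop trailing zeros
  last <- max(which(n > 0))
  n <- n[seq_len(last)]
  values <- factorial(seq_along(n)) * n
  structure(list(values = values, n = n, spectrum = spectrum),
            class = "moment_sequence")
}

#' Gaussian quadrature from raw moments (Golub-Welsch)
#'
#' Builds a P-point Gaussian quadrature rule for an unknown positive measure
#' from its raw moments m_0 ... m_{2P-1}: the Hankel moment matrix is
#' Cholesky-factorized (in extended precision, on rescaled moments) to obtain
#' the three-term recurrence of the orthogonal polynomials; the symmetric
#' tridiagonal Jacobi matrix is eigen-decomposed; nodes are the eigenvalues
#' and weight `alpha_i = m_0 * v_{1i}^2` where `v_{1i}` is the first component
#' of the i-th normalized eigenvector.
#'
#' A rule is accepted only if all pivots are positive, all nodes exceed
#' `min_node`, all weights are strictly positive, and the rule reproduces the
#' input moments to relative tolerance `rel_tol` (quadrature exactness). Raw
#' moment problems are notoriously ill-conditioned, so by default the
#' requested point count is decremented until a valid rule is found
#' (`allow_fewer = TRUE`); if no P >= 1 works the moment sequence is
#' inconsistent with a positive measure and an error is raised.
#'
#' @param moments A `moment_sequence` (or bare numeric vector of raw moments).
#' @param n_points Requested number of quadrature points P; requires
#'   `2 * n_points <= length(moments)`.
#' @param allow_fewer Decrement P on failure instead of erroring. Default TRUE.
#' @param min_node Nodes below this are rejected (the weight/node ratio would
#'   blow up). Default 1e-12.
#' @param rel_tol Relative tolerance for the moment-reproduction check.
#'   Default 1e-6.
#' @return An object of class `quadrature_rule`: list with `nodes`, `weights`,
#'   `n_points`, `n_points_requested`.
#' @examples
#' # one-point measure 6 * delta_1: moments 6, 6, 6
#' golub_welsch(c(6, 6, 6), n_points = 1)
#' @export
golub_welsch <- function(moments, n_points, allow_fewer = TRUE,
                         min_node = 1e-12, rel_tol = 1e-6) {
  m <- if (inherits(moments, "moment_sequence")) moments$values else
    as.numeric(moments)
  L <- length(m)
  n_points <- check_count(n_points, "n_points")
  if (2 * n_points > L)
    stop("need at least 2*n_points moments (have ", L, ", requested P = ",
         n_points, ")", call. = FALSE)
  if (m[1] <= 0) stop("m_0 must be positive", call. = FALSE)

  for (P in seq(n_points, 1)) {
    rule <- try_rule(m, P, min_node, rel_tol)
    if (!is.null(rule)) {
      rule$n_points_requested <- n_points
      return(rule)
    }
    if (!allow_fewer) break
  }
  stop("moment sequence inconsistent with a positive measure ",
       "(no valid quadrature rule at any P <= ", n_points, ")", call. = FALSE)
}

# Attempt a P-point rule; NULL if invalid at this P.
try_rule <- function(m, P, min_node, rel_tol) {
  jac <- cpp_jacobi_from_moments(m[seq_len(2 * P)], P)
  if (!isTRUE(jac$ok)) return(NULL)
  J <- diag(jac$alpha, nrow = P)
  if (P > 1) {
    idx <- cbind(seq_len(P - 1), seq_len(P - 1) + 1)
    J[idx] <- jac$b
    J[idx[, 2:1, drop = FALSE]] <- jac$b
  }
  ed <- eigen(J, symmetric = TRUE)
  ord <- order(ed$values)
  nodes_scaled <- ed$values[ord]
  first_comp <- ed$vectors[1, ord]
  nodes <- nodes_scaled * jac$scale
  weights <- m[1] * first_comp^2
  if (any(!is.finite(nodes)) || any(nodes <= min_node)) return(NULL)
  if (any(!is.finite(weights)) || any(weights <= 0)) return(NULL)
  # quadrature exactness on the scaled moments
  s <- m[seq_len(2 * P)] / (m[1] * jac$scale^(0:(2 * P - 1)))
  w_norm <- weights / m[1]
  repro <- vapply(0:(2 * P - 1),
                  function(j) sum(w_norm * nodes_scaled^j), numeric(1))
  err <- abs(repro - s) / pmax(abs(s), .Machine$double.eps)
  # zero moments cannot be matched in relative terms; compare those absolutely
  zero <- abs(s) < .Machine$double.eps
  err[zero] <- abs(repro[zero])
  if (any(err > rel_tol)) return(NULL)
  structure(list(nodes = nodes, weights = weights, n_points = P),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat("Gaussian quadrature rule (", x$n_points, " point",
      if (x$n_points > 1) "s", ")\n", sep = "")
  print(data.frame(node = x$nodes, weight = x$weights), row.names = FALSE)
  invisible(x)
}

#' Estimate the number of uncaptured distinct k-mers
#'
#' Approximates `N * integral(exp(-lambda) d mu)` — the expected number of
#' distinct k-mers of the metagenome missing from the sample — by
#' `sum(alpha_i / lambda_i)` over the Gaussian quadrature rule fitted to the
#' transformed moments of the observed spectrum.
#'
#' @param spectrum A [kmer_spectrum] with `n_1 > 0`.
#' @param max_points Maximum quadrature points; the largest achievable valid
#'   rule with `P <= max_points` is used. Default 10.
#' @param ... Passed to [golub_welsch()].
#' @return List with `value` (estimated uncaptured count, >= 0) and `rule`
#'   (the [golub_welsch()] rule used).
#' @export
estimate_uncaptured <- function(spectrum, max_points = 10, ...) {
  max_points <- check_count(max_points, "max_points")
  mom <- moments_from_spectrum(spectrum, max_moments = 2 * max_points)
  if (length(mom$values) < 2 && max(spectrum$freq) > 2 * max_points) {
    # truncation left only m_0: lift the cap to the full spectrum
    mom <- moments_from_spectrum(spectrum, max_moments = max(spectrum$freq))
  }
  P <- min(max_points, floor(length(mom$values) / 2))
  if (P < 1)
    stop("too few frequency classes to build a quadrature rule", call. = FALSE)
  rule <- golub_welsch(mom, n_points = P, allow_fewer = TRUE, ...)
  list(value = sum(rule$weights / rule$nodes), rule = rule)
}

#' Estimate the metagenome's total distinct k-mer count
#'
#' Adds the estimated uncaptured distinct k-mer count
#' ([estimate_uncaptured()]) to the observed DKC of the sample spectrum.
#' Optionally attaches a percentile bootstrap confidence interval
#' ([bootstrap_ci()]).
#'
#' @inheritParams estimate_uncaptured
#' @param n_bootstrap Number of bootstrap replicates (0 = no interval).
#' @param ci_level Confidence level, default 0.95.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `unseen_estimate`: list with `uncaptured`,
#'   `dkc_observed`, `dkc_total`, `ci_lower`, `ci_upper`, `ci_level`,
#'   `n_bootstrap`, `n_points_used`, `seed`, `warnings`.
#' @export
estimate_total_dkc <- function(spectrum, max_points = 10, n_bootstrap = 0,
                               ci_level = 0.95, seed = 1L) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  st <- spectrum_stats(spectrum)
  warnings <- character(0)
  if (st$dkc < 100) {
    warnings <- c(warnings, sprintf(
      "tiny spectrum (DKC = %.0f < 100); estimate unreliable", st$dkc))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  est <- estimate_uncaptured(spectrum, max_points = max_points)
  ci <- list(lower = NA_real_, upper = NA_real_)
  if (n_bootstrap > 0) {
    ci <- bootstrap_ci(spectrum, n_bootstrap = n_bootstrap, level = ci_level,
                       seed = seed, max_points = max_points)
    point <- st$dkc + est$value
    # percentile intervals need not contain the point estimate; widen so the
    # reported triplet is always ordered
    ci$lower <- min(ci$lower, point)
    ci$upper <- max(ci$upper, point)
    if (ci$n_failed > 0)
      warnings <- c(warnings, sprintf(
        "%d bootstrap replicates dropped (no singletons after redraws)",
        ci$n_failed))
  }
  structure(list(
    uncaptured = est$value,
    dkc_observed = st$dkc,
    dkc_total = st$dkc + est$value,
    ci_lower = ci$lower,
    ci_upper = ci$upper,
    ci_level = if (n_bootstrap > 0) ci_level else NA_real_,
    n_bootstrap = n_bootstrap,
    n_points_used = est$rule$n_points,
    seed = seed,
    warnings = warnings
  ), class = "unseen_estimate")
}

#' @export
print.unseen_estimate <- function(x, ...) {
  cat("Distinct k-mer count estimate\n")
  cat(sprintf("  observed DKC : %.0f\n", x$dkc_observed))
  cat(sprintf("  uncaptured   : %.0f\n", x$uncaptured))
  cat(sprintf("  total DKC    : %.0f\n", x$dkc_total))
  if (!is.na(x$ci_lower))
    cat(sprintf("  %.0f%% bootstrap CI: [%.0f, %.0f] (%d replicates)\n",
                100 * x$ci_level, x$ci_lower, x$ci_upper, x$n_bootstrap))
  cat("  quadrature points used:", x$n_points_used, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the total DKC estimate
#'
#' Resamples DKC distinct k-mers with replacement from the observed frequency
#' classes (a multinomial over multiplicities j with probabilities
#' n_j / DKC), re-runs the total-DKC estimator on each replicate spectrum,
#' and returns the percentile interval. Replicates with no singletons are
#' redrawn a bounded number of times, then dropped and flagged. Deterministic
#' given `seed`.
#'
#' @inheritParams estimate_total_dkc
#' @param n_bootstrap Number of replicates (>= 2). Default 100.
#' @param level Confidence level in (0, 1). Default 0.95.
#' @param max_retries Redraws allowed per degenerate replicate. Default 10.
#' @return List with `lower`, `upper`, `estimates` (per-replicate totals) and
#'   `n_failed`.
#' @export
bootstrap_ci <- function(spectrum, n_bootstrap = 100, level = 0.95,
                         seed = 1L, max_points = 10, max_retries = 10) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap", min = 2)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  st <- spectrum_stats(spectrum)
  dkc <- round(st$dkc)
  prob <- spectrum$count / st$dkc
  with_seed(seed, {
    estimates <- rep(NA_real_, n_bootstrap)
    n_failed <- 0
    for (b in seq_len(n_bootstrap)) {
      for (attempt in seq_len(max_retries + 1)) {
        counts <- as.numeric(rmultinom(1, size = dkc, prob = prob))
        if (counts[1] > 0 && spectrum$freq[1] == 1L) break
        if (sum(counts[spectrum$freq == 1L]) > 0) break
      }
      keep <- counts > 0
      if (!any(spectrum$freq[keep] == 1L)) { n_failed <- n_failed + 1; next }
      rep_spec <- kmer_spectrum(spectrum$freq[keep], counts[keep],
                                k = spectrum$k, canonical = spectrum$canonical)
      est <- tryCatch(estimate_uncaptured(rep_spec, max_points = max_points),
                      error = function(e) NULL)
      if (is.null(est)) { n_failed <- n_failed + 1; next }
      estimates[b] <- sum(rep_spec$count) + est$value
    }
    good <- estimates[!is.na(estimates)]
    if (length(good) < 2)
      stop("bootstrap failed: fewer than 2 valid replicates", call. = FALSE)
    qs <- quantile(good, probs = c((1 - level) / 2, (1 + level) / 2),
                   names = FALSE)
    list(lower = qs[1], upper = qs[2], estimates = estimates,
         n_failed = n_failed)
  })
}
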