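#' Paired Wilcoxon signed-rank test on session means
#'
#' Two-sided signed-rank test on paired session-level values (the unit of
#' all between-condition comparisons: per-pair metrics are first averaged
#' within each recording session). Results with fewer than 5 pairs are
#' flagged underpowered.
#'
#' @param session_means_a,session_means_b Paired numeric vectors, one
#'   value per session.
#' @param alpha Significance level.
#' @return Tibble of class `test_result`: `test`, `statistic`, `p_value`,
#'   `n`, `alpha`, `significant`, `underpowered`.
#' @export
paired_wilcoxon <- function(session_means_a, session_means_b, alpha = 0.05) {
  stopifnot(length(session_means_a) == length(session_means_b))
  n <- length(session_means_a)
  if (n < 1) abort("No sessions provided.")
  underpowered <- n < 5
  if (underpowered) warn(sprintf("Only %d session pairs: test is underpowered.", n))
  d <- session_means_a - session_means_b
  if (all(d == 0)) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    res <- suppressWarnings(
      stats::wilcox.test(session_means_a, session_means_b, paired = TRUE)
    )
  }
  tibble(
    test = "wilcoxon_signed_rank",
    statistic = unname(res$statistic), p_value = res$p.value,
    n = n, alpha = alpha,
    significant = !underpowered && res$p.value < alpha,
    underpowered = underpowered
  )
}

#' Correlation between neural and behavioral d-prime changes
#'
#' Pearson correlation across (session x target) pairs between the
#' engagement-related change in neural d-prime and behavioral d-prime,
#' with a percentile bootstrap 95% CI (resampling pairs) and a resampling
#' null built by shuffling the pairing between neural and behavioral
#' values; the correlation is significant when it exceeds the 97.5th
#' percentile of that null (one-sided).
#'
#' @param delta_dprimes Neural values, one per (session, target).
#' @param behavioral_dprimes Matching behavioral values.
#' @param n_boot Resamples for both the CI and the null.
#' @param seed Seed.
#' @return Tibble with `r`, `ci_lo`, `ci_hi`, `null_q975`, `p_value`
#'   (one-sided resampling p), `n`, `significant`.
#' @export
neural_behavior_correlation <- function(delta_dprimes, behavioral_dprimes,
                                        n_boot = 1000, seed = 1L) {
  stopifnot(length(delta_dprimes) == length(behavioral_dprimes))
  n <- length(delta_dprimes)
  if (n < 3) abort("At least 3 (session, target) pairs are required.")
  if (stats::sd(delta_dprimes) < 1e-12 || stats::sd(behavioral_dprimes) < 1e-12) {
    abort("Correlation undefined: one input vector is constant.")
  }
  set.seed(as.integer(seed))
  r <- stats::cor(delta_dprimes, behavioral_dprimes)
  null <- vapply(seq_len(n_boot), function(i) {
    stats::cor(delta_dprimes, sample(behavioral_dprimes))
  }, numeric(1))
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(delta_dprimes[idx]) < 1e-12 ||
        stats::sd(behavioral_dprimes[idx]) < 1e-12) return(NA_real_)
    stats::cor(delta_dprimes[idx], behavioral_dprimes[idx])
  }, numeric(1))
  q975 <- stats::quantile(null, 0.975, names = FALSE)
  tibble(
    r = r,
    ci_lo = stats::quantile(boot, 0.025, na.rm = TRUE, names = FALSE),
    ci_hi = stats::quantile(boot, 0.975, na.rm = TRUE, names = FALSE),
    null_q975 = q975,
    p_value = mean(null >= r),
    n = n,
    significant = r > q975
  )
}

#' Percentile bootstrap confidence interval
#'
#' @param values Numeric vector.
#' @param statistic Function of a numeric vector returning a scalar.
#' @param n_boot Resamples.
#' @param seed Seed.
#' @param level Confidence level.
#' @return Length-2 numeric `(lo, hi)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  if (length(values) < 2) abort("At least 2 values are required.")
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(i) {
    statistic(sample(values, length(values), replace = TRUE))
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(boot, c(a, 1 - a), names = FALSE)
}
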