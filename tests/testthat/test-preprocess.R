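# Minimal hand-built session: counts array with known content.
mk_session <- function(counts, events = NULL, pupil = NULL) {
  d <- dim(counts)
  if (is.null(events)) {
    events <- tibble::tibble(
      event_id = seq_len(d[2]), trial_id = seq_len(d[2]), state = "passive",
      position = 1L, category = "catch", stimulus = "catch",
      snr_db = NA_real_, onset_s = seq_len(d[2]) * 2, is_reminder = FALSE,
      outcome = NA_character_
    )
  }
  structure(
    list(events = events, counts = counts,
         bins = list(bin_width = 0.02, n_baseline = 5, n_evoked = 15),
         pupil = pupil, truth = NULL, config = NULL),
    class = "task_session"
  )
}

test_that("a stationary neuron has a near-zero PSTH after baseline normalization", {
  set.seed(2)
  counts <- array(rpois(2 * 200 * 20, 4), dim = c(2, 200, 20))
  ps <- zscore_psth(mk_session(counts))
  expect_lt(max(abs(ps$psth)), 0.2)
})

test_that("smoothing spreads a delta response with the 30 ms kernel and keeps area", {
  counts <- array(0L, dim = c(1, 40, 20))
  counts[1, , 12] <- 30L # single responsive bin, identical on every event
  ps <- zscore_psth(mk_session(counts), sigma = 0.03)
  expect_equal(which.max(ps$psth), 12)
  # oracle by hand: baseline is zero, so the only nonzero z value before
  # smoothing is at bin 12, z12 = rate / pooled SD of binned rates
  rates <- rep(c(rep(0, 11), 1500, rep(0, 8)), each = 40)
  z12 <- 1500 / sd(rates)
  # central weight of the discrete normalized Gaussian (sigma 30 ms,
  # 20 ms bins, +/-5 bins): 1/(1 + 2(e^-2/9 + e^-8/9 + e^-2 + e^-32/9 + e^-50/9))
  k0 <- 1 / (1 + 2 * (exp(-2/9) + exp(-8/9) + exp(-2) + exp(-32/9) + exp(-50/9)))
  expect_equal(max(ps$psth), z12 * k0, tolerance = 1e-10)
  # the kernel is normalized: total area is preserved
  expect_equal(sum(ps$psth), z12, tolerance = 1e-10)
})

test_that("z-scored PSTH shape is invariant to doubling all counts", {
  set.seed(3)
  base <- array(rpois(1 * 100 * 20, 3), dim = c(1, 100, 20))
  base[1, , 8:14] <- base[1, , 8:14] + 5L
  p1 <- zscore_psth(mk_session(base))
  p2 <- zscore_psth(mk_session(base * 2L))
  expect_equal(p1$psth, p2$psth, tolerance = 1e-10)
})

test_that("evoked responses match a hand-computed z-transform", {
  # 2 events: evoked window all ones vs all zeros
  counts <- array(0L, dim = c(1, 2, 20))
  counts[1, 1, 6:20] <- 1L
  r <- evoked_response(mk_session(counts))
  # window rates 50 and 0 sp/s; mean 25, sample SD 35.355
  expect_equal(as.vector(r$z), c(25, -25) / (50 / sqrt(2)), tolerance = 1e-10)
  # identical events give identical responses
  counts2 <- array(2L, dim = c(1, 3, 20))
  counts2[1, , 6] <- 5L
  expect_warning(evoked_response(mk_session(counts2)), "zero pooled SD")
})

test_that("pooled z-scoring gives mean 0, SD 1 per neuron and commutes with reordering", {
  s <- small_session(seed = 1)
  r <- evoked_response(s)
  expect_lt(max(abs(colMeans(r$z))), 1e-10)
  expect_equal(unname(apply(r$z, 2, sd)), rep(1, ncol(r$z)), tolerance = 1e-10)
  perm <- sample(nrow(s$events))
  s2 <- s
  s2$events <- s$events[perm, ]
  s2$counts <- s$counts[, perm, , drop = FALSE]
  r2 <- evoked_response(s2)
  expect_equal(r2$z, r$z[perm, ], tolerance = 1e-12)
})

test_that("pupil regression recovers a linear coupling and removes it", {
  set.seed(8)
  n <- 300
  p_trace <- tibble::tibble(time_s = seq(0.05, n * 2 + 3, 0.05),
                            size = runif(ceiling((n * 2 + 3) / 0.05)))
  ev <- tibble::tibble(
    event_id = 1:n, trial_id = 1:n, state = "passive", position = 1L,
    category = "catch", stimulus = "catch", snr_db = NA_real_,
    onset_s = (1:n) * 2 - 1.5, is_reminder = FALSE, outcome = NA_character_
  )
  p_ev <- popdprime:::pupil_at_events(p_trace, ev$onset_s, 0.75, 0.3)
  z <- cbind(2 * p_ev + rnorm(n, 0, 0.05), rnorm(n)) # coupled and uncoupled
  resp <- fake_evoked(z, "catch", "passive", "catch")
  resp$events <- ev
  resp$pupil <- p_trace
  corr <- regress_out_pupil(resp)
  pf <- attr(corr, "pupil_fit")
  expect_equal(pf$alpha[pf$neuron == 1], 2, tolerance = 0.05)
  expect_lt(abs(cor(corr$z[, 1], p_ev)), 0.02)
  # uncoupled neuron: fitted slope within OLS noise of zero
  # (SE ~ sd(resp)/(sd(pupil regressor) * sqrt(n)) ~ 0.5 here)
  expect_equal(corr$z[, 2], z[, 2], tolerance = 0.2)
  expect_lt(abs(attr(corr, "pupil_fit")$alpha[pf$neuron == 2]), 1.2)
  # per-stimulus means preserved to numerical precision
  expect_lt(max(abs(colMeans(corr$z) - colMeans(z))), 1e-10)
  # idempotence: correcting again does (almost) nothing
  corr2 <- regress_out_pupil(corr)
  expect_equal(corr2$z, corr$z, tolerance = 1e-8)
  expect_lt(max(abs(attr(corr2, "pupil_fit")$alpha)), 1e-8)
})

test_that("pupil correction errors without a trace and skips tiny groups", {
  z <- matrix(rnorm(10), 5, 2)
  resp <- fake_evoked(z, "catch", "passive", "catch")
  expect_error(regress_out_pupil(resp), "pupil")
  resp$pupil <- tibble::tibble(time_s = seq(0, 20, 0.1), size = runif(201))
  resp$events$stimulus <- c("a", "a", "b", "b", "b")
  expect_message(regress_out_pupil(resp), "fewer than 3|<3|Skipping")
})
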