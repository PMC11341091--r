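test_that("trial generation is deterministic and schema-stable across seeds", {
  cfg <- small_config(seed = 5)
  t1 <- generate_trials(cfg)
  t2 <- generate_trials(cfg)
  expect_identical(t1, t2)
  s1 <- small_session(seed = 1)
  s2 <- simulate_session(small_config(seed = 2), region_mode = "dPEG_like")
  expect_identical(dim(s1$counts)[c(1, 3)], dim(s2$counts)[c(1, 3)])
  expect_identical(names(s1$events), names(s2$events))
  expect_false(identical(s1$counts, s2$counts))
})

test_that("degenerate psychometric rates produce deterministic outcomes", {
  cfg <- session_config(
    n_neurons = 10, trials_per_stim = 15, snrs = c(0, Inf),
    hit_rates = c(`0` = 0.5, `Inf` = 1), catch_fa = 0, seed = 3
  )
  tr <- generate_trials(cfg)
  act <- tr[tr$state == "active" & !tr$is_reminder, ]
  expect_true(all(act$outcome[act$category == "target" & !is.finite(act$snr_db) |
                                (act$category == "target" & act$snr_db == Inf)] == "hit"))
  expect_true(all(act$outcome[act$category == "catch"] == "correct_reject"))
  # the coupling-adjusted redraw preserves the degenerate rates too
  s <- simulate_session(cfg, region_mode = "A1_like")
  act2 <- s$events[s$events$state == "active" & !s$events$is_reminder, ]
  expect_true(all(act2$outcome[act2$category == "catch"] == "correct_reject"))
  expect_true(all(act2$outcome[act2$category == "target" & act2$snr_db == Inf] == "hit"))
})

test_that("distractor counts follow a flat hazard", {
  cfg <- session_config(n_neurons = 5, trials_per_stim = 1000, seed = 11,
                        max_events = 5, hazard = 0.35)
  tr <- generate_trials(cfg, .keep_all_reminders = TRUE)
  n_dist <- tr |>
    dplyr::group_by(trial_id) |>
    dplyr::summarise(d = sum(category == "distractor"))
  # empirical per-position stop probability P(d = k | d >= k)
  for (k in 0:3) {
    at_risk <- sum(n_dist$d >= k)
    stopped <- sum(n_dist$d == k)
    expect_equal(stopped / at_risk, 0.35, tolerance = 0.12)
  }
})

test_that("zero trials requested is an error", {
  expect_error(session_config(trials_per_stim = 0))
})

test_that("latent response moments converge to the configured factor model", {
  set.seed(21)
  p <- 20
  L <- matrix(rnorm(p, 0, 1.5), p, 1)
  psi <- runif(p, 0.5, 2)
  mu <- rnorm(p, 5)
  X <- popdprime:::rmvn_factor(5000, mu, L, psi)
  S_true <- tcrossprod(L) + diag(psi)
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(cov(X) - S_true) / frob(S_true), 0.10)
  expect_lt(max(abs(colMeans(X) - mu)), 4 * sqrt(max(diag(S_true)) / 5000) * 2)
})

test_that("generated counts carry the rank-1 shared covariance direction", {
  cfg <- session_config(n_neurons = 50, seed = 9)
  tr <- ground_truth(cfg, "dPEG_like", rank = 1)
  tr$alpha[] <- 0
  events <- tibble::tibble(
    event_id = 1:500, trial_id = 1:500, state = "passive", position = 1L,
    category = "catch", stimulus = "catch", snr_db = NA_real_,
    onset_s = seq(0, by = 2, length.out = 500), is_reminder = FALSE,
    outcome = NA_character_
  )
  gen <- generate_counts(tr, events, cfg)
  rate <- t(apply(gen$counts[, , 6:20], c(1, 2), sum)) / 0.3
  e1 <- eigen(cov(rate), symmetric = TRUE)$vectors[, 1]
  cs <- abs(sum(e1 * tr$loadings_passive[, 1])) /
    sqrt(sum(tr$loadings_passive[, 1]^2))
  expect_gt(cs, 0.95)
})

test_that("without pupil coupling, responses are uncorrelated with pupil", {
  cfg <- small_config(seed = 13)
  truth <- ground_truth(cfg, "A1_like", pupil_frac = 0)
  s <- simulate_session(cfg, truth = truth)
  r <- evoked_response(s)
  p_ev <- popdprime:::pupil_at_events(s$pupil, s$events$onset_s, 0.75, 0.3)
  pas <- s$events$state == "passive"
  cors <- apply(r$z[pas, ], 2, function(v) cor(v, p_ev[pas]))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("a state-null ground truth yields equal active/passive means", {
  cfg <- session_config(n_neurons = 15, trials_per_stim = 10, seed = 17)
  truth <- ground_truth(cfg, "A1_like", pupil_frac = 0)
  truth$mu_active <- truth$mu_passive
  truth$gain[] <- 1
  events <- tibble::tibble(
    event_id = 1:2000, trial_id = 1:2000,
    state = rep(c("active", "passive"), each = 1000), position = 1L,
    category = "catch", stimulus = "catch", snr_db = NA_real_,
    onset_s = seq(0, by = 2, length.out = 2000), is_reminder = FALSE,
    outcome = NA_character_
  )
  gen <- generate_counts(truth, events, cfg)
  rate <- t(apply(gen$counts[, , 6:20], c(1, 2), sum)) / 0.3
  act <- rate[1:1000, ]; pas <- rate[1001:2000, ]
  se <- sqrt(apply(act, 2, var) / 1000 + apply(pas, 2, var) / 1000)
  expect_true(all(abs(colMeans(act) - colMeans(pas)) < 4 * se))
})

test_that("non-positive-definite covariance is rejected with the state named", {
  cfg <- small_config(seed = 1)
  truth <- ground_truth(cfg, "A1_like")
  truth$psi_active <- rep(-5, cfg$n_neurons)
  tr <- generate_trials(cfg)
  expect_error(generate_counts(truth, tr, cfg), "active")
})

test_that("unknown stimuli in the trial table are rejected", {
  cfg <- small_config(seed = 1)
  truth <- ground_truth(cfg, "A1_like")
  tr <- generate_trials(cfg)
  tr$stimulus[1] <- "unknown_stim"
  expect_error(generate_counts(truth, tr, cfg), "unknown_stim")
})

test_that("region modes shape the ground-truth selectivity as constructed", {
  cfg <- small_config(seed = 19)
  tr_d <- ground_truth(cfg, "dPEG_like")
  tr_a <- ground_truth(cfg, "A1_like")
  # dPEG-like: positive analytic selective enhancement
  expect_gt(truth_selective_enhancement(tr_d), 0)
  expect_gt(truth_selective_enhancement(tr_d, normalized = TRUE), 0)
  # A1-like: gain uniform within neuron, hence zero normalized selectivity
  expect_true(all(apply(tr_a$gain, 1, function(g) diff(range(g))) < 1e-12))
  # per-neuron gain jitter leaves a tiny residual selectivity
  expect_lt(abs(truth_selective_enhancement(tr_a, normalized = TRUE)), 1e-3)
  # dPEG gain change is larger for tone-contrast neurons on targets
  dg_target <- tr_d$gain[, "target_InfdB"] - 1
  expect_gt(cor(dg_target, abs(tr_d$mu_passive[, "target_InfdB"] -
                                 tr_d$mu_passive[, "catch"])), 0)
})

test_that("fixture bundles round-trip and differ across seeds", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- make_fixture(d1, "dPEG_like", seed = 1, pupil_frac = 0)
  s2 <- make_fixture(d2, "dPEG_like", seed = 2, pupil_frac = 0)
  r1 <- read_session(d1)
  expect_identical(s1$counts, r1$counts)
  expect_equal(as.data.frame(s1$events), as.data.frame(r1$events))
  expect_equal(r1$truth$mu_active, s1$truth$mu_active, tolerance = 1e-12)
  expect_false(identical(s1$counts, s2$counts))
  expect_identical(dim(s1$counts)[c(1, 3)], dim(s2$counts)[c(1, 3)])
})
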