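#' Configuration for a synthetic go/no-go session
#'
#' Defines the trial structure and behavioral statistics of a simulated
#' tone-in-noise detection session: blocks of active (task-engaged) and
#' passive trials, each trial a sequence of narrowband noise distractors
#' (0.3 s duration, 0.2 s ISI) terminated by a target tone at one of
#' several SNRs or by an explicit catch stimulus (noise matched to the
#' target's masker, no tone). The number of distractors per trial follows
#' a flat hazard (truncated geometric), so stimulus timing is
#' unpredictable. Behavioral outcomes are drawn from the configured
#' psychometric rates.
#'
#' @param n_neurons Number of simultaneously recorded units.
#' @param trials_per_stim Trials per terminal stimulus (each target SNR and
#'   the catch) per state. 25 matches the scale at which the >= 5-trial
#'   inclusion rule starts to bind for difficult targets.
#' @param snrs Target SNRs in dB relative to the 60 dB SPL masker;
#'   `Inf` is a pure tone without masker.
#' @param hit_rates Named numeric, hit probability per SNR (names as in
#'   `snrs`). Defaults follow a realistic psychometric curve.
#' @param catch_fa Probability of a false alarm on catch trials.
#' @param n_distractors Number of distinct distractor center frequencies.
#' @param max_events Maximum distractors per trial (hazard truncation).
#' @param hazard Per-position stop probability of the flat-hazard
#'   distractor count.
#' @param stim_dur,isi Stimulus duration and inter-stimulus interval (s).
#' @param bin_width Spike-count bin width (s).
#' @param baseline_s Pre-stimulus baseline window (s).
#' @param iti_s Inter-trial interval (s).
#' @param pupil_dt Pupil sampling interval (s).
#' @param pupil_lag Lag of pupil relative to spiking (s); the generator
#'   couples responses to pupil in the lagged window so that analysis with
#'   the same lag recovers the coupling.
#' @param pupil_state_offset Difference in mean pupil between active and
#'   passive blocks (arousal is higher during engagement).
#' @param pupil_outcome_coupling Probit-scale dependence of trial outcome
#'   on standardized pre-trial pupil (larger pupil, more licking).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_neurons = 60,
                           trials_per_stim = 25,
                           snrs = c(-10, -5, 0, Inf),
                           hit_rates = NULL,
                           catch_fa = 0.15,
                           n_distractors = 3,
                           max_events = 5,
                           hazard = 0.35,
                           stim_dur = 0.3,
                           isi = 0.2,
                           bin_width = 0.02,
                           baseline_s = 0.1,
                           iti_s = 1.5,
                           pupil_dt = 0.05,
                           pupil_lag = 0.75,
                           pupil_state_offset = 0.3,
                           pupil_outcome_coupling = 0.5,
                           seed = 1L) {
  if (is.null(hit_rates)) {
    hit_rates <- stats::setNames(c(0.35, 0.6, 0.8, 0.95)[seq_along(snrs)],
                                 as.character(snrs))
  }
  stopifnot(
    n_neurons >= 2, trials_per_stim >= 1, length(snrs) >= 1,
    all(hit_rates >= 0 & hit_rates <= 1), catch_fa >= 0, catch_fa <= 1,
    n_distractors >= 1, max_events >= 0, hazard > 0, hazard <= 1,
    stim_dur > 0, isi >= 0, bin_width > 0, baseline_s > 0
  )
  if (!setequal(names(hit_rates), as.character(snrs))) {
    abort("`hit_rates` must be named by the target SNRs.")
  }
  structure(
    list(
      n_neurons = n_neurons, trials_per_stim = trials_per_stim,
      snrs = snrs, hit_rates = hit_rates, catch_fa = catch_fa,
      n_distractors = n_distractors, max_events = max_events,
      hazard = hazard, stim_dur = stim_dur, isi = isi,
      bin_width = bin_width, baseline_s = baseline_s, iti_s = iti_s,
      pupil_dt = pupil_dt, pupil_lag = pupil_lag,
      pupil_state_offset = pupil_state_offset,
      pupil_outcome_coupling = pupil_outcome_coupling,
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
}

target_label <- function(snr) paste0("target_", snr, "dB")

config_stimuli <- function(config) {
  c(paste0("dist_", seq_len(config$n_distractors)), "catch",
    target_label(config$snrs))
}

#' Generate the trial/event table of a synthetic session
#'
#' One row per stimulus event. Each trial carries a flat-hazard number of
#' distractors followed by a terminal target or catch stimulus; catch
#' trials on which the response was withheld conclude with a pure-tone
#' reminder target (flagged `is_reminder` and excluded from analyses).
#' Outcomes are sampled independently per trial from the configured
#' psychometric rates; passive trials have outcome `NA`.
#'
#' @param config A [session_config()].
#' @param .keep_all_reminders Internal: keep reminder rows of active catch
#'   trials regardless of outcome (used when outcomes are redrawn later).
#' @return A tibble with columns `event_id`, `trial_id`, `state`,
#'   `position`, `category`, `stimulus`, `snr_db`, `onset_s`,
#'   `is_reminder`, `outcome`.
#' @export
generate_trials <- function(config, .keep_all_reminders = FALSE) {
  stopifnot(inherits(config, "session_config"))
  if (config$trials_per_stim < 1) abort("At least one trial per stimulus is required.")
  set.seed(config$seed)
  t0 <- 0
  out <- vector("list", 2L)
  names(out) <- c("active", "passive")
  trial_id0 <- 0L
  for (state in c("active", "passive")) {
    term <- c(target_label(config$snrs), "catch")
    term <- sample(rep(term, config$trials_per_stim))
    n_tr <- length(term)
    n_dist <- pmin(stats::rgeom(n_tr, config$hazard), config$max_events)
    rows <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      d <- n_dist[i]
      stim <- character(0)
      if (d > 0) stim <- paste0("dist_", sample.int(config$n_distractors, d, replace = TRUE))
      is_catch <- term[i] == "catch"
      stim <- c(stim, term[i])
      categ <- c(rep("distractor", d), if (is_catch) "catch" else "target")
      snr <- c(rep(NA_real_, d),
               if (is_catch) NA_real_ else config$snrs[match(term[i], target_label(config$snrs))])
      rem <- c(rep(FALSE, d + 1))
      # outcome from psychometric rates (redrawn later if pupil-coupled)
      outc <- NA_character_
      if (state == "active") {
        if (is_catch) {
          outc <- if (stats::runif(1) < config$catch_fa) "false_alarm" else "correct_reject"
        } else {
          snr_i <- as.character(snr[length(snr)])
          outc <- if (stats::runif(1) < config$hit_rates[[snr_i]]) "hit" else "miss"
        }
      }
      # reminder pure tone concluding catch trials (always replayed in
      # passive blocks; only delivered after a withheld response in active
      # blocks -- invalid reminders are dropped once outcomes are final)
      if (is_catch) {
        stim <- c(stim, target_label(Inf))
        categ <- c(categ, "target")
        snr <- c(snr, Inf)
        rem <- c(rem, TRUE)
      }
      k <- length(stim)
      onset <- t0 + (seq_len(k) - 1) * (config$stim_dur + config$isi)
      rows[[i]] <- tibble(
        trial_id = trial_id0 + i, state = state, position = seq_len(k),
        category = categ, stimulus = stim, snr_db = snr, onset_s = onset,
        is_reminder = rem, outcome = outc
      )
      t0 <- max(onset) + config$stim_dur + 1.0 + config$iti_s
    }
    out[[state]] <- dplyr::bind_rows(rows)
    trial_id0 <- trial_id0 + n_tr
    t0 <- t0 + 10 # short gap between blocks
  }
  ev <- dplyr::bind_rows(out)
  if (!.keep_all_reminders) ev <- drop_invalid_reminders(ev)
  ev$event_id <- seq_len(nrow(ev))
  dplyr::select(ev, "event_id", dplyr::everything())
}

# Reminder targets are only delivered when the catch response was withheld.
drop_invalid_reminders <- function(trials) {
  keep <- !(trials$is_reminder & trials$state == "active" &
              trials$outcome != "correct_reject")
  trials[keep, , drop = FALSE]
}

#' Ground-truth generative parameters of a synthetic population
#'
#' Builds per-state mean responses, low-rank shared covariance loadings,
#' private variances, multiplicative gain profiles and pupil couplings for
#' a population of tone-in-noise auditory cortical neurons. Each neuron
#' has a baseline rate, a narrowband-noise response (shared by the catch
#' stimulus and target maskers), a tone response, and per-distractor
#' responses; target means mix the tone and noise components according to
#' SNR. Task engagement acts as a multiplicative gain on the evoked part
#' of the mean:
#' * `dPEG_like`: gain is stimulus-selective, scaled per neuron by its
#'   tone-vs-noise contrast; targets are amplified and the catch response
#'   is suppressed, enhancing the task-relevant (target vs catch)
#'   separation more than the task-irrelevant ones.
#' * `A1_like`: gain is statistically uniform across stimuli, so all
#'   discriminations improve equally.
#'
#' @param config A [session_config()].
#' @param region_mode `"dPEG_like"` or `"A1_like"`.
#' @param rank Rank of the shared covariance (columns of the loading matrix).
#' @param gain_strength Engagement gain-change magnitude; defaults to 0.6
#'   (dPEG_like) or 0.35 (A1_like).
#' @param pupil_frac Fraction of neurons coupled to pupil.
#' @param alpha_sd SD of the pupil coupling (spikes/s per pupil unit) of
#'   coupled neurons.
#' @param state_noise_change `"none"` keeps loadings identical across
#'   states; `"rotate"` rotates the active-state loadings toward the
#'   task-relevant discrimination direction.
#' @param psi_active_scale Multiplier on active-state private variances.
#' @param rotate_frac Rotation fraction used when
#'   `state_noise_change = "rotate"`.
#' @param seed Seed for the parameter draws (defaults to `config$seed + 100`).
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(config,
                         region_mode = c("dPEG_like", "A1_like"),
                         rank = 1,
                         gain_strength = NULL,
                         pupil_frac = 0.3,
                         alpha_sd = 6,
                         state_noise_change = c("none", "rotate"),
                         psi_active_scale = 1,
                         rotate_frac = 0.5,
                         seed = config$seed + 100L) {
  region_mode <- match.arg(region_mode)
  state_noise_change <- match.arg(state_noise_change)
  if (is.null(gain_strength)) {
    gain_strength <- if (region_mode == "dPEG_like") 0.6 else 0.35
  }
  set.seed(as.integer(seed))
  p <- config$n_neurons
  stims <- config_stimuli(config)
  baseline <- stats::runif(p, 4, 16)
  nu <- pmax(stats::rnorm(p, 8, 4), 0)      # response to the target-band noise
  tau <- pmax(stats::rnorm(p, 8, 5), 0)     # response to the target tone
  snr_chr <- as.character(config$snrs)
  tone_w <- stats::setNames(pmin(0.3 + 0.45 * (config$snrs + 10) / 10, 1), snr_chr)
  tone_w[!is.finite(config$snrs)] <- 1
  noise_w <- stats::setNames(rep(1, length(config$snrs)), snr_chr)
  noise_w[!is.finite(config$snrs)] <- 0

  mu_passive <- matrix(0, p, length(stims), dimnames = list(NULL, stims))
  for (d in seq_len(config$n_distractors)) {
    mu_passive[, paste0("dist_", d)] <- baseline + pmax(stats::rnorm(p, 7, 4), 0)
  }
  mu_passive[, "catch"] <- baseline + nu
  for (s in snr_chr) {
    mu_passive[, target_label(as.numeric(s))] <-
      baseline + noise_w[[s]] * nu + tone_w[[s]] * tau
  }

  gain <- matrix(1, p, length(stims), dimnames = list(NULL, stims))
  if (region_mode == "A1_like") {
    g <- 1 + gain_strength + stats::rnorm(p, 0, 0.05)
    gain[] <- g # same gain for every stimulus within a neuron
  } else {
    contrast <- tau / (tau + nu + 1e-6) # tone preference in [0, 1]
    for (s in snr_chr) {
      gain[, target_label(as.numeric(s))] <-
        1 + gain_strength * tone_w[[s]] * 2 * contrast
    }
    gain[, "catch"] <- pmax(1 - 0.4 * gain_strength * 2 * contrast, 0.2)
  }
  mu_active <- baseline + gain * (mu_passive - baseline)

  L <- matrix(stats::rnorm(p * rank), p, rank)
  L <- sweep(L, 2, 2 / sqrt(seq_len(rank)), `*`)
  psi <- stats::runif(p, 4, 12)
  L_active <- L
  if (state_noise_change == "rotate") {
    dmu <- rowMeans(mu_active[, target_label(config$snrs), drop = FALSE]) -
      mu_active[, "catch"]
    dmu_u <- unitize(dmu, "discrimination direction")
    for (j in seq_len(rank)) {
      nj <- sqrt(sum(L[, j]^2))
      L_active[, j] <- unitize((1 - rotate_frac) * unitize(L[, j]) +
                                 rotate_frac * dmu_u) * nj
    }
  }
  psi_active <- psi * psi_active_scale

  alpha <- numeric(p)
  n_coupled <- round(pupil_frac * p)
  if (n_coupled > 0) {
    idx <- sample.int(p, n_coupled)
    alpha[idx] <- stats::rnorm(n_coupled, 0, alpha_sd)
  }

  structure(
    list(
      mu_active = mu_active, mu_passive = mu_passive,
      loadings_active = L_active, loadings_passive = L,
      psi_active = psi_active, psi_passive = psi,
      gain = gain, alpha = alpha, baseline = baseline,
      stimuli = stims, region_mode = region_mode, rank = rank,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' Generating mean and covariance of a ground truth in one state
#' @param truth A [ground_truth()].
#' @param state `"active"` or `"passive"`.
#' @return List with `mu` (neurons x stimuli) and `Sigma` (neurons x neurons).
#' @export
truth_moments <- function(truth, state = c("active", "passive")) {
  state <- match.arg(state)
  L <- truth[[paste0("loadings_", state)]]
  list(
    mu = truth[[paste0("mu_", state)]],
    Sigma = tcrossprod(L) + diag(truth[[paste0("psi_", state)]])
  )
}

#' Analytic population d-prime of the generating Gaussian
#'
#' The full-space optimal linear discriminability
#' \eqn{d' = \sqrt{\Delta\mu^\top \Sigma^{-1} \Delta\mu}} computed directly
#' from the generating parameters; the oracle against which pipeline
#' estimates are validated.
#'
#' @inheritParams truth_moments
#' @param stim_a,stim_b Stimulus labels (columns of the mean matrix).
#' @export
truth_dprime <- function(truth, stim_a, stim_b, state = c("active", "passive")) {
  m <- truth_moments(truth, state)
  dmu <- m$mu[, stim_a] - m$mu[, stim_b]
  sqrt(drop(crossprod(dmu, solve(m$Sigma, dmu))))
}

#' Analytic selective enhancement of a ground truth
#'
#' Mean engagement-related change in target-vs-catch d-prime minus the
#' mean change in target-vs-target d-prime, computed analytically from the
#' generating parameters. Positive values indicate task-specific coding
#' enhancement (the dPEG-like regime); ~0 indicates uniform enhancement
#' (A1-like).
#'
#' @param truth A [ground_truth()].
#' @param snrs Target SNRs to include; defaults to all targets in `truth`.
#' @param normalized Use the sum-normalized change
#'   \eqn{(d'_a - d'_p)/(d'_a + d'_p)} per pair instead of the raw
#'   difference. On this scale a uniform gain change yields exactly zero
#'   selectivity.
#' @export
truth_selective_enhancement <- function(truth, snrs = NULL, normalized = FALSE) {
  tg <- grep("^target_", truth$stimuli, value = TRUE)
  if (!is.null(snrs)) tg <- target_label(snrs)
  delta <- function(a, b) {
    da <- truth_dprime(truth, a, b, "active")
    dp <- truth_dprime(truth, a, b, "passive")
    if (normalized) (da - dp) / (da + dp) else da - dp
  }
  d_tc <- vapply(tg, function(s) delta(s, "catch"), numeric(1))
  pairs <- utils::combn(tg, 2)
  d_tt <- apply(pairs, 2, function(pr) delta(pr[1], pr[2]))
  mean(d_tc) - mean(d_tt)
}

# Ornstein-Uhlenbeck-like slow pupil trace over the session timeline with a
# state-dependent set point, min-max rescaled to [0, 1].
generate_pupil <- function(trials, config, seed = config$seed + 1000L) {
  set.seed(as.integer(seed))
  t_end <- max(trials$onset_s) + config$stim_dur + 2
  tt <- seq(0, t_end, by = config$pupil_dt)
  # state of each time point from trial membership (gaps inherit previous)
  block <- trials |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(start = min(.data$onset_s), .groups = "drop") |>
    dplyr::arrange(start)
  m <- rep(0.5, length(tt))
  for (i in seq_len(nrow(block))) {
    off <- if (block$state[i] == "active") config$pupil_state_offset / 2 else
      -config$pupil_state_offset / 2
    m[tt >= block$start[i]] <- 0.5 + off
  }
  theta <- 0.5; sig <- 0.25
  x <- numeric(length(tt))
  x[1] <- m[1]
  dt <- config$pupil_dt
  eps <- stats::rnorm(length(tt))
  for (k in 2:length(tt)) {
    x[k] <- x[k - 1] + theta * (m[k] - x[k - 1]) * dt + sig * sqrt(dt) * eps[k]
  }
  x <- (x - min(x)) / (max(x) - min(x))
  tibble(time_s = tt, size = x)
}

# Mean pupil in [onset + lag, onset + lag + width] per event.
pupil_at_events <- function(pupil, onsets, lag, width) {
  vapply(onsets, function(o) {
    sel <- pupil$time_s >= o + lag & pupil$time_s <= o + lag + width
    if (!any(sel)) return(NA_real_)
    mean(pupil$size[sel])
  }, numeric(1))
}

#' Generate binned spike counts (and pupil trace) for a trial table
#'
#' For every stimulus event, a latent population rate vector is drawn from
#' the state- and stimulus-specific Gaussian
#' \eqn{N(\mu, L L^\top + \Psi)}, a pupil term \eqn{\alpha_i p(t)} is
#' added (pupil measured in the lagged evoked window), and the rate is
#' converted to nonnegative integer counts in 20 ms bins (rounding, even
#' spread across the evoked window). Baseline bins carry independent
#' baseline-rate counts.
#'
#' @param truth A [ground_truth()].
#' @param trials Event table from [generate_trials()].
#' @param config The [session_config()].
#' @param pupil Optional pupil tibble (`time_s`, `size`); if `NULL` and any
#'   coupling is nonzero, one is generated.
#' @param seed Seed (defaults to `truth$seed + 1`).
#' @return List with `counts` (neurons x events x bins array), `pupil`,
#'   and `bins` metadata.
#' @export
generate_counts <- function(truth, trials, config, pupil = NULL,
                            seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  missing_stim <- setdiff(unique(trials$stimulus), truth$stimuli)
  if (length(missing_stim)) {
    abort(paste0("Trial table contains stimuli unknown to the ground truth: ",
                 paste(missing_stim, collapse = ", ")))
  }
  for (state in c("active", "passive")) {
    S <- truth_moments(truth, state)$Sigma
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(sprintf("Generating covariance for state '%s' is not positive semi-definite.", state))
    }
  }
  set.seed(as.integer(seed))
  if (is.null(pupil)) pupil <- generate_pupil(trials, config)
  p <- config$n_neurons
  n_ev <- nrow(trials)
  n_base <- round(config$baseline_s / config$bin_width)
  n_evoked <- round(config$stim_dur / config$bin_width)
  counts <- array(0L, dim = c(p, n_ev, n_base + n_evoked))

  p_ev <- pupil_at_events(pupil, trials$onset_s, config$pupil_lag, config$stim_dur)
  p_ev[is.na(p_ev)] <- mean(pupil$size)

  grp <- split(seq_len(n_ev), list(trials$state, trials$stimulus), drop = TRUE)
  for (g in grp) {
    state <- trials$state[g[1]]
    stim <- trials$stimulus[g[1]]
    L <- truth[[paste0("loadings_", state)]]
    psi <- truth[[paste0("psi_", state)]]
    mu <- truth[[paste0("mu_", state)]][, stim]
    lat <- rmvn_factor(length(g), mu, L, psi)
    if (any(truth$alpha != 0)) lat <- lat + p_ev[g] %o% truth$alpha
    K <- pmax(round(lat * config$stim_dur), 0) # events x neurons
    base <- K %/% n_evoked
    rem <- K %% n_evoked
    for (b in seq_len(n_evoked)) {
      counts[, g, n_base + b] <- t(base + (rem >= b))
    }
    # independent baseline activity
    lat0 <- matrix(truth$baseline, length(g), p, byrow = TRUE) +
      matrix(stats::rnorm(length(g) * p, 0, rep(sqrt(psi), each = length(g))),
             length(g), p)
    K0 <- pmax(round(lat0 * config$baseline_s), 0)
    b0 <- K0 %/% n_base
    r0 <- K0 %% n_base
    for (b in seq_len(n_base)) {
      counts[, g, b] <- t(b0 + (r0 >= b))
    }
  }
  storage.mode(counts) <- "integer"
  list(
    counts = counts, pupil = pupil,
    bins = list(bin_width = config$bin_width, n_baseline = n_base,
                n_evoked = n_evoked)
  )
}

# Redraw outcomes with a probit-scale pupil adjustment; marginal rates stay
# at the configured values because the adjustment is centered. Expects a
# trial table that still carries all reminder rows.
redraw_outcomes <- function(trials, config, pupil, seed) {
  if (config$pupil_outcome_coupling == 0) {
    trials <- drop_invalid_reminders(trials)
    trials$event_id <- seq_len(nrow(trials))
    return(trials)
  }
  set.seed(as.integer(seed))
  tr <- trials |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(state = dplyr::first(.data$state),
                     t_on = min(.data$onset_s), .groups = "drop")
  pre <- vapply(tr$t_on, function(o) {
    sel <- pupil$time_s >= o - 1 & pupil$time_s < o
    if (!any(sel)) return(NA_real_)
    mean(pupil$size[sel])
  }, numeric(1))
  # standardize within active trials: the state offset must not leak into
  # the outcome adjustment
  act <- tr$state == "active"
  z <- rep(0, nrow(tr))
  z[act] <- (pre[act] - mean(pre[act], na.rm = TRUE)) /
    stats::sd(pre[act], na.rm = TRUE)
  z[is.na(z)] <- 0
  zmap <- stats::setNames(z, tr$trial_id)
  c0 <- config$pupil_outcome_coupling
  # qnorm(rate) is scaled by sqrt(1 + c0^2) so the marginal response rate
  # over the pupil distribution stays at the configured value
  sc <- sqrt(1 + c0^2)
  term <- !trials$is_reminder & trials$category != "distractor" &
    trials$state == "active"
  for (i in which(term)) {
    zi <- zmap[[as.character(trials$trial_id[i])]]
    if (trials$category[i] == "catch") {
      pr <- stats::pnorm(stats::qnorm(config$catch_fa) * sc + c0 * zi)
      trials$outcome[i] <- if (stats::runif(1) < pr) "false_alarm" else "correct_reject"
    } else {
      rate <- config$hit_rates[[as.character(trials$snr_db[i])]]
      pr <- stats::pnorm(stats::qnorm(min(max(rate, 1e-6), 1 - 1e-6)) * sc + c0 * zi)
      trials$outcome[i] <- if (stats::runif(1) < pr) "hit" else "miss"
    }
  }
  # propagate the (possibly new) outcome to all events of the trial and
  # drop/add reminders consistently
  out_map <- trials |>
    dplyr::filter(!.data$is_reminder, .data$category != "distractor") |>
    dplyr::select("trial_id", new_outcome = "outcome")
  trials <- trials |>
    dplyr::left_join(out_map, by = "trial_id") |>
    dplyr::mutate(outcome = ifelse(.data$state == "active", .data$new_outcome,
                                   .data$outcome)) |>
    dplyr::select(-"new_outcome")
  trials <- drop_invalid_reminders(trials)
  trials$event_id <- seq_len(nrow(trials))
  trials
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper tying together [generate_trials()],
#' [ground_truth()], pupil generation, pupil-coupled outcome assignment
#' and [generate_counts()] into a session object consumed by the rest of
#' the pipeline.
#'
#' @param config A [session_config()].
#' @param truth Optional [ground_truth()]; generated from `config` and
#'   `region_mode` if omitted.
#' @param region_mode Passed to [ground_truth()] when `truth` is `NULL`.
#' @param ... Further arguments to [ground_truth()].
#' @return A list of class `task_session` with elements `events`,
#'   `counts`, `bins`, `pupil`, `truth`, `config`.
#' @export
simulate_session <- function(config, truth = NULL,
                             region_mode = c("dPEG_like", "A1_like"), ...) {
  region_mode <- match.arg(region_mode)
  if (is.null(truth)) truth <- ground_truth(config, region_mode, ...)
  trials <- generate_trials(config, .keep_all_reminders = TRUE)
  pupil <- generate_pupil(trials, config)
  trials <- redraw_outcomes(trials, config, pupil, config$seed + 2000L)
  gen <- generate_counts(truth, trials, config, pupil = pupil)
  structure(
    list(events = trials, counts = gen$counts, bins = gen$bins,
         pupil = gen$pupil, truth = truth, config = config),
    class = "task_session"
  )
}

#' @export
print.task_session <- function(x, ...) {
  cat(sprintf(
    "<task_session> %d neurons, %d events (%d trials), %d bins of %g s\n",
    dim(x$counts)[1], dim(x$counts)[2],
    length(unique(x$events$trial_id)), dim(x$counts)[3], x$bins$bin_width
  ))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: %s (rank %d shared covariance)\n",
                x$truth$region_mode, x$truth$rank))
  }
  invisible(x)
}
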