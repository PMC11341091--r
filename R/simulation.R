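#' The four Gaussian ablation models
#'
#' Each model specifies which generative parameters are matched to the
#' state-dependent estimates and which are tied to the active-state
#' estimates when simulating passive responses:
#' * `null`: mean, private variance and shared covariance all fixed to the
#'   active estimates — simulated states are statistically identical.
#' * `gain_only`: the mean follows each state's own estimate; all variance
#'   is fixed to the active estimates.
#' * `indep_var`: mean and private variance follow the state; shared
#'   covariance fixed to active.
#' * `shared_var`: every parameter follows its own state (the full model).
#'
#' @return Character vector of model names in nesting order.
#' @export
sim_models <- function() c("null", "gain_only", "indep_var", "shared_var")

#' Per-stimulus, per-state factor-analysis fits for simulation
#'
#' Fits a factor model to the single-trial responses to every stimulus in
#' both states (correct active trials, as in decoding). The rank is
#' selected once per stimulus/state (cross-validated likelihood) and
#' reused by all ablation models.
#'
#' @param responses An `evoked_set`.
#' @param rank Fixed rank, or `NULL` to cross-validate.
#' @param R_max,folds Rank-selection controls.
#' @param min_trials Minimum trials per stimulus per state.
#' @param seed Seed for fold assignment.
#' @return Nested list `fits[[state]][[stimulus]]` of `fa_fit` objects.
#' @export
fa_by_stimulus <- function(responses, rank = NULL, R_max = 3, folds = 5,
                           min_trials = 5, seed = 1L) {
  stopifnot(inherits(responses, "evoked_set"))
  ev <- responses$events
  stims <- unique(ev$stimulus[!ev$is_reminder])
  fits <- list(active = list(), passive = list())
  for (state in names(fits)) {
    for (stim in stims) {
      X <- stim_responses(responses, stim, state)
      if (nrow(X) < max(min_trials, 3)) next
      R <- rank %||% select_dimensionality(
        X, R_max = min(R_max, ncol(X) - 1, nrow(X) - 2),
        folds = min(folds, nrow(X)), seed = seed
      )$R
      fits[[state]][[stim]] <- fit_fa(X, R)
    }
  }
  fits
}

# Combine active/passive FA fits into the generating parameters of one
# ablation model for one stimulus.
model_params <- function(fit_active, fit_passive, model, state) {
  pick <- function(use_active) if (use_active) fit_active else fit_passive
  if (state == "active") {
    return(list(mu = fit_active$mu, L = fit_active$loadings, psi = fit_active$psi))
  }
  switch(model,
    null = list(mu = fit_active$mu, L = fit_active$loadings, psi = fit_active$psi),
    gain_only = list(mu = fit_passive$mu, L = fit_active$loadings, psi = fit_active$psi),
    indep_var = list(mu = fit_passive$mu, L = fit_active$loadings, psi = fit_passive$psi),
    shared_var = list(mu = fit_passive$mu, L = fit_passive$loadings, psi = fit_passive$psi),
    abort(sprintf("Unknown ablation model '%s'.", model))
  )
}

#' Simulate population responses under an ablation model
#'
#' Draws `n_samples` multivariate-Gaussian responses per stimulus and
#' state from the factor-analysis parameter estimates, with the
#' state-matching pattern of the requested model, and packages them as an
#' `evoked_set` so the identical decoding pipeline runs on simulated and
#' real data.
#'
#' @param fits Output of [fa_by_stimulus()].
#' @param model One of [sim_models()].
#' @param n_samples Samples per stimulus/state.
#' @param seed Seed for the draws.
#' @param events_meta Optional tibble mapping `stimulus` to `category` and
#'   `snr_db` (carried over from the source session when available).
#' @return An `evoked_set` of simulated responses.
#' @export
simulate_population <- function(fits, model = sim_models(), n_samples = 2000,
                                seed = 1L, events_meta = NULL) {
  model <- match.arg(model)
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  stims <- intersect(names(fits$active), names(fits$passive))
  if (!length(stims)) abort("No stimulus has factor-analysis fits in both states.")
  missing_fit <- setdiff(union(names(fits$active), names(fits$passive)), stims)
  if (length(missing_fit)) {
    inform(paste0("Stimuli without fits in both states are skipped: ",
                  paste(missing_fit, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  z <- list(); evs <- list()
  for (state in c("active", "passive")) {
    for (stim in stims) {
      par <- model_params(fits$active[[stim]], fits$passive[[stim]], model, state)
      z[[paste(state, stim)]] <- rmvn_factor(n_samples, par$mu, par$L, par$psi)
      meta <- if (!is.null(events_meta) && stim %in% events_meta$stimulus) {
        events_meta[match(stim, events_meta$stimulus), ]
      } else {
        tibble(stimulus = stim,
               category = ifelse(grepl("^target", stim), "target",
                                 ifelse(stim == "catch", "catch", "distractor")),
               snr_db = NA_real_)
      }
      evs[[paste(state, stim)]] <- tibble(
        stimulus = stim, state = state, category = meta$category,
        snr_db = meta$snr_db, is_reminder = FALSE,
        outcome = ifelse(state == "active",
                         ifelse(meta$category == "catch", "correct_reject", "hit"),
                         NA_character_),
        onset_s = NA_real_, trial_id = NA_integer_
      )[rep(1, n_samples), ]
    }
  }
  zmat <- do.call(rbind, z)
  events <- dplyr::bind_rows(evs)
  events$event_id <- seq_len(nrow(events))
  colnames(zmat) <- as.character(seq_len(ncol(zmat)))
  structure(
    list(z = zmat, events = events,
         scale = tibble(neuron = seq_len(ncol(zmat)), mean = NA_real_, sd = NA_real_),
         pupil = NULL, bins = NULL),
    class = "evoked_set"
  )
}

#' Selective enhancement from decoding results
#'
#' The engagement-related change in task-relevant discriminability beyond
#' the task-irrelevant change: mean \eqn{\Delta d'} (target vs catch)
#' minus mean \eqn{\Delta d'} (target vs target). Defined only when both
#' categories are present.
#'
#' @param results A `decoding_tbl`.
#' @param normalized Use the sum-normalized delta instead of the raw one.
#' @return Scalar selective enhancement (z-units, or unitless if
#'   normalized).
#' @export
selective_enhancement <- function(results, normalized = FALSE) {
  metric <- if (normalized) "delta_norm" else "delta"
  cs <- category_summary(results, metric = metric)
  need <- c("target_vs_catch", "target_vs_target")
  if (!all(need %in% cs$category)) {
    abort("Selective enhancement needs both target_vs_catch and target_vs_target pairs.")
  }
  cs$mean_value[cs$category == "target_vs_catch"] -
    cs$mean_value[cs$category == "target_vs_target"]
}

#' Run the full ablation over the four models for one session
#'
#' Fits per-stimulus factor models, simulates each ablation model, and
#' runs the identical pairwise decoding on the simulated responses, so
#' differences in predicted selective enhancement reflect only the
#' ablated parameters.
#'
#' @param responses An `evoked_set` from a real or synthetic session.
#' @param models Which ablation models to run.
#' @param n_samples Simulated trials per stimulus/state.
#' @param rank,R_max,folds Factor-model rank controls (see
#'   [fa_by_stimulus()]).
#' @param min_trials Inclusion rule.
#' @param seed Seed for fits and draws.
#' @return List with `fits`, `decoding` (named list of `decoding_tbl` per
#'   model) and `selective_enhancement` (tibble per model).
#' @export
engagement_ablation <- function(responses, models = sim_models(),
                                n_samples = 2000, rank = NULL, R_max = 3,
                                folds = 5, min_trials = 5, seed = 1L) {
  fits <- fa_by_stimulus(responses, rank = rank, R_max = R_max, folds = folds,
                         min_trials = min_trials, seed = seed)
  meta <- responses$events |>
    dplyr::filter(!.data$is_reminder) |>
    dplyr::distinct(.data$stimulus, .data$category, .data$snr_db)
  dec <- list(); se <- list()
  for (m in models) {
    sim <- simulate_population(fits, m, n_samples = n_samples,
                               seed = seed + match(m, sim_models()),
                               events_meta = meta)
    dec[[m]] <- pairwise_decoding(sim, min_trials = min_trials)
    se[[m]] <- tibble(
      model = m,
      selective_enhancement = selective_enhancement(dec[[m]]),
      selective_enhancement_norm = selective_enhancement(dec[[m]], normalized = TRUE)
    )
  }
  list(fits = fits, decoding = dec,
       selective_enhancement = dplyr::bind_rows(se))
}

#' Model performance: correlation of simulated and actual values
#'
#' Pearson correlation across sessions between a model's simulated
#' selective enhancement (or delta d-prime) and the actual values.
#'
#' @param simulated_values,actual_values Equal-length numeric vectors,
#'   one value per session.
#' @export
model_performance <- function(simulated_values, actual_values) {
  stopifnot(length(simulated_values) == length(actual_values))
  if (length(simulated_values) < 3) abort("At least 3 sessions are required.")
  stats::cor(simulated_values, actual_values)
}

#' Bootstrap comparison of ablation models against the full model
#'
#' For each model, computes 1000 (by default) bootstrap resamples of its
#' correlation with the actual values (resampling sessions with
#' replacement). A model is deemed *not* significantly different from the
#' full (`shared_var`) model when the 97.5th percentile of its bootstrap
#' distribution exceeds the observed full-model correlation; otherwise it
#' is significantly worse.
#'
#' @param simulated Named list of per-model numeric vectors (one value
#'   per session).
#' @param actual Numeric vector of actual per-session values.
#' @param full_model Name of the reference model.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed.
#' @return Tibble with `model`, `r`, `boot_q975`, `boot_ci_lo`,
#'   `boot_ci_hi`, `significantly_worse`.
#' @export
model_comparison <- function(simulated, actual, full_model = "shared_var",
                             n_boot = 1000, seed = 1L) {
  if (n_boot < 1) abort("`n_boot` must be a positive integer.")
  if (!full_model %in% names(simulated)) {
    abort(sprintf("Full model '%s' missing from `simulated`.", full_model))
  }
  set.seed(as.integer(seed))
  n <- length(actual)
  r_full <- model_performance(simulated[[full_model]], actual)
  purrr::imap(simulated, function(v, m) {
    r_obs <- model_performance(v, actual)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(v[idx]) < 1e-12 || stats::sd(actual[idx]) < 1e-12) return(NA_real_)
      stats::cor(v[idx], actual[idx])
    }, numeric(1))
    q <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    tibble(
      model = m, r = r_obs, r_full = r_full,
      boot_ci_lo = q[1], boot_ci_hi = q[2], boot_q975 = q[2],
      significantly_worse = q[2] < r_full
    )
  }) |> dplyr::bind_rows()
}
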