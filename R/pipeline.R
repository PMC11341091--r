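#' End-to-end analysis of one or more sessions
#'
#' Runs the full pipeline in order on each session: evoked-response
#' extraction, optional pupil correction, behavioral psychometrics,
#' pairwise population decoding, category summaries, covariability
#' metrics; then cross-session statistics: signed-rank comparison of
#' task-relevant vs task-irrelevant decoding improvements, per-category
#' improvement tests, and the neural-behavioral d-prime correlation.
#'
#' @param sessions List of `task_session` objects, or paths to session
#'   bundles (read with [read_session()]).
#' @param pupil_correct Remove pupil-explainable variance before decoding
#'   (skipped with a warning for sessions without a pupil trace).
#' @param min_trials Inclusion rule for stimuli and pairs.
#' @param covariability Also compute factor-analysis metrics per session.
#' @param fa_rank Rank for covariability fits (`NULL` cross-validates).
#' @param n_boot Resamples for correlation null/CI.
#' @param alpha Significance level.
#' @param seed Seed governing all resampling.
#' @return A list of class `task_report`: `behavior`, `decoding`,
#'   `category_means`, `covariability`, `tests`, `neural_behavior`,
#'   `log`.
#' @export
run_pipeline <- function(sessions, pupil_correct = TRUE, min_trials = 5,
                         covariability = TRUE, fa_rank = NULL,
                         n_boot = 1000, alpha = 0.05, seed = 1L) {
  if (inherits(sessions, "task_session")) sessions <- list(sessions)
  if (!length(sessions)) abort("No sessions supplied.")
  sessions <- purrr::map(sessions, function(s) {
    if (is.character(s)) read_session(s) else s
  })
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  behav <- list(); dec <- list(); covar <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    resp <- evoked_response(s)
    if (pupil_correct) {
      if (is.null(s$pupil)) {
        warn(sprintf("Session %d has no pupil trace; decoding without pupil correction.", i))
        note("session %d: pupil correction skipped (no trace)", i)
      } else {
        resp <- regress_out_pupil(resp)
        note("session %d: pupil correction applied", i)
      }
    }
    behav[[i]] <- psychometric_table(s$events) |> dplyr::mutate(session = i)
    d <- pairwise_decoding(resp, min_trials = min_trials)
    note("session %d: %d stimulus pairs decoded", i, nrow(d))
    dec[[i]] <- dplyr::mutate(d, session = i)
    if (covariability) {
      cv <- covariability_metrics(resp, rank = fa_rank, min_trials = min_trials,
                                  seed = seed)
      covar[[i]] <- dplyr::mutate(cv$metrics, session = i)
    }
  }
  decoding <- dplyr::bind_rows(dec)
  class(decoding) <- c("decoding_tbl", class(tibble()))
  cat_means <- category_summary(decoding, metric = "delta_norm")

  # task-relevant vs task-irrelevant improvement across sessions
  wide <- cat_means |>
    tidyr::pivot_wider(id_cols = "session", names_from = "category",
                       values_from = "mean_value")
  tests <- list()
  if (all(c("target_vs_catch", "target_vs_target") %in% names(wide))) {
    ok <- stats::complete.cases(wide[, c("target_vs_catch", "target_vs_target")])
    tests$selectivity <- paired_wilcoxon(
      wide$target_vs_catch[ok], wide$target_vs_target[ok], alpha = alpha
    ) |> dplyr::mutate(comparison = "TvC_vs_TvT_delta_norm")
  }
  for (cat in unique(cat_means$category)) {
    v <- cat_means$mean_value[cat_means$category == cat]
    if (length(v) >= 5) {
      tests[[cat]] <- paired_wilcoxon(v, rep(0, length(v)), alpha = alpha) |>
        dplyr::mutate(comparison = paste0(cat, "_delta_norm_vs_0"))
    }
  }

  # neural vs behavioral d-prime per (session, target)
  nb_tbl <- decoding |>
    dplyr::filter(.data$category == "target_vs_catch") |>
    dplyr::mutate(target_snr = ifelse(.data$stim_a == "catch", .data$stim_b,
                                      .data$stim_a)) |>
    dplyr::select("session", "target_snr", "delta")
  beh_tbl <- dplyr::bind_rows(behav) |>
    dplyr::mutate(target_snr = target_label(.data$snr_db)) |>
    dplyr::select("session", "target_snr", behavioral = "dprime")
  nb <- dplyr::inner_join(nb_tbl, beh_tbl, by = c("session", "target_snr"))
  neural_behavior <- NULL
  if (nrow(nb) >= 3 && stats::sd(nb$delta) > 1e-12 &&
      stats::sd(nb$behavioral) > 1e-12) {
    neural_behavior <- neural_behavior_correlation(
      nb$delta, nb$behavioral, n_boot = n_boot, seed = seed
    )
  } else {
    note("neural-behavioral correlation skipped (too few or degenerate pairs)")
  }

  structure(
    list(
      behavior = dplyr::bind_rows(behav),
      decoding = decoding,
      category_means = cat_means,
      covariability = if (covariability) dplyr::bind_rows(covar) else NULL,
      tests = dplyr::bind_rows(tests),
      neural_behavior = neural_behavior,
      neural_behavior_pairs = nb,
      log = log_lines,
      seed = seed
    ),
    class = "task_report"
  )
}

#' @export
print.task_report <- function(x, ...) {
  n_ses <- length(unique(x$decoding$session))
  cat(sprintf("<task_report> %d session(s), %d decoded pairs\n",
              n_ses, nrow(x$decoding)))
  if (nrow(x$tests)) {
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("  %s: p = %.4g%s\n", x$tests$comparison[i],
                  x$tests$p_value[i],
                  ifelse(x$tests$significant[i], " *", "")))
    }
  }
  if (!is.null(x$neural_behavior)) {
    cat(sprintf("  neural-behavioral r = %.3f (null 97.5%% = %.3f)%s\n",
                x$neural_behavior$r, x$neural_behavior$null_q975,
                ifelse(x$neural_behavior$significant, " *", "")))
  }
  invisible(x)
}

#' @rdname tidy_popdprime
#' @export
glance.task_report <- function(x, ...) {
  tibble(
    n_sessions = length(unique(x$decoding$session)),
    n_pairs = nrow(x$decoding),
    selectivity_p = if ("TvC_vs_TvT_delta_norm" %in% x$tests$comparison) {
      x$tests$p_value[x$tests$comparison == "TvC_vs_TvT_delta_norm"]
    } else NA_real_,
    neural_behavior_r = if (!is.null(x$neural_behavior)) x$neural_behavior$r else NA_real_
  )
}
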