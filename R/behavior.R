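#' Response rates per terminal stimulus
#'
#' Hit rates for each target stimulus and the response (false-alarm) rate
#' for the explicit catch stimulus, from active trials only. Reminder
#' targets concluding catch trials are excluded: their outcome is
#' conditioned on the preceding correct reject.
#'
#' @param trials Event table (as in `task_session$events`).
#' @return Tibble with `stimulus`, `category`, `snr_db`, `n`,
#'   `n_responses`, `rate`.
#' @export
response_rates <- function(trials) {
  term <- trials |>
    dplyr::filter(.data$state == "active", !.data$is_reminder,
                  .data$category %in% c("target", "catch"))
  if (nrow(term) == 0) abort("No active target or catch presentations in trial table.")
  term |>
    dplyr::group_by(.data$stimulus, .data$category, .data$snr_db) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_responses = sum(.data$outcome %in% c("hit", "false_alarm")),
      rate = .data$n_responses / .data$n,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$snr_db)
}

#' Behavioral d-prime
#'
#' Signal-detection sensitivity: the difference of inverse-normal
#' transformed hit and catch (false-alarm) rates,
#' \eqn{d' = \Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{FA})}. Rates are
#' clipped to \eqn{[1/(2n),\ 1 - 1/(2n)]} so extreme rates give finite
#' values; \eqn{d' = 0} is chance.
#'
#' @param hit_rate,catch_rate Response rates in `[0, 1]` (vectorized).
#' @param n_target,n_catch Trial counts behind each rate.
#' @return Numeric d-prime (z-units).
#' @export
behavioral_dprime <- function(hit_rate, catch_rate, n_target, n_catch) {
  if (any(n_target <= 0) || any(n_catch <= 0)) abort("Trial counts must be positive.")
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1), all(catch_rate >= 0 & catch_rate <= 1))
  stats::qnorm(clip_rate(hit_rate, n_target)) -
    stats::qnorm(clip_rate(catch_rate, n_catch))
}

#' Psychometric summary table
#'
#' One behavioral d-prime per target SNR: the z-scored hit rate for that
#' target minus the z-scored catch response rate.
#'
#' @param trials Event table.
#' @return Tibble with `snr_db`, `n_target`, `hit_rate`, `n_catch`,
#'   `catch_rate`, `dprime`.
#' @export
psychometric_table <- function(trials) {
  rr <- response_rates(trials)
  catch <- dplyr::filter(rr, .data$category == "catch")
  if (nrow(catch) == 0) abort("No catch presentations: false-alarm rate undefined.")
  tg <- dplyr::filter(rr, .data$category == "target")
  if (nrow(tg) == 0) {
    warn("No target presentations; returning catch rate only.")
    return(tibble(snr_db = numeric(0), n_target = integer(0),
                  hit_rate = numeric(0), n_catch = integer(0),
                  catch_rate = numeric(0), dprime = numeric(0)))
  }
  tibble(
    snr_db = tg$snr_db,
    n_target = tg$n,
    hit_rate = tg$rate,
    n_catch = catch$n,
    catch_rate = catch$rate,
    dprime = behavioral_dprime(tg$rate, catch$rate, tg$n, catch$n)
  ) |>
    dplyr::arrange(.data$snr_db)
}

#' Pre-trial pupil size by behavioral outcome
#'
#' Mean pupil size in the window before each trial's first stimulus,
#' grouped by outcome class (`hit`, `miss`, `correct_reject`,
#' `false_alarm`, plus the derived `correct` = hits and correct rejects),
#' with pairwise Wilcoxon rank-sum tests between the classes the task
#' literature compares (correct vs miss, hit vs miss, hit vs correct
#' reject).
#'
#' @param trials Event table (active trials are used).
#' @param pupil Pupil tibble (`time_s`, `size`).
#' @param window Pre-trial window length in seconds.
#' @return List with `means` (per-class mean, SD, n) and `tests`
#'   (pairwise Wilcoxon rank-sum p-values).
#' @export
pretrial_pupil_by_outcome <- function(trials, pupil, window = 1) {
  if (is.null(pupil)) abort("A pupil trace is required for the pre-trial pupil analysis.")
  tr <- trials |>
    dplyr::filter(.data$state == "active") |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(outcome = dplyr::first(stats::na.omit(.data$outcome)),
                     t_on = min(.data$onset_s), .groups = "drop")
  tr$pre <- vapply(tr$t_on, function(o) {
    sel <- pupil$time_s >= o - window & pupil$time_s < o
    if (!any(sel)) return(NA_real_)
    mean(pupil$size[sel])
  }, numeric(1))
  tr <- dplyr::filter(tr, !is.na(.data$pre))
  grab <- function(cls) {
    if (cls == "correct") tr$pre[tr$outcome %in% c("hit", "correct_reject")]
    else tr$pre[tr$outcome == cls]
  }
  classes <- c("hit", "miss", "correct_reject", "false_alarm", "correct")
  means <- purrr::map(classes, function(cls) {
    v <- grab(cls)
    tibble(class = cls, n = length(v),
           mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }) |> dplyr::bind_rows()
  pairs <- list(c("correct", "miss"), c("hit", "miss"), c("hit", "correct_reject"))
  tests <- purrr::map(pairs, function(pr) {
    a <- grab(pr[1]); b <- grab(pr[2])
    p <- if (length(a) >= 2 && length(b) >= 2) {
      suppressWarnings(tryCatch(stats::wilcox.test(a, b)$p.value,
                                error = function(e) NA_real_))
    } else NA_real_
    tibble(class_a = pr[1], class_b = pr[2], n_a = length(a), n_b = length(b),
           p_value = p)
  }) |> dplyr::bind_rows()
  list(means = means, tests = tests)
}
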