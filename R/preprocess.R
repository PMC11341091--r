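#' Smoothed, z-scored PSTHs per neuron and stimulus
#'
#' Trial-averaged firing rate in 20 ms bins, normalized to the 100 ms
#' pre-stimulus baseline (the neuron's mean baseline rate is subtracted),
#' z-scored by the neuron's binned-rate SD, and smoothed with a Gaussian
#' kernel (default width 30 ms). Intended for visualization; downstream
#' statistics use [evoked_response()].
#'
#' @param session A `task_session`.
#' @param sigma Gaussian kernel SD in seconds.
#' @return A tibble with `neuron`, `state`, `stimulus`, `time_s`, `psth`
#'   (z-units). Zero-variance neurons are excluded with a warning.
#' @export
zscore_psth <- function(session, sigma = 0.03) {
  stopifnot(inherits(session, "task_session"))
  cts <- session$counts
  bw <- session$bins$bin_width
  p <- dim(cts)[1]; n_bins <- dim(cts)[3]
  rates <- cts / bw
  base_bins <- seq_len(session$bins$n_baseline)
  # per-neuron normalization over all bins and events
  mu0 <- vapply(seq_len(p), function(i) mean(rates[i, , base_bins]), numeric(1))
  sd_all <- vapply(seq_len(p), function(i) stats::sd(as.vector(rates[i, , ])), numeric(1))
  keep <- sd_all > 0
  if (any(!keep)) {
    warn(sprintf("Excluding %d zero-variance neuron(s) from PSTHs.", sum(!keep)))
  }
  kern <- gauss_kernel(sigma, bw)
  tt <- (seq_len(n_bins) - session$bins$n_baseline - 0.5) * bw
  grp <- split(seq_len(dim(cts)[2]),
               list(session$events$state, session$events$stimulus), drop = TRUE)
  out <- purrr::imap(grp, function(idx, key) {
    parts <- strsplit(key, "\\.")[[1]]
    m <- apply(rates[keep, idx, , drop = FALSE], c(1, 3), mean)
    z <- (m - mu0[keep]) / sd_all[keep]
    zs <- t(apply(z, 1, smooth_vec, kern = kern))
    tibble(
      neuron = rep(which(keep), times = n_bins),
      state = parts[1], stimulus = parts[2],
      time_s = rep(tt, each = sum(keep)),
      psth = as.vector(zs)
    )
  })
  dplyr::bind_rows(out)
}

gauss_kernel <- function(sigma, bw) {
  half <- max(1L, ceiling(3 * sigma / bw))
  x <- (-half):half
  k <- exp(-(x * bw)^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_vec <- function(v, kern) {
  half <- (length(kern) - 1L) / 2L
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + length(v))]
}

#' Single-trial evoked responses, z-scored per neuron
#'
#' One scalar response per neuron per stimulus event: the mean firing rate
#' over the 300 ms evoked window, z-scored per neuron with normalization
#' parameters pooled across both behavioral states (so active and passive
#' responses share a scale and their d-primes are comparable). Active-state
#' responses include hit, correct-reject and miss trials.
#'
#' @param session A `task_session`.
#' @return An object of class `evoked_set`: list with `z` (events x
#'   neurons matrix), `events` (the event table), and `scale` (per-neuron
#'   mean/SD of raw window rates). Neurons with zero pooled SD are dropped
#'   with a warning.
#' @export
evoked_response <- function(session) {
  stopifnot(inherits(session, "task_session"))
  ev_bins <- session$bins$n_baseline + seq_len(session$bins$n_evoked)
  win_s <- session$bins$n_evoked * session$bins$bin_width
  # events x neurons matrix of window-mean rates
  rate <- t(apply(session$counts[, , ev_bins, drop = FALSE], c(1, 2), sum)) / win_s
  mu <- colMeans(rate)
  s <- apply(rate, 2, stats::sd)
  keep <- s > 0
  if (any(!keep)) {
    warn(sprintf("Dropping %d neuron(s) with zero pooled SD from evoked responses.",
                 sum(!keep)))
  }
  z <- sweep(sweep(rate[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], `/`)
  colnames(z) <- which(keep)
  structure(
    list(
      z = z,
      events = as_tibble(session$events),
      scale = tibble(neuron = which(keep), mean = mu[keep], sd = s[keep]),
      pupil = session$pupil,
      bins = session$bins
    ),
    class = "evoked_set"
  )
}

#' @export
print.evoked_set <- function(x, ...) {
  cat(sprintf("<evoked_set> %d events x %d neurons (z-scored evoked rates)\n",
              nrow(x$z), ncol(x$z)))
  if (!is.null(attr(x, "pupil_fit"))) cat("  pupil-corrected\n")
  invisible(x)
}

#' @rdname tidy_popdprime
#' @export
tidy.evoked_set <- function(x, ...) {
  tibble(
    event_id = rep(x$events$event_id, times = ncol(x$z)),
    neuron = rep(as.integer(colnames(x$z)), each = nrow(x$z)),
    stimulus = rep(x$events$stimulus, times = ncol(x$z)),
    state = rep(x$events$state, times = ncol(x$z)),
    outcome = rep(x$events$outcome, times = ncol(x$z)),
    response = as.vector(x$z)
  )
}

#' Remove pupil-explainable variance from evoked responses
#'
#' For each neuron and stimulus, the response is regressed on the mean
#' pupil size over the (lagged) evoked window, and the pupil-dependent
#' part is subtracted in centered form,
#' \eqn{\bar r_i = r_i - \alpha_i (p - \bar p)}, which removes
#' pupil-correlated variability while preserving the per-stimulus mean
#' response. Active and passive events are fit jointly, so variance that
#' tracks the engagement-arousal correlation is removed too. Groups with
#' fewer than 3 events are left uncorrected.
#'
#' @param responses An `evoked_set`.
#' @param pupil Pupil tibble (`time_s`, `size`); defaults to the one
#'   carried by the session.
#' @param lag Pupil lag relative to spiking, seconds.
#' @return The corrected `evoked_set`; the per-(neuron, stimulus) slopes
#'   and intercepts are attached as attribute `"pupil_fit"` (a tibble with
#'   `neuron`, `stimulus`, `alpha`, `beta`, `n`).
#' @export
regress_out_pupil <- function(responses, pupil = NULL, lag = 0.75) {
  stopifnot(inherits(responses, "evoked_set"))
  pupil <- pupil %||% responses$pupil
  if (is.null(pupil)) abort("No pupil trace available for pupil correction.")
  win_s <- responses$bins$n_evoked * responses$bins$bin_width
  p_ev <- pupil_at_events(pupil, responses$events$onset_s, lag, win_s)
  if (anyNA(p_ev)) {
    warn("Pupil trace does not cover some events; using trace mean there.")
    p_ev[is.na(p_ev)] <- mean(pupil$size)
  }
  z <- responses$z
  fits <- list()
  for (stim in unique(responses$events$stimulus)) {
    idx <- which(responses$events$stimulus == stim)
    if (length(idx) < 3) {
      inform(sprintf("Skipping pupil correction for '%s' (<3 events).", stim))
      next
    }
    pc <- p_ev[idx] - mean(p_ev[idx])
    denom <- sum(pc^2)
    if (denom < 1e-12) next
    alpha <- unname(drop(crossprod(pc, z[idx, , drop = FALSE]))) / denom
    beta <- unname(colMeans(z[idx, , drop = FALSE])) - alpha * mean(p_ev[idx])
    z[idx, ] <- z[idx, , drop = FALSE] - pc %o% alpha
    fits[[stim]] <- tibble(
      neuron = as.integer(colnames(responses$z)), stimulus = stim,
      alpha = alpha, beta = beta, n = length(idx)
    )
  }
  responses$z <- z
  attr(responses, "pupil_fit") <- dplyr::bind_rows(fits)
  attr(responses, "pupil_per_event") <- p_ev
  responses
}
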