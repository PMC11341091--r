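#' Fit a decoding-based dimensionality-reduction (dDR) space
#'
#' Projects population activity into the plane spanned by the signal axis
#' (the normalized class-mean difference \eqn{\Delta\mu = \mu_a - \mu_b})
#' and the noise axis (the first eigenvector of the stimulus-independent,
#' pooled within-class covariance, Gram-Schmidt-orthogonalized against the
#' signal axis). Decoders estimated in this 2-D space avoid the
#' small-sample unreliability of full-space discriminant axes.
#'
#' @param responses_a,responses_b Trials x neurons matrices for the two
#'   classes.
#' @return An object of class `ddr_space`: `signal`, `noise` (unit
#'   vectors) and `proj` (2 x neurons projection matrix; one row if the
#'   space degenerates to 1-D).
#' @export
fit_ddr <- function(responses_a, responses_b) {
  A <- assert_matrixlike(responses_a, "responses_a")
  B <- assert_matrixlike(responses_b, "responses_b")
  stopifnot(ncol(A) == ncol(B))
  dmu <- unname(colMeans(A) - colMeans(B))
  if (sqrt(sum(dmu^2)) < 1e-12) {
    abort("Class means are equal: signal axis undefined.")
  }
  signal <- unitize(dmu, "signal axis")
  # trial-to-trial residuals pooled over the pair
  resid <- rbind(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  S <- stats::cov(resid)
  ev <- eigen(S, symmetric = TRUE)
  noise <- NULL
  for (k in seq_len(ncol(ev$vectors))) {
    e_k <- ev$vectors[, k]
    e_k <- e_k * sign(e_k[which.max(abs(e_k))])
    orth <- e_k - sum(e_k * signal) * signal
    if (sqrt(sum(orth^2)) > 1e-8) {
      noise <- unitize(orth, "noise axis")
      break
    }
  }
  if (is.null(noise)) {
    warn("All covariance eigenvectors are parallel to the signal axis; using a 1-D space.")
    proj <- matrix(signal, nrow = 1)
  } else {
    proj <- rbind(signal, noise)
  }
  rownames(proj) <- NULL
  structure(list(signal = signal, noise = noise, proj = proj),
            class = "ddr_space")
}

#' d-prime from class moments
#'
#' Closed-form optimal linear discriminability
#' \eqn{d' = \sqrt{\Delta\mu^\top \Sigma^{-1} \Delta\mu}}.
#'
#' @param dmu Mean-difference vector.
#' @param Sigma Stimulus-independent covariance matrix.
#' @param ridge Ridge added as `ridge * mean(diag(Sigma))` for
#'   conditioning (0 disables).
#' @export
dprime_from_moments <- function(dmu, Sigma, ridge = 0) {
  Sigma <- as.matrix(Sigma)
  if (ridge > 0) Sigma <- Sigma + diag(ridge * mean(diag(Sigma)), nrow(Sigma))
  x <- tryCatch(solve(Sigma, dmu), error = function(e) {
    abort("Covariance matrix is singular; cannot compute d-prime.")
  })
  sqrt(max(drop(crossprod(dmu, x)), 0))
}

#' Population d-prime in a dDR space
#'
#' Projects both classes into the fitted 2-D space and computes
#' \eqn{d' = \sqrt{\Delta\mu^\top \Sigma^{-1} \Delta\mu}} with
#' \eqn{\Sigma} the pooled within-class covariance (average of the two
#' projected class covariances), plus a small ridge
#' (`1e-6 * mean(diag)`) for conditioning.
#'
#' @param responses_a,responses_b Trials x neurons matrices.
#' @param space A `ddr_space` from [fit_ddr()]; fitted from the data if
#'   `NULL`.
#' @export
population_dprime <- function(responses_a, responses_b, space = NULL) {
  A <- assert_matrixlike(responses_a, "responses_a")
  B <- assert_matrixlike(responses_b, "responses_b")
  if (is.null(space)) space <- fit_ddr(A, B)
  Ap <- A %*% t(space$proj)
  Bp <- B %*% t(space$proj)
  dmu <- colMeans(Ap) - colMeans(Bp)
  dprime_from_moments(dmu, pooled_cov(Ap, Bp), ridge = 1e-6)
}

#' Full-space plug-in population d-prime
#'
#' In-sample d-prime using the full-dimensional mean difference and the
#' (ridge-stabilized) inverse of the pooled within-class covariance, with
#' the same ridge convention as the 2-D decoder. Included as the
#' overfitting-prone baseline that motivates dDR: with trial counts near
#' or below the neuron count the sample covariance is near-singular and
#' this estimator grossly overestimates discriminability.
#'
#' @param responses_a,responses_b Trials x neurons matrices.
#' @param ridge Ridge fraction of the mean diagonal (as in
#'   [dprime_from_moments()]).
#' @export
population_dprime_fullrank <- function(responses_a, responses_b, ridge = 1e-6) {
  A <- assert_matrixlike(responses_a, "responses_a")
  B <- assert_matrixlike(responses_b, "responses_b")
  dmu <- colMeans(A) - colMeans(B)
  dprime_from_moments(dmu, pooled_cov(A, B), ridge = ridge)
}

# Events x neurons response matrix for one stimulus in one state, applying
# the analysis inclusion rules: reminders excluded; active-state stimulus
# decoding uses correct trials only (hit and correct-reject).
stim_responses <- function(responses, stim, state, correct_only = TRUE) {
  ev <- responses$events
  sel <- ev$stimulus == stim & ev$state == state & !ev$is_reminder
  if (state == "active" && correct_only) {
    sel <- sel & ev$outcome %in% c("hit", "correct_reject")
  }
  responses$z[sel, , drop = FALSE]
}

pair_category <- function(cat_a, cat_b) {
  if (cat_a == "target" && cat_b == "target") return("target_vs_target")
  if (cat_a == "distractor" && cat_b == "distractor") return("distractor_vs_distractor")
  if (setequal(c(cat_a, cat_b), c("target", "catch"))) return("target_vs_catch")
  NA_character_
}

#' Pairwise population decoding across task stimuli
#'
#' For every qualifying stimulus pair (both stimuli presented on at least
#' `min_trials` usable trials in each state), fits a dDR space and
#' computes population d-prime separately per state, labels the pair as
#' task-relevant (target vs catch) or task-irrelevant (target vs target,
#' distractor vs distractor), and reports the engagement-related change
#' both raw (active - passive) and normalized by the sum.
#'
#' @param responses An `evoked_set` (optionally pupil-corrected).
#' @param min_trials Inclusion rule: minimum usable trials per stimulus
#'   per state.
#' @param correct_only Use only correct (hit and correct-reject) active
#'   trials, as in stimulus decoding.
#' @return A tibble of class `decoding_tbl`: one row per pair with
#'   `stim_a`, `stim_b`, `category`, `dprime_active`, `dprime_passive`,
#'   `delta`, `delta_norm` and trial counts. Empty (with a warning) if no
#'   pair qualifies.
#' @export
pairwise_decoding <- function(responses, min_trials = 5, correct_only = TRUE) {
  stopifnot(inherits(responses, "evoked_set"))
  ev <- responses$events
  stim_cat <- ev |>
    dplyr::filter(!.data$is_reminder) |>
    dplyr::distinct(.data$stimulus, .data$category)
  stims <- stim_cat$stimulus
  if (length(stims) < 2) {
    warn("Fewer than two stimuli: no pairs to decode.")
    return(empty_decoding_tbl())
  }
  pairs <- utils::combn(seq_along(stims), 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- stims[pairs[1, j]]; b <- stims[pairs[2, j]]
    categ <- pair_category(stim_cat$category[pairs[1, j]],
                           stim_cat$category[pairs[2, j]])
    if (is.na(categ)) next
    mats <- list(
      aa = stim_responses(responses, a, "active", correct_only),
      ap = stim_responses(responses, a, "passive", correct_only),
      ba = stim_responses(responses, b, "active", correct_only),
      bp = stim_responses(responses, b, "passive", correct_only)
    )
    if (any(vapply(mats, nrow, integer(1)) < min_trials)) next
    d_act <- population_dprime(mats$aa, mats$ba)
    d_pas <- population_dprime(mats$ap, mats$bp)
    rows[[length(rows) + 1]] <- tibble(
      stim_a = a, stim_b = b, category = categ,
      dprime_active = d_act, dprime_passive = d_pas,
      delta = d_act - d_pas,
      delta_norm = (d_act - d_pas) / (d_act + d_pas),
      n_active_a = nrow(mats$aa), n_active_b = nrow(mats$ba),
      n_passive_a = nrow(mats$ap), n_passive_b = nrow(mats$bp)
    )
  }
  if (!length(rows)) {
    warn("No stimulus pair satisfies the minimum-trial rule.")
    return(empty_decoding_tbl())
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("decoding_tbl", class(out))
  out
}

empty_decoding_tbl <- function() {
  out <- tibble(
    stim_a = character(0), stim_b = character(0), category = character(0),
    dprime_active = numeric(0), dprime_passive = numeric(0),
    delta = numeric(0), delta_norm = numeric(0),
    n_active_a = integer(0), n_active_b = integer(0),
    n_passive_a = integer(0), n_passive_b = integer(0)
  )
  class(out) <- c("decoding_tbl", class(out))
  out
}

#' Session-level category means of decoding results
#'
#' Averages the per-pair metric within each category; the session-level
#' unit entering the paired signed-rank tests (one value per category per
#' session, which controls for statistical dependence among pairs
#' recorded together).
#'
#' @param results A `decoding_tbl` (optionally with a `session` column).
#' @param metric Which per-pair column to average.
#' @return Tibble with (`session`,) `category`, `n_pairs`, `mean_value`.
#' @export
category_summary <- function(results, metric = c("delta_norm", "delta",
                                                 "dprime_active", "dprime_passive")) {
  metric <- match.arg(metric)
  if (nrow(results) == 0) {
    warn("No decoding results to summarise.")
    return(tibble(category = character(0), n_pairs = integer(0),
                  mean_value = numeric(0)))
  }
  g <- if ("session" %in% names(results)) c("session", "category") else "category"
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(g))) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_value = mean(.data[[metric]]), .groups = "drop")
}

#' Choice probability: decoding trial outcome from population activity
#'
#' Leave-one-out cross-validated percent correct for classifying hit vs
#' miss trials. Within each fold the dDR space, the optimal linear
#' discrimination axis \eqn{w = \Sigma^{-1}\Delta\mu} and the decision
#' threshold (midpoint of the projected class means) are fitted on the
#' training trials only; the held-out trial is classified by its
#' projection.
#'
#' @param responses_hit,responses_miss Trials x neurons matrices.
#' @param min_trials Minimum trials per class.
#' @return Percent of correctly classified trials (0-100).
#' @export
choice_probability <- function(responses_hit, responses_miss, min_trials = 5) {
  A <- assert_matrixlike(responses_hit, "responses_hit")
  B <- assert_matrixlike(responses_miss, "responses_miss")
  if (nrow(A) == 0 || nrow(B) == 0) abort("Both outcome classes must be non-empty.")
  if (nrow(A) < min_trials || nrow(B) < min_trials) {
    abort(sprintf("Each outcome class needs at least %d trials.", min_trials))
  }
  n <- nrow(A) + nrow(B)
  lab <- c(rep(TRUE, nrow(A)), rep(FALSE, nrow(B)))
  X <- rbind(A, B)
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr_A <- X[lab & seq_len(n) != i, , drop = FALSE]
    tr_B <- X[!lab & seq_len(n) != i, , drop = FALSE]
    sp <- tryCatch(fit_ddr(tr_A, tr_B), error = function(e) NULL)
    if (is.null(sp)) { correct[i] <- NA; next }
    Ap <- tr_A %*% t(sp$proj); Bp <- tr_B %*% t(sp$proj)
    Sg <- pooled_cov(Ap, Bp)
    Sg <- Sg + diag(1e-6 * mean(diag(Sg)), nrow(Sg))
    w <- solve(Sg, colMeans(Ap) - colMeans(Bp))
    thr <- sum(w * (colMeans(Ap) + colMeans(Bp)) / 2)
    score <- sum((X[i, ] %*% t(sp$proj)) * w) - thr
    correct[i] <- (score > 0) == lab[i]
  }
  100 * mean(correct, na.rm = TRUE)
}

#' Choice probability per target stimulus of a session
#'
#' Applies [choice_probability()] to the active hit vs miss trials of each
#' target stimulus with enough trials of both outcomes.
#'
#' @param responses An `evoked_set`.
#' @param min_trials Minimum trials per outcome class.
#' @return Tibble with `stimulus`, `n_hit`, `n_miss`, `percent_correct`.
#' @export
choice_probability_table <- function(responses, min_trials = 5) {
  ev <- responses$events
  targets <- unique(ev$stimulus[ev$category == "target" & !ev$is_reminder])
  rows <- list()
  for (stim in targets) {
    hit <- ev$stimulus == stim & ev$state == "active" & !ev$is_reminder &
      ev$outcome == "hit"
    miss <- ev$stimulus == stim & ev$state == "active" & !ev$is_reminder &
      ev$outcome == "miss"
    if (sum(hit) < min_trials || sum(miss) < min_trials) next
    rows[[stim]] <- tibble(
      stimulus = stim, n_hit = sum(hit), n_miss = sum(miss),
      percent_correct = choice_probability(
        responses$z[hit, , drop = FALSE], responses$z[miss, , drop = FALSE],
        min_trials = min_trials
      )
    )
  }
  dplyr::bind_rows(rows)
}
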