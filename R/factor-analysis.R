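#' Maximum-likelihood factor analysis of spike-count covariance
#'
#' Decomposes the covariance of trial-to-trial population responses into
#' a low-rank shared part and a diagonal private part,
#' \eqn{\Sigma = \Sigma_{shared} + \Psi = L L^\top + \Psi}, by
#' expectation-maximization on the Gaussian likelihood. Fitting is on the
#' covariance scale (no standardization, no rotation), deterministic
#' (spectral initialization), and supports `R = 0` (pure diagonal model).
#'
#' @param responses Trials x neurons matrix.
#' @param R Number of factors (rank of the shared covariance).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `fa_fit`: `loadings` (neurons x R),
#'   `psi` (private variances), `mu` (mean vector), `R`, `loglik`,
#'   `n`, `n_iter`, `converged`.
#' @export
fit_fa <- function(responses, R, max_iter = 5000, tol = 1e-7) {
  X <- assert_matrixlike(responses, "responses")
  n <- nrow(X); p <- ncol(X)
  if (R < 0 || R >= p) abort("`R` must satisfy 0 <= R < n_neurons.")
  if (n < R + 2) abort("Need at least R + 2 trials to fit the factor model.")
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / n # ML covariance
  psi_floor <- 1e-6 * mean(diag(S))
  if (R == 0) {
    psi <- pmax(diag(S), psi_floor)
    ll <- fa_loglik_S(S, n, matrix(0, p, 0), psi)
    return(new_fa_fit(matrix(0, p, 0), psi, mu, 0L, ll, n, 0L, TRUE))
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values[seq_len(R)], psi_floor)
  L <- e$vectors[, seq_len(R), drop = FALSE] %*% diag(sqrt(ev), R)
  psi <- pmax(diag(S) - rowSums(L^2), psi_floor)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Sigma <- tcrossprod(L) + diag(psi)
    beta <- t(solve(Sigma, L)) # R x p
    SB <- S %*% t(beta)        # p x R
    Ezz <- diag(R) - beta %*% L + beta %*% SB
    L <- SB %*% solve(Ezz)
    psi <- pmax(diag(S) - rowSums(L * SB), psi_floor)
    ll <- fa_loglik_S(S, n, L, psi)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    abort(sprintf("Factor-analysis EM did not converge in %d iterations.", max_iter))
  }
  new_fa_fit(L, psi, mu, as.integer(R), ll_old, n, iter, TRUE)
}

new_fa_fit <- function(L, psi, mu, R, loglik, n, n_iter, converged) {
  structure(
    list(loadings = L, psi = psi, mu = mu, R = R, loglik = loglik,
         n = n, n_iter = n_iter, converged = converged),
    class = "fa_fit"
  )
}

# Gaussian log-likelihood of a fitted (L, psi) given a sample covariance
# S computed from n observations (means profiled out).
fa_loglik_S <- function(S, n, L, psi) {
  p <- nrow(S)
  Sigma <- if (NCOL(L) > 0) tcrossprod(L) + diag(psi) else diag(psi, p)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  -n / 2 * (p * log(2 * pi) + logdet + tr)
}

#' Log-likelihood of held-out responses under a factor-analysis fit
#'
#' @param fit An `fa_fit`.
#' @param responses Trials x neurons matrix evaluated under the fitted
#'   Gaussian (mean from the fit).
#' @export
fa_loglik <- function(fit, responses) {
  X <- assert_matrixlike(responses, "responses")
  Xc <- sweep(X, 2, fit$mu)
  S <- crossprod(Xc) / nrow(X)
  fa_loglik_S(S, nrow(X), fit$loadings, fit$psi)
}

#' @export
print.fa_fit <- function(x, ...) {
  cat(sprintf("<fa_fit> %d neurons, R = %d, logLik = %.2f (n = %d, %d EM iterations)\n",
              length(x$psi), x$R, x$loglik, x$n, x$n_iter))
  invisible(x)
}

#' @rdname tidy_popdprime
#' @export
tidy.fa_fit <- function(x, ...) {
  if (x$R == 0) {
    return(tibble(neuron = integer(0), factor = integer(0),
                  loading = numeric(0), psi = numeric(0)))
  }
  Lr <- rotated_loadings(x)
  tibble(
    neuron = rep(seq_along(x$psi), times = x$R),
    factor = rep(seq_len(x$R), each = length(x$psi)),
    loading = as.vector(Lr),
    psi = rep(x$psi, times = x$R)
  )
}

#' @rdname tidy_popdprime
#' @export
glance.fa_fit <- function(x, ...) {
  tibble(
    R = x$R, loglik = x$loglik, n = x$n, n_iter = x$n_iter,
    percent_shared_variance = percent_shared_variance(x),
    loading_similarity = if (x$R >= 1) loading_similarity(x) else NA_real_
  )
}

# Orthonormal rotation of the factor space so factor variances are ordered:
# SVD of L; columns of the rotated loadings are orthogonal with decreasing
# contribution to tr(LL').
rotated_loadings <- function(fit) {
  if (fit$R == 0) return(fit$loadings)
  sv <- svd(fit$loadings)
  sv$u %*% diag(sv$d, fit$R)
}

#' Dominant shared-variability axis of a factor model
#'
#' Unit-norm loading vector of the factor explaining the most shared
#' variance (after orthonormal rotation ordering the factors); the
#' "noise axis" used in alignment analyses.
#'
#' @param fit An `fa_fit` with `R >= 1`.
#' @export
dominant_factor <- function(fit) {
  if (fit$R < 1) abort("The fit has no factors (R = 0).")
  w <- rotated_loadings(fit)[, 1]
  w <- w * sign(w[which.max(abs(w))])
  unitize(w, "dominant factor")
}

#' Loading similarity of the dominant factor
#'
#' \eqn{1 - N \mathrm{Var}(w)} for the unit-norm dominant loading vector
#' `w` of `N` neurons (population variance), clipped to `[0, 1]`: 1 means
#' all neurons load identically, 0 maximal dissimilarity. Invariant to a
#' global sign flip.
#'
#' @param fit An `fa_fit` with `R >= 1`.
#' @export
loading_similarity <- function(fit) {
  w <- dominant_factor(fit)
  N <- length(w)
  v <- mean((w - mean(w))^2)
  min(max(1 - N * v, 0), 1)
}

#' Percent shared variance
#'
#' Mean over neurons of the percentage of each neuron's variance that is
#' explained by the shared factors:
#' \eqn{100\,\mathrm{diag}(LL^\top) / (\mathrm{diag}(LL^\top) + \Psi)}.
#'
#' @param fit An `fa_fit`.
#' @export
percent_shared_variance <- function(fit) {
  sh <- if (fit$R > 0) rowSums(fit$loadings^2) else rep(0, length(fit$psi))
  mean(100 * sh / (sh + fit$psi))
}

#' Alignment of two population axes
#'
#' Absolute cosine similarity, \eqn{|u \cdot v| / (\|u\| \|v\|)}: 0 for
#' orthogonal axes, 1 for parallel (sign and scale are irrelevant).
#'
#' @param axis_u,axis_v Nonzero numeric vectors of equal length.
#' @export
alignment <- function(axis_u, axis_v) {
  stopifnot(length(axis_u) == length(axis_v))
  abs(sum(unitize(axis_u, "axis_u") * unitize(axis_v, "axis_v")))
}

#' Select factor-analysis dimensionality by cross-validated likelihood
#'
#' In-sample likelihood is non-decreasing in `R`, so the number of factors
#' is chosen as the `R` in `r_grid` maximizing the k-fold cross-validated
#' log-likelihood.
#'
#' @param responses Trials x neurons matrix.
#' @param R_max Largest rank considered.
#' @param folds Number of cross-validation folds.
#' @param r_grid Candidate ranks (default `1:R_max`; include 0 to allow
#'   an independent-neuron model).
#' @param seed Seed for the fold assignment.
#' @return List with `R` (the selected rank), and `cv` (tibble of rank vs
#'   summed held-out log-likelihood).
#' @export
select_dimensionality <- function(responses, R_max, folds = 10,
                                  r_grid = seq_len(R_max), seed = 1L) {
  X <- assert_matrixlike(responses, "responses")
  if (R_max >= ncol(X)) abort("`R_max` must be smaller than the number of neurons.")
  if (nrow(X) < folds) abort("Fewer trials than cross-validation folds.")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(folds), length.out = nrow(X)))
  ll <- vapply(r_grid, function(R) {
    sum(vapply(seq_len(folds), function(k) {
      fit <- fit_fa(X[fold != k, , drop = FALSE], R)
      fa_loglik(fit, X[fold == k, , drop = FALSE])
    }, numeric(1)))
  }, numeric(1))
  list(R = r_grid[which.max(ll)], cv = tibble(R = r_grid, cv_loglik = ll))
}

#' Factor-analysis covariability metrics for a session
#'
#' Fits a factor model per behavioral state to the single-trial responses
#' to the catch stimulus (the stimulus common to all target-vs-catch
#' discriminations, so covariance is stimulus-independent), and reports
#' dimensionality, percent shared variance, loading similarity, and the
#' alignment of the dominant covariability axis with each target-vs-catch
#' discrimination (signal) axis.
#'
#' @param responses An `evoked_set`.
#' @param rank Fixed rank, or `NULL` to select by cross-validation.
#' @param R_max,folds Passed to [select_dimensionality()] when
#'   `rank = NULL`.
#' @param min_trials Minimum catch trials per state.
#' @param seed Seed for fold assignment.
#' @return List with `metrics` (per-state tibble) and `alignments`
#'   (per-state, per-target tibble), plus the underlying `fits`.
#' @export
covariability_metrics <- function(responses, rank = NULL, R_max = 5,
                                  folds = 10, min_trials = 5, seed = 1L) {
  stopifnot(inherits(responses, "evoked_set"))
  ev <- responses$events
  targets <- unique(ev$stimulus[ev$category == "target" & !ev$is_reminder])
  fits <- list(); metrics <- list(); aligns <- list()
  for (state in c("active", "passive")) {
    Xc <- stim_responses(responses, "catch", state)
    if (nrow(Xc) < max(min_trials, 3)) {
      warn(sprintf("Too few catch trials in the %s state; skipping.", state))
      next
    }
    R <- rank %||% select_dimensionality(
      Xc, R_max = min(R_max, ncol(Xc) - 1),
      folds = min(folds, nrow(Xc)), seed = seed
    )$R
    fit <- fit_fa(Xc, R)
    fits[[state]] <- fit
    metrics[[state]] <- tibble(
      state = state, n_trials = nrow(Xc), R = fit$R,
      percent_shared_variance = percent_shared_variance(fit),
      loading_similarity = if (fit$R >= 1) loading_similarity(fit) else NA_real_
    )
    if (fit$R >= 1) {
      noise_ax <- dominant_factor(fit)
      aligns[[state]] <- purrr::map(targets, function(tg) {
        Xt <- stim_responses(responses, tg, state)
        if (nrow(Xt) < min_trials) return(NULL)
        dmu <- colMeans(Xt) - colMeans(Xc)
        tibble(state = state, target = tg,
               alignment = alignment(noise_ax, dmu))
      }) |> dplyr::bind_rows()
    }
  }
  list(metrics = dplyr::bind_rows(metrics),
       alignments = dplyr::bind_rows(aligns), fits = fits)
}
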