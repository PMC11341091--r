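mk_fits <- function(p = 12, seed = 50, equal_means = FALSE) {
  set.seed(seed)
  mk <- function(mu_shift, l_sd, psi_lo) {
    fake_fa_fit(matrix(rnorm(p, 0, l_sd), p, 1), runif(p, psi_lo, psi_lo + 1),
                mu = rnorm(p, mu_shift))
  }
  act <- list(catch = mk(0, 1.2, 0.5), target_0dB = mk(2, 1.2, 0.5))
  pas <- if (equal_means) {
    list(catch = fake_fa_fit(act$catch$loadings * 0.5, act$catch$psi * 2,
                             act$catch$mu),
         target_0dB = fake_fa_fit(act$target_0dB$loadings * 0.5,
                                  act$target_0dB$psi * 2, act$target_0dB$mu))
  } else {
    list(catch = mk(0, 0.8, 1), target_0dB = mk(1, 0.8, 1))
  }
  list(active = act, passive = pas)
}

test_that("ablation models tie exactly the parameters they are meant to tie", {
  fits <- mk_fits()
  fa <- fits$active$target_0dB; fp <- fits$passive$target_0dB
  mp <- function(m) popdprime:::model_params(fa, fp, m, "passive")
  expect_identical(mp("null"),
                   list(mu = fa$mu, L = fa$loadings, psi = fa$psi))
  expect_identical(mp("gain_only"),
                   list(mu = fp$mu, L = fa$loadings, psi = fa$psi))
  expect_identical(mp("indep_var"),
                   list(mu = fp$mu, L = fa$loadings, psi = fp$psi))
  expect_identical(mp("shared_var"),
                   list(mu = fp$mu, L = fp$loadings, psi = fp$psi))
  # active draws always use the active estimates
  for (m in sim_models()) {
    expect_identical(popdprime:::model_params(fa, fp, m, "active"),
                     list(mu = fa$mu, L = fa$loadings, psi = fa$psi))
  }
})

test_that("null-model simulations are statistically identical across states", {
  fits <- mk_fits(seed = 51)
  sim <- simulate_population(fits, "null", n_samples = 2000, seed = 2)
  for (stim in c("catch", "target_0dB")) {
    act <- sim$z[sim$events$state == "active" & sim$events$stimulus == stim, ]
    pas <- sim$z[sim$events$state == "passive" & sim$events$stimulus == stim, ]
    se <- sqrt(apply(act, 2, var) / nrow(act) + apply(pas, 2, var) / nrow(pas))
    expect_true(all(abs(colMeans(act) - colMeans(pas)) < 3.9 * se))
  }
})

test_that("gain-only with equal means reduces to the null model", {
  fits <- mk_fits(seed = 52, equal_means = TRUE)
  fa <- fits$active$catch; fp <- fits$passive$catch
  g <- popdprime:::model_params(fa, fp, "gain_only", "passive")
  n <- popdprime:::model_params(fa, fp, "null", "passive")
  expect_identical(g, n)
})

test_that("shared-variance simulations reproduce the per-state covariance", {
  fits <- mk_fits(seed = 53)
  sim <- simulate_population(fits, "shared_var", n_samples = 2000, seed = 3)
  frob <- function(M) sqrt(sum(M^2))
  for (state in c("active", "passive")) {
    f <- fits[[state]]$catch
    S_true <- tcrossprod(f$loadings) + diag(f$psi)
    S_hat <- cov(sim$z[sim$events$state == state &
                         sim$events$stimulus == "catch", ])
    expect_lt(frob(S_hat - S_true) / frob(S_true), 0.10)
  }
})

test_that("selective enhancement is the category-mean difference", {
  res <- tibble::tibble(
    category = c("target_vs_catch", "target_vs_catch", "target_vs_target"),
    delta = c(0.5, 0.3, 0.1), delta_norm = c(0.5, 0.3, 0.1)
  )
  expect_equal(selective_enhancement(res), 0.3)
  res_eq <- tibble::tibble(
    category = c("target_vs_catch", "target_vs_target"),
    delta = c(0.2, 0.2), delta_norm = c(0.2, 0.2)
  )
  expect_equal(selective_enhancement(res_eq), 0)
  expect_error(selective_enhancement(res[3, ]), "both")
})

test_that("model performance is the Pearson correlation across sessions", {
  x <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  expect_equal(model_performance(x, x), 1)
  expect_equal(model_performance(x, -x), -1)
  expect_error(model_performance(x[1:2], x[1:2]), "3 sessions")
  # independent draws at 12 sessions rarely exceed |r| = 0.6
  set.seed(54)
  big <- vapply(1:400, function(i) {
    abs(cor(rnorm(12), rnorm(12)))
  }, numeric(1))
  expect_gte(mean(big < 0.6), 0.95)
})

test_that("bootstrap model comparison flags clearly worse models only", {
  set.seed(55)
  actual <- rnorm(12)
  sims <- list(
    shared_var = actual + rnorm(12, 0, 0.1),
    null = rnorm(12)
  )
  cmp <- model_comparison(sims, actual, n_boot = 500, seed = 1)
  expect_false(cmp$significantly_worse[cmp$model == "shared_var"])
  expect_true(cmp$significantly_worse[cmp$model == "null"])
  expect_error(model_comparison(sims, actual, n_boot = 0), "positive")
  expect_error(model_comparison(sims["null"], actual), "missing")
})

test_that("analytic model errors shrink along the ablation nesting", {
  # ground truth where engagement changes gain, raises private variance
  # AND rotates the shared axis: each added state-dependent parameter
  # brings the model's predicted engagement effect closer to the truth.
  # (With concordant changes the errors compound; a variance decrease can
  # instead cancel the rotation error and break the ordering.)
  cfg <- session_config(n_neurons = 30, seed = 57)
  tr <- ground_truth(cfg, "A1_like", state_noise_change = "rotate",
                     psi_active_scale = 1.5, rotate_frac = 0.7, pupil_frac = 0)
  mkfit <- function(state, stim) {
    fake_fa_fit(tr[[paste0("loadings_", state)]], tr[[paste0("psi_", state)]],
                tr[[paste0("mu_", state)]][, stim])
  }
  d_an <- function(par_a, par_b) {
    dmu <- par_a$mu - par_b$mu
    Sg <- (tcrossprod(par_a$L) + diag(par_a$psi) +
             tcrossprod(par_b$L) + diag(par_b$psi)) / 2
    sqrt(drop(crossprod(dmu, solve(Sg, dmu))))
  }
  pairs <- lapply(grep("^target", tr$stimuli, value = TRUE),
                  function(t1) c(t1, "catch"))
  err <- sapply(sim_models()[-1], function(m) {
    mean(sapply(pairs, function(pr) {
      fa1 <- mkfit("active", pr[1]); fa2 <- mkfit("active", pr[2])
      fp1 <- mkfit("passive", pr[1]); fp2 <- mkfit("passive", pr[2])
      p_a1 <- popdprime:::model_params(fa1, fp1, m, "active")
      p_a2 <- popdprime:::model_params(fa2, fp2, m, "active")
      p_p1 <- popdprime:::model_params(fa1, fp1, m, "passive")
      p_p2 <- popdprime:::model_params(fa2, fp2, m, "passive")
      delta_m <- d_an(p_a1, p_a2) - d_an(p_p1, p_p2)
      delta_true <- truth_dprime(tr, pr[1], pr[2], "active") -
        truth_dprime(tr, pr[1], pr[2], "passive")
      abs(delta_m - delta_true)
    }))
  })
  expect_lte(err[["shared_var"]], err[["indep_var"]] + 1e-9)
  expect_lte(err[["indep_var"]], err[["gain_only"]] + 1e-9)
})
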