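test_that("dDR axes are orthogonalized by Gram-Schmidt", {
  # residual variance exactly along (1,1); signal along (1,0)
  t_res <- c(-1, -0.5, 0.5, 1, -0.8, 0.8)
  A <- cbind(0.5 + t_res, t_res)
  B <- cbind(-0.5 + t_res, t_res)
  sp <- fit_ddr(A, B)
  expect_equal(sp$signal, c(1, 0), tolerance = 1e-12)
  expect_equal(abs(sp$noise), c(0, 1), tolerance = 1e-10)
  expect_lt(abs(sum(sp$signal * sp$noise)), 1e-8)
  expect_equal(unname(sp$proj %*% sp$signal), cbind(c(1, 0)), tolerance = 1e-10)
  # already-orthogonal case in 3-D
  set.seed(1)
  A3 <- cbind(2 + rnorm(200, 0, 0.01), rnorm(200, 0, 2), rnorm(200, 0, 0.01))
  B3 <- cbind(-2 + rnorm(200, 0, 0.01), rnorm(200, 0, 2), rnorm(200, 0, 0.01))
  sp3 <- fit_ddr(A3, B3)
  expect_gt(abs(sp3$signal[1]), 0.99)
  expect_gt(abs(sp3$noise[2]), 0.99)
  expect_error(fit_ddr(A, A), "signal axis undefined")
})

test_that("moment-based d-prime matches closed forms exactly", {
  expect_equal(dprime_from_moments(c(1, 0), diag(2)), 1, tolerance = 1e-14)
  expect_equal(dprime_from_moments(c(1, 1), diag(2)), sqrt(2), tolerance = 1e-14)
  expect_equal(dprime_from_moments(c(1, 0), diag(c(4, 1))), 0.5, tolerance = 1e-14)
  expect_error(dprime_from_moments(c(1, 0), matrix(0, 2, 2)), "singular")
})

test_that("dDR d-prime matches the generating Gaussian's closed form", {
  set.seed(30)
  p <- 10; n <- 5000
  l <- rnorm(p); psi <- runif(p, 0.8, 1.2); dmu <- rnorm(p, 0.4, 0.3)
  Sg <- tcrossprod(l) + diag(psi)
  d_true <- sqrt(drop(t(dmu) %*% solve(Sg, dmu)))
  A <- popdprime:::rmvn_factor(n, dmu / 2, matrix(l), psi)
  B <- popdprime:::rmvn_factor(n, -dmu / 2, matrix(l), psi)
  expect_equal(population_dprime(A, B), d_true, tolerance = 0.05)
  # the 2-D projection can never beat the full-space analytic value
  expect_lt(population_dprime(A, B), d_true * 1.05)
})

test_that("d-prime is invariant to a common invertible linear transform", {
  set.seed(31)
  p <- 8; n <- 4000
  l <- rnorm(p); psi <- runif(p, 0.8, 1.2); dmu <- rnorm(p, 0.4, 0.3)
  A <- popdprime:::rmvn_factor(n, dmu / 2, matrix(l), psi)
  B <- popdprime:::rmvn_factor(n, -dmu / 2, matrix(l), psi)
  d0 <- population_dprime(A, B)
  M <- qr.Q(qr(matrix(rnorm(p * p), p))) # random rotation
  expect_equal(population_dprime(A %*% M, B %*% M), d0, tolerance = 0.10)
})

test_that("pairwise decoding enumerates the task-defined categories", {
  set.seed(32)
  mats <- function(mu) matrix(rnorm(8 * 4, mu), 8, 4)
  z <- rbind(mats(0), mats(1), mats(0.5), mats(-0.5),
             mats(0), mats(1), mats(0.5), mats(-0.5))
  resp <- fake_evoked(
    z,
    stimulus = rep(rep(c("target_0dB", "catch", "dist_1", "dist_2"), each = 8), 2),
    state = rep(c("active", "passive"), each = 32),
    category = rep(rep(c("target", "catch", "distractor", "distractor"), each = 8), 2)
  )
  res <- pairwise_decoding(resp, min_trials = 5)
  expect_equal(sum(res$category == "target_vs_catch"), 1)
  expect_equal(sum(res$category == "distractor_vs_distractor"), 1)
  expect_equal(sum(res$category == "target_vs_target"), 0)
  expect_true(all(res$dprime_active >= 0))
  expect_true(all(abs(res$delta_norm) <= 1))
  # raising the inclusion bar empties the result
  expect_warning(res2 <- pairwise_decoding(resp, min_trials = 10),
                 "minimum-trial")
  expect_equal(nrow(res2), 0)
})

test_that("state-identical data give delta d-prime centered on zero", {
  set.seed(33)
  deltas <- replicate(20, {
    z <- matrix(rnorm(40 * 6), 40, 6)
    z[1:10, 1] <- z[1:10, 1] + 1.5
    z[21:30, 1] <- z[21:30, 1] + 1.5
    resp <- fake_evoked(
      z,
      stimulus = rep(rep(c("target_0dB", "catch"), each = 10), 2),
      state = rep(c("active", "passive"), each = 20),
      category = rep(rep(c("target", "catch"), each = 10), 2)
    )
    pairwise_decoding(resp)$delta
  })
  expect_lt(abs(mean(deltas)), 0.25)
})

test_that("category summary averages within category and session", {
  res <- tibble::tibble(
    stim_a = c("t1", "t1", "t2"), stim_b = c("catch", "t2", "catch"),
    category = c("target_vs_catch", "target_vs_target", "target_vs_catch"),
    delta = c(0.1, 0.3, 0.3), delta_norm = c(0.1, 0.3, 0.3)
  )
  cs <- category_summary(res, metric = "delta")
  expect_equal(cs$mean_value[cs$category == "target_vs_catch"], 0.2)
  expect_equal(cs$mean_value[cs$category == "target_vs_target"], 0.3)
  expect_warning(category_summary(res[0, ]), "No decoding results")
})

test_that("choice probability is perfect for separated classes and symmetric", {
  set.seed(34)
  A <- matrix(rnorm(20 * 5, 10), 20, 5)
  B <- matrix(rnorm(20 * 5, -10), 20, 5)
  expect_equal(choice_probability(A, B), 100)
  # symmetric under class relabeling
  A2 <- matrix(rnorm(15 * 5, 0.5), 15, 5)
  B2 <- matrix(rnorm(15 * 5), 15, 5)
  expect_equal(choice_probability(A2, B2), choice_probability(B2, A2))
  expect_error(choice_probability(A[0, ], B), "non-empty")
  expect_error(choice_probability(A[1:3, ], B), "at least")
})
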