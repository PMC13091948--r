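test_that("EM log-likelihood is non-decreasing on simulated panels", {
  for (seed in c(2, 11, 23)) {
    sim <- simulate_ema(two_class_config(n_subjects = 30, seed = seed,
      missing = 0.2
    ))
    ld <- lcgmm_data(outcome_data(sim))
    start <- lcgmm_params(
      matrix(c(40, rep(0, ld$p - 1), 50, rep(0, ld$p - 1)), ld$p, 2),
      5, 8, c(0.5, 0.5)
    )
    fit <- fit_em(ld, start, max_iter = 200)
    expect_true(all(diff(fit$loglik_trace) >= -1e-7 * abs(fit$loglik)))
  }
})

test_that("EM started at a stationary point stays there", {
  sim <- simulate_ema(two_class_config(n_subjects = 40, seed = 7))
  ld <- lcgmm_data(outcome_data(sim))
  fit <- grid_search_fit(ld, 2, n_starts = 5, seed = 1, reorder = FALSE)
  refit <- fit_em(ld, fit$params, max_iter = 50)
  expect_lte(refit$n_iterations, 2)
  expect_equal(refit$params$beta, fit$params$beta, tolerance = 1e-2)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-7)
})

test_that("well-separated two-class simulation recovers intercepts within 2 points", {
  sim <- simulate_ema(two_class_config(n_subjects = 80, sigma_b = 3,
    sigma_eps = 5, seed = 31
  ))
  ld <- lcgmm_data(outcome_data(sim))
  fit <- grid_search_fit(ld, 2, n_starts = 10, seed = 2)
  intercepts <- sort(fit$params$beta[1, ])
  expect_lt(abs(intercepts[1] - 20), 2)
  expect_lt(abs(intercepts[2] - 70), 2)
  acc <- fit_accuracy(fit, sim$truth)
  expect_gte(acc$accuracy, 0.95)
})

test_that("one-class fit matches an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  sim <- simulate_ema(sim_config(
    n_subjects = 50, n_days = 30, class_proportions = 1,
    class_anchor_curves = list(
      data.frame(day = c(0, 15, 29), value = c(50, 40, 45))
    ),
    sigma_b = 6, sigma_eps = 5, seed = 9
  ))
  ld <- lcgmm_data(outcome_data(sim))
  f1 <- fit_one_class(ld)
  mdf <- data.frame(y = ld$y, X = I(ld$X[, -1]), subj = ld$subj)
  m <- lme4::lmer(y ~ X + (1 | subj), data = mdf, REML = FALSE)
  expect_equal(f1$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(f1$params$beta[, 1]), unname(lme4::fixef(m)),
    tolerance = 1e-5
  )
  expect_equal(f1$params$sigma_b,
    unname(attr(lme4::VarCorr(m)[[1]], "stddev")),
    tolerance = 1e-3
  )
  expect_equal(f1$beta_se, unname(sqrt(diag(as.matrix(vcov(m))))),
    tolerance = 1e-3
  )
  # consistency with the mixture likelihood at G = 1
  expect_equal(f1$loglik, mixture_loglik(ld, f1$params), tolerance = 1e-10)
})

test_that("one-class fit of constant noise-free data degenerates gracefully", {
  const <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 10),
    day = rep(0:9, 3), value = 42
  )
  ld <- lcgmm_data(const, spline_basis_spec(1))
  f <- fit_one_class(ld)
  expect_equal(unname(f$params$beta[1, 1]), 42, tolerance = 1e-6)
  expect_lt(f$params$sigma_eps, 0.01)
  expect_lt(f$params$sigma_b, 0.01)
})

test_that("grid search delegates at G = 1 and is deterministic in its seed", {
  sim <- simulate_ema(two_class_config(n_subjects = 25, seed = 13))
  ld <- lcgmm_data(outcome_data(sim))
  g1 <- grid_search_fit(ld, 1, seed = 5)
  f1 <- fit_one_class(ld)
  expect_equal(g1$loglik, f1$loglik)

  fa <- grid_search_fit(ld, 2, n_starts = 8, seed = 99)
  fb <- grid_search_fit(ld, 2, n_starts = 8, seed = 99)
  expect_identical(fa$params, fb$params)
  expect_identical(fa$posterior, fb$posterior)
})

test_that("parameter counting follows G(1+df) + (G-1) + 2", {
  expect_identical(count_parameters(1, 3), 6L)
  expect_identical(count_parameters(4, 3), 21L)
  expect_error(count_parameters(2, 0), "at least 1")
})

test_that("classes are reported ordered by day-0 level, optimizer labels kept", {
  sim <- simulate_ema(two_class_config(n_subjects = 40, seed = 17))
  ld <- lcgmm_data(outcome_data(sim))
  fit <- grid_search_fit(ld, 2, n_starts = 6, seed = 3)
  day0 <- predict_class_trajectory(fit, days = 0)
  expect_true(diff(day0$estimate) <= 0)
  expect_setequal(fit$relabeling, 1:2)
})

test_that("random-intercept variance is recovered at large n", {
  sim <- simulate_ema(sim_config(
    n_subjects = 500, n_days = 30, class_proportions = 1,
    class_anchor_curves = list(
      data.frame(day = c(0, 29), value = c(45, 40))
    ),
    sigma_b = 8, sigma_eps = 6, seed = 41
  ))
  ld <- lcgmm_data(outcome_data(sim))
  f <- fit_one_class(ld)
  expect_lt(abs(f$params$sigma_b - 8) / 8, 0.25)
  expect_lt(abs(f$params$sigma_eps - 6) / 6, 0.1)
})

test_that("trajectory bands narrow with sample size and cover the truth", {
  fits <- lapply(c(50, 500), function(n) {
    sim <- simulate_ema(sim_config(
      n_subjects = n, n_days = 30, class_proportions = 1,
      class_anchor_curves = list(
        data.frame(day = c(0, 29), value = c(45, 40))
      ),
      sigma_b = 6, sigma_eps = 5, seed = 19
    ))
    fit_one_class(lcgmm_data(outcome_data(sim)))
  })
  tr_small <- predict_class_trajectory(fits[[1]])
  tr_large <- predict_class_trajectory(fits[[2]])
  w_small <- mean(tr_small$conf_high - tr_small$conf_low)
  w_large <- mean(tr_large$conf_high - tr_large$conf_low)
  expect_lt(w_large, w_small / 2)

  flat <- lcgmm_params(
    matrix(c(33, rep(0, fits[[1]]$spec$df)), ncol = 1), 1, 1, 1
  )
  fits[[1]]$params <- flat
  tr_flat <- predict_class_trajectory(fits[[1]])
  expect_equal(tr_flat$estimate, rep(33, nrow(tr_flat)))
})

test_that("degenerate mixtures are flagged, not silently returned", {
  # three tight identical subjects cannot support two classes
  const <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 8),
    day = rep(0:7, 2), value = rep(c(30, 31), each = 8)
  )
  ld <- lcgmm_data(const, spline_basis_spec(1))
  start <- lcgmm_params(
    matrix(c(30, 0, 90, 0), 2, 2), 1, 1, c(0.999, 0.001)
  )
  fit <- fit_em(ld, start, max_iter = 50)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "degenerate")
})
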