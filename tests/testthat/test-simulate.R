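test_that("study-scale default configuration matches the published design", {
  cfg <- default_study_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(length(cfg$class_proportions), 4)
  expect_equal(cfg$class_proportions[2], 0.401)
  expect_equal(cfg$class_anchor_curves[[3]]$value[1], 60)
  expect_equal(cfg$missing_raw_fraction, 0.225)
  expect_equal(cfg$n_subjects, 147L)
  expect_equal(cfg$n_days, 84L)
})

test_that("class mean curves pass exactly through their anchors", {
  cfg <- default_study_config()
  curves <- class_mean_curves(cfg)
  for (g in seq_along(cfg$class_anchor_curves)) {
    ac <- cfg$class_anchor_curves[[g]]
    got <- curves$mean[curves$class == g][ac$day + 1]
    expect_equal(got, ac$value)
  }
  expect_true(all(curves$mean >= 0 & curves$mean <= 100))
})

test_that("noise-free simulation reproduces the class mean tabulation", {
  cfg <- default_study_config(
    n_subjects = 12, sigma_b = 0, sigma_eps = 0,
    missing_raw_fraction = 0, seed = 4
  )
  sim <- simulate_ema(cfg)
  joined <- outcome_data(sim) |>
    dplyr::inner_join(sim$truth, by = "subject_id") |>
    dplyr::inner_join(sim$class_means,
      by = c(class_label = "class", "day")
    )
  expect_equal(joined$value, joined$mean)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- default_study_config(n_subjects = 20, seed = 77)
  sim1 <- simulate_ema(cfg)
  sim2 <- simulate_ema(cfg)
  expect_identical(sim1$panel, sim2$panel)
  expect_identical(sim1$truth, sim2$truth)
})

test_that("empirical class frequencies converge to the mixing proportions", {
  cfg <- default_study_config(n_subjects = 5000, seed = 8,
    missing_raw_fraction = 0
  )
  sim <- simulate_ema(cfg)
  freq <- as.vector(table(factor(sim$truth$class_label, levels = 1:4))) / 5000
  expect_true(all(abs(freq - cfg$class_proportions) <= 0.02))
})

test_that("every emitted value lies on the 0-100 scale even under heavy noise", {
  cfg <- default_study_config(n_subjects = 30, sigma_b = 40, sigma_eps = 40,
    seed = 2
  )
  sim <- simulate_ema(cfg)
  expect_true(all(sim$panel$value >= 0 & sim$panel$value <= 100))
})

test_that("anchors outside the day range are rejected", {
  expect_error(
    sim_config(
      n_subjects = 5, n_days = 10, class_proportions = 1,
      class_anchor_curves = list(data.frame(day = c(0, 20), value = c(10, 20)))
    ),
    "outside"
  )
  expect_error(
    default_study_config(class_proportions = c(0.5, 0.4)),
    "sum to 1"
  )
})

test_that("MCAR missingness hits the target fraction and fraction 0 is identity", {
  cfg <- default_study_config(n_subjects = 500, seed = 3)
  sim <- simulate_ema(cfg)
  n_expected <- 500 * 84
  outcome <- dplyr::filter(sim$panel, item == cfg$outcome_item)
  realized <- 1 - nrow(outcome) / n_expected
  expect_lt(abs(realized - 0.225), 0.01)

  cfg0 <- default_study_config(n_subjects = 10, missing_raw_fraction = 0,
    seed = 5
  )
  sim0 <- simulate_ema(cfg0)
  panel0 <- apply_missingness(sim0$panel, cfg0)
  expect_identical(panel0, sim0$panel)
  expect_error(
    sim_config(
      n_subjects = 2, class_proportions = 1,
      class_anchor_curves = list(data.frame(day = 0, value = 1)),
      missing_raw_fraction = 1
    ),
    "must be in"
  )
})

test_that("MAR-age missingness increases missing days with age", {
  cfg <- default_study_config(
    n_subjects = 400, missingness_mode = "MAR-age", seed = 21
  )
  sim <- simulate_ema(cfg)
  outcome <- dplyr::filter(sim$panel, item == cfg$outcome_item)
  obs <- dplyr::count(outcome, subject_id)
  df <- dplyr::inner_join(sim$truth, obs, by = "subject_id")
  missing_days <- 84 - df$n
  expect_gt(cor(df$age, missing_days), 0.2)
})

test_that("simulated baseline scores respect their instrument bounds", {
  cfg <- default_study_config(n_subjects = 300, seed = 6)
  sim <- simulate_ema(cfg)
  bl <- simulate_baseline(sim$truth, cfg)
  expect_true(all(bl$THI_pre >= 0 & bl$THI_pre <= 100))
  expect_true(all(bl$THI_post >= 0 & bl$THI_post <= 100))
  expect_true(all(bl$PHQ9_pre >= 0 & bl$PHQ9_pre <= 27))
  expect_true(all(bl$PHQ9_post >= 0 & bl$PHQ9_post <= 27))
  expect_true(all(bl$age >= 18 & bl$age <= 80))
  expect_true(all(bl$extraversion >= 12 & bl$extraversion <= 60))
})

test_that("a class-linked THI change shift is detected with high power", {
  # one class improves 10 points more than the rest; ANOVA on the change
  # score across true classes should reject essentially always at n = 150
  hits <- vapply(1:40, function(r) {
    cfg <- default_study_config(n_subjects = 150, seed = 1000 + r)
    sim <- simulate_ema(cfg)
    bl <- simulate_baseline(sim$truth, cfg,
      class_effects = list(THI_change = c(-10, 0, 0, 0))
    )
    change <- bl$THI_post - bl$THI_pre
    p <- summary(aov(change ~ factor(sim$truth$class_label)))[[1]][["Pr(>F)"]][1]
    p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("config round-trips through YAML", {
  cfg <- default_study_config(seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$class_proportions, cfg$class_proportions)
  expect_equal(
    cfg2$class_anchor_curves[[3]]$value,
    cfg$class_anchor_curves[[3]]$value
  )
  expect_identical(simulate_ema(cfg2)$panel, simulate_ema(cfg)$panel)
})
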