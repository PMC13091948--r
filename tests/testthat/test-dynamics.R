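test_that("reverse coding is an involution fixing the midpoint", {
  expect_equal(reverse_code(0), 100)
  expect_equal(reverse_code(50), 50)
  x <- c(0, 12.5, 99, 100)
  expect_equal(reverse_code(reverse_code(x)), x)
  expect_error(reverse_code(101), "\\[0, 100\\]")
})

test_that("standardized difference is an exact per-subject z score", {
  df <- tibble::tibble(
    subject_id = "s1", item = rep(c("loud", "dis"), each = 3),
    day = rep(0:2, 2), value = c(11, 22, 33, 10, 20, 30)
  )
  sd1 <- standardized_difference(df, "loud", "dis")
  expect_equal(sd1$d, c(1, 2, 3))
  expect_equal(sd1$z, c(-1, 0, 1))

  # location shifts of loudness leave z unchanged
  df2 <- dplyr::mutate(df,
    value = ifelse(item == "loud", value + 7, value)
  )
  expect_equal(standardized_difference(df2, "loud", "dis")$z, sd1$z)

  # constant difference: subject reported and excluded
  dfc <- dplyr::mutate(df, value = ifelse(item == "loud", 60, 20))
  sdc <- standardized_difference(dfc, "loud", "dis")
  expect_equal(attr(sdc, "excluded"), "s1")
  expect_equal(nrow(sdc), 0)

  expect_error(standardized_difference(df, "nope", "dis"), "Unknown item")
})

test_that("z is standardized within every subject of a random panel", {
  panel <- dplyr::bind_rows(
    dplyr::mutate(random_gapped_panel(5, 40, 0.2, seed = 3), item = "loud"),
    dplyr::mutate(random_gapped_panel(5, 40, 0.2, seed = 4), item = "dis")
  )
  sdz <- standardized_difference(panel, "loud", "dis")
  per <- sdz |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(z), s = sd(z))
  expect_equal(per$m, rep(0, nrow(per)), tolerance = 1e-10)
  expect_equal(per$s, rep(1, nrow(per)), tolerance = 1e-10)
})

test_that("weekly correlations hit their degenerate and null cases", {
  panel <- dplyr::bind_rows(
    dplyr::mutate(random_gapped_panel(8, 28, 0.1, seed = 5), item = "a"),
    dplyr::mutate(random_gapped_panel(8, 28, 0.1, seed = 5), item = "b")
  )
  asg <- tibble::tibble(
    subject_id = paste0("s", 1:8), class = rep(1:2, each = 4)
  )
  same <- weekly_class_correlation(panel, "a", "b", asg)
  expect_true(all(abs(same$r - 1) < 1e-12))
  expect_equal(sort(unique(same$week)), 1:4)

  rev <- dplyr::mutate(panel,
    value = ifelse(item == "b", 100 - value, value)
  )
  opp <- weekly_class_correlation(rev, "a", "b", asg)
  expect_true(all(abs(opp$r + 1) < 1e-12))

  # independent streams stay near zero in a large class
  big <- dplyr::bind_rows(
    dplyr::mutate(random_gapped_panel(60, 28, 0, seed = 6), item = "a"),
    dplyr::mutate(random_gapped_panel(60, 28, 0, seed = 7), item = "b")
  )
  asg_big <- tibble::tibble(
    subject_id = paste0("s", 1:60), class = 1
  )
  null_r <- weekly_class_correlation(big, "a", "b", asg_big)
  expect_true(all(abs(null_r$r) < 0.1))
})

test_that("pooled weekly correlation equals a brute-force Pearson oracle", {
  panel <- dplyr::bind_rows(
    dplyr::mutate(random_gapped_panel(4, 14, 0.2, seed = 8), item = "a"),
    dplyr::mutate(random_gapped_panel(4, 14, 0.3, seed = 9), item = "b")
  )
  asg <- tibble::tibble(subject_id = paste0("s", 1:4), class = 1)
  got <- weekly_class_correlation(panel, "a", "b", asg)
  wide <- tidyr::pivot_wider(panel, names_from = item, values_from = value)
  wide <- wide[!is.na(wide$a) & !is.na(wide$b), ]
  for (w in unique(got$week)) {
    sub <- wide[wide$day %/% 7 + 1 == w, ]
    expect_equal(got$r[got$week == w], cor(sub$a, sub$b))
    expect_equal(got$n_pairs[got$week == w], nrow(sub))
  }
  # the averaged-per-subject variant stays in [-1, 1] and shares support
  by_subj <- weekly_class_correlation(panel, "a", "b", asg, by_subject = TRUE)
  expect_true(all(abs(by_subj$r) <= 1, na.rm = TRUE))
})

test_that("class mean trajectories: exactness, decomposition and CI scaling", {
  series <- tibble::tibble(
    subject_id = rep(paste0("s", 1:4), each = 10),
    item = "a", day = rep(0:9, 4),
    value = rep(c(30, 30, 50, 70), each = 10)
  )
  asg <- tibble::tibble(subject_id = paste0("s", 1:4), class = c(1, 1, 2, 2))
  tr <- class_mean_trajectories(series, asg, "a")
  expect_equal(tr$mean[tr$class == 1], rep(30, 10))
  expect_equal(tr$conf_high[tr$class == 1] - tr$conf_low[tr$class == 1],
    rep(0, 10)
  )
  # n-weighted mean of class means equals the pooled mean
  pooled <- tr |>
    dplyr::group_by(day) |>
    dplyr::summarise(m = sum(mean * n) / sum(n))
  expect_equal(pooled$m, rep(45, 10))

  # CI width scales like 1/sqrt(n)
  width_at <- function(n) {
    p <- random_gapped_panel(n, 20, 0, seed = 11)
    a <- tibble::tibble(subject_id = paste0("s", 1:n), class = 1)
    trn <- class_mean_trajectories(p, a, "a")
    mean(trn$conf_high - trn$conf_low)
  }
  ratio <- width_at(25) / width_at(100)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("falling distress under flat loudness raises the z trend", {
  # class 1: distress falls linearly; class 2: both flat
  days <- 0:59
  mk_subj <- function(id, cls) {
    withr::with_seed(id * 7 + cls, {
      loud <- 70 + rnorm(60, 0, 1)
      dis <- if (cls == 1) 60 - 0.5 * days + rnorm(60, 0, 1) else 40 + rnorm(60, 0, 1)
      dplyr::bind_rows(
        tibble::tibble(subject_id = paste0("s", id), item = "loud",
          day = days, value = clamp01(loud)
        ),
        tibble::tibble(subject_id = paste0("s", id), item = "dis",
          day = days, value = clamp01(dis)
        )
      )
    })
  }
  panel <- dplyr::bind_rows(lapply(1:20, function(i) {
    mk_subj(i, ifelse(i <= 10, 1, 2))
  }))
  asg <- tibble::tibble(
    subject_id = paste0("s", 1:20), class = rep(1:2, each = 10)
  )
  sdz <- standardized_difference(panel, "loud", "dis")
  summ <- standardized_difference_summary(sdz, asg)
  slope <- function(cls) {
    d <- summ[summ$class == cls, ]
    coef(lm(mean_z ~ day, data = d))[2]
  }
  expect_gt(slope(1), 0.02)
  expect_lt(abs(slope(2)), 0.01)
})
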