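test_that("Holm step-down matches hand-worked examples", {
  expect_equal(holm_adjust(0.04), 0.04)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  # the fifteen baseline p values of the motivating study all adjust to 1
  p15 <- c(
    0.730, 0.520, 0.090, 0.660, 0.900, 0.860, 0.940, 0.530,
    0.290, 0.570, 0.520, 0.510, 0.420, 0.390, 0.330
  )
  expect_equal(holm_adjust(p15), rep(1, 15))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm agrees with the reference implementation and its bounds", {
  withr::local_seed(1)
  for (rep in 1:20) {
    m <- sample(1:12, 1)
    p <- runif(m)
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, method = "holm"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(m * p, 1)))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("baseline contrasts: degenerate and hand-computable cases", {
  baseline <- tibble::tibble(
    subject_id = paste0("s", 1:8),
    cat = rep(c("x", "y"), 4),
    num = c(1, 2, 3, 4, 1, 2, 3, 4),
    flat = rep(5, 8)
  )
  asg <- tibble::tibble(subject_id = paste0("s", 1:8), class = rep(1:2, each = 4))
  res <- contrast_baseline(baseline, asg, variables = c("cat", "num", "flat"))

  # identical cell counts -> chi-square 0, p 1
  chi <- res[res$variable == "cat", ]
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_raw, 1)

  # identical class means and spreads -> F = 0
  f <- res[res$variable == "num", ]
  expect_equal(f$statistic, 0)
  expect_equal(f$p_raw, 1)

  # constant variable untestable and outside the Holm family
  flat <- res[res$variable == "flat", ]
  expect_equal(flat$note, "constant variable")
  expect_true(is.na(flat$p_adjusted))

  # two-group ANOVA equals the textbook F statistic
  b2 <- tibble::tibble(
    subject_id = paste0("s", 1:6),
    v = c(3, 5, 4, 8, 9, 10)
  )
  a2 <- tibble::tibble(subject_id = paste0("s", 1:6), class = rep(1:2, each = 3))
  r2 <- contrast_baseline(b2, a2, variables = "v")
  g1 <- c(3, 5, 4); g2 <- c(8, 9, 10)
  ssb <- 3 * (mean(g1) - mean(c(g1, g2)))^2 + 3 * (mean(g2) - mean(c(g1, g2)))^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(r2$statistic, (ssb / 1) / (ssw / 4))

  # 2x2 chi-square equals the Pearson formula
  b3 <- tibble::tibble(
    subject_id = paste0("s", 1:20),
    g = rep(c("a", "a", "a", "b"), 5)
  )
  a3 <- tibble::tibble(
    subject_id = paste0("s", 1:20),
    class = c(rep(1, 10), rep(2, 10))
  )
  b3$g[1:10] <- c(rep("a", 8), "b", "b")
  b3$g[11:20] <- c(rep("a", 5), rep("b", 5))
  r3 <- contrast_baseline(b3, a3, variables = "g")
  O <- table(b3$g, a3$class)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(r3$statistic, sum((O - E)^2 / E))
  expect_equal(r3$df, 1)

  expect_error(
    contrast_baseline(b2, dplyr::mutate(a2, subject_id = paste0("x", 1:6))),
    "shared"
  )
})

test_that("null-scenario contrasts keep their nominal size (quick check)", {
  withr::local_seed(7)
  rejections <- vapply(1:200, function(r) {
    n <- 60
    cls <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    bl <- tibble::tibble(subject_id = as.character(1:n), v = rnorm(n))
    asg <- tibble::tibble(subject_id = as.character(1:n), class = cls)
    contrast_baseline(bl, asg, variables = "v")$p_raw < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("PROM changes are flagged against their MCID thresholds", {
  n <- 40
  mk <- function(change, noise = 0) {
    cls <- rep(1:2, each = n / 2)
    withr::with_seed(3, {
      pre <- runif(n, 30, 70)
      tibble::tibble(
        subject_id = as.character(1:n),
        THI_pre = pre,
        THI_post = pre + change[cls] + rnorm(n, 0, noise),
        TFI_pre = pre, TFI_post = pre + change[cls],
        PHQ9_pre = pre / 4, PHQ9_post = pre / 4
      )
    })
  }
  asg <- tibble::tibble(
    subject_id = as.character(1:n), class = rep(1:2, each = n / 2)
  )
  res <- prom_change_by_class(mk(c(-12, -9), noise = 0.5), asg)

  thi <- res[res$instrument == "THI", ]
  expect_true(thi$clinically_relevant[thi$class == 1]) # -12 vs MCID 11
  expect_false(thi$clinically_relevant[thi$class == 2]) # -9 vs MCID 11
  tfi <- res[res$instrument == "TFI", ]
  expect_true(tfi$clinically_relevant[tfi$class == 2]) # boundary -9 = MCID 9
  expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))

  # zero change: t statistic 0, nothing clinically relevant
  phq <- res[res$instrument == "PHQ9", ]
  expect_equal(phq$statistic, c(0, 0))
  expect_false(any(phq$clinically_relevant))

  # a class with fewer than 2 paired observations is reported untestable
  small <- mk(c(-12, -9), noise = 0.5)
  small$THI_post[small$subject_id %in% as.character(2:(n / 2))] <- NA
  res_small <- prom_change_by_class(small, asg)
  row <- res_small[res_small$instrument == "THI" & res_small$class == 1, ]
  expect_match(row$note, "fewer than 2")
  expect_true(is.na(row$p_raw))
})

test_that("class-by-arm table counts without testing", {
  arms <- tibble::tibble(
    subject_id = as.character(1:6),
    arm = c("CBT", "CBT", "HA", "HA", "ST", "ST")
  )
  asg <- tibble::tibble(subject_id = as.character(1:6), class = c(1, 2, 1, 2, 1, 2))
  tab <- class_by_arm_table(arms, asg)
  expect_equal(sum(tab$n), 6)
  expect_equal(nrow(tab), 6)
})
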