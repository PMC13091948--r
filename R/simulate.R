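#' Tabulate class mean trajectories
#'
#' Interpolates each class's anchor points over the full day grid with a
#' shape-preserving monotone cubic (Fritsch--Carlson), so the mean passes
#' exactly through the anchors and never overshoots the 0--100 scale between
#' them.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `class`, `day`, `mean`.
#' @export
class_mean_curves <- function(config) {
  days <- 0:(config$n_days - 1)
  purrr::map_dfr(seq_along(config$class_anchor_curves), function(g) {
    ac <- config$class_anchor_curves[[g]]
    f <- if (nrow(ac) >= 2) {
      splinefun(ac$day, ac$value, method = "monoH.FC")
    } else {
      function(d) rep(ac$value, length(d))
    }
    tibble::tibble(class = g, day = days, mean = f(days))
  })
}

#' Simulate a latent-class EMA panel
#'
#' Draws, per subject, a latent class from the mixing proportions and a
#' Gaussian random intercept; the daily primary outcome is the class mean
#' plus the intercept plus Gaussian residual noise, clamped to the 0--100
#' scale.  Secondary items are linear functions of the primary outcome plus
#' noise.  Missingness is then applied at the subject-day level.  All draws
#' are governed by `config$seed`, so identical configurations yield
#' identical panels.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `ema_sim`: a list with
#'   \describe{
#'     \item{panel}{long tibble `subject_id, day, item, value`; missing
#'       subject-days are absent rows}
#'     \item{truth}{tibble `subject_id, class_label, subject_intercept, age`}
#'     \item{class_means}{output of [class_mean_curves()]}
#'     \item{config}{the configuration used}
#'   }
#' @export
#' @examples
#' sim <- simulate_ema(default_study_config(seed = 42))
#' dplyr::count(sim$truth, class_label)
simulate_ema <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    G <- length(config$class_proportions)
    n <- config$n_subjects
    days <- 0:(config$n_days - 1)
    means <- class_mean_curves(config)
    mean_mat <- matrix(means$mean, nrow = config$n_days)  # day x class

    labels <- sample.int(G, n, replace = TRUE, prob = config$class_proportions)
    intercepts <- rnorm(n, 0, config$sigma_b)
    ages <- round(clamp01(rnorm(n, 54.7, 11.9), 18, 80))
    ids <- sprintf("S%03d", seq_len(n))

    truth <- tibble::tibble(
      subject_id = ids,
      class_label = labels,
      subject_intercept = intercepts,
      age = ages
    )

    y <- as.vector(mean_mat[, labels]) +
      rep(intercepts, each = config$n_days) +
      rnorm(n * config$n_days, 0, config$sigma_eps)
    y <- clamp01(y)

    panel <- tibble::tibble(
      subject_id = rep(ids, each = config$n_days),
      day = rep(days, times = n),
      item = config$outcome_item,
      value = y
    )

    secondary <- purrr::imap_dfr(config$secondary_item_params, function(p, nm) {
      v <- clamp01(p$offset + p$slope * y + rnorm(length(y), 0, p$sd))
      tibble::tibble(
        subject_id = panel$subject_id,
        day = panel$day,
        item = nm,
        value = v
      )
    })
    panel <- dplyr::bind_rows(panel, secondary)

    panel <- apply_missingness(panel, config, covariate = truth)

    structure(
      list(panel = panel, truth = truth, class_means = means, config = config),
      class = "ema_sim"
    )
  })
}

#' @export
print.ema_sim <- function(x, ...) {
  cat(sprintf(
    "<ema_sim> %d subjects, %d observed rows (%d items), %d classes\n",
    nrow(x$truth), nrow(x$panel), dplyr::n_distinct(x$panel$item),
    length(x$config$class_proportions)
  ))
  invisible(x)
}

#' Remove subject-days from a complete panel
#'
#' Deletes whole subject-days (all items of that day) until the target raw
#' missing fraction is met.  Under MCAR, deleted subject-days are uniform;
#' under MAR-age the per-subject deletion probability increases with age, so
#' older subjects accumulate more missing days while observed values are
#' untouched.
#'
#' @param panel Long EMA tibble (`subject_id, day, item, value`).
#' @param config A [sim_config()]; `missing_raw_fraction` and
#'   `missingness_mode` are used.
#' @param covariate Tibble with `subject_id` and `age`; required for MAR-age.
#' @param seed Optional seed; by default the surrounding RNG state is used
#'   (as inside [simulate_ema()]).
#' @return The panel with removed subject-days absent.
#' @export
apply_missingness <- function(panel, config, covariate = NULL, seed = NULL) {
  frac <- config$missing_raw_fraction
  if (frac >= 1) abort("Missing fraction must be < 1.")
  if (frac <= 0) return(panel)
  run <- function() {
    cells <- dplyr::distinct(panel, .data$subject_id, .data$day)
    n_remove <- round(frac * nrow(cells))
    if (n_remove == 0) return(panel)
    if (config$missingness_mode == "MCAR") {
      drop_idx <- sample.int(nrow(cells), n_remove)
    } else {
      if (is.null(covariate)) abort("MAR-age missingness needs an age covariate.")
      w <- covariate$age[match(cells$subject_id, covariate$subject_id)]
      if (anyNA(w)) abort("Every subject needs an age for MAR-age missingness.")
      w <- exp(0.06 * (w - mean(w)))
      drop_idx <- sample.int(nrow(cells), n_remove, prob = w)
    }
    dropped <- cells[drop_idx, ]
    dplyr::anti_join(panel, dropped, by = c("subject_id", "day"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# default class-specific pre-to-post changes of the retrospective
# questionnaires (negative = improvement), one value per class of the
# four-class default configuration
default_prom_changes <- function() {
  list(
    THI = c(-12, -8, -16, -14),
    TFI = c(-6, -10, -13, -12),
    PHQ9 = c(-1, -2.5, -3.5, -3)
  )
}

#' Simulate a baseline / outcome table for simulated subjects
#'
#' Draws demographic, clinical and personality covariates in their published
#' ranges.  By default covariates are independent of the latent class (the
#' null scenario mirroring the finding that baseline variables do not
#' predict class membership); `class_effects` adds class-linked mean shifts
#' for power studies.  Post-treatment questionnaire scores are the baseline
#' score plus a class-specific change plus noise.
#'
#' @param truth `truth` tibble from [simulate_ema()] (uses `class_label` and
#'   `age`).
#' @param config The [sim_config()] used for the panel (supplies the seed).
#' @param class_effects Optional named list `variable -> numeric vector of
#'   per-class mean shifts` (variables: `age`, `THI_pre`, `TFI_pre`,
#'   `PHQ9_pre`, `THI_change`, `TFI_change`, `PHQ9_change`).
#' @param prom_changes Named list of per-class mean changes for `THI`, `TFI`,
#'   `PHQ9`.
#' @param seed Seed; defaults to a sub-seed derived from `config$seed`.
#'
#' @return Tibble with one row per subject: gender, education, age,
#'   `THI_pre/post`, `TFI_pre/post`, `PHQ9_pre/post`, hearing loss (PTA4),
#'   tinnitus duration, five personality scores, number of comorbidities and
#'   prior treatments.
#' @export
simulate_baseline <- function(truth, config,
                              class_effects = NULL,
                              prom_changes = default_prom_changes(),
                              seed = derive_seed(config$seed, 7L)) {
  n <- nrow(truth)
  G <- length(config$class_proportions)
  cls <- truth$class_label
  shift <- function(var) {
    if (!is.null(class_effects[[var]])) class_effects[[var]][cls] else 0
  }
  per_class <- function(v) {
    v <- rep_len(v, G)
    v[cls]
  }
  withr::with_seed(seed, {
    thi_pre <- clamp01(rnorm(n, 49.2, 20.3) + shift("THI_pre"), 0, 100)
    tfi_pre <- clamp01(rnorm(n, 51.3, 21.2) + shift("TFI_pre"), 0, 100)
    phq_pre <- clamp01(rnorm(n, 7.6, 4.9) + shift("PHQ9_pre"), 0, 27)
    tibble::tibble(
      subject_id = truth$subject_id,
      gender = factor(
        sample(c("female", "male"), n, TRUE, prob = c(0.449, 0.551))
      ),
      education = factor(
        sample(c("elementary", "high_school", "middle_school", "university"),
          n, TRUE,
          prob = c(0.109, 0.156, 0.299, 0.436)
        )
      ),
      age = clamp01(truth$age + shift("age"), 18, 80),
      THI_pre = thi_pre,
      THI_post = clamp01(
        thi_pre + per_class(prom_changes$THI) + shift("THI_change") +
          rnorm(n, 0, 10), 0, 100
      ),
      TFI_pre = tfi_pre,
      TFI_post = clamp01(
        tfi_pre + per_class(prom_changes$TFI) + shift("TFI_change") +
          rnorm(n, 0, 10), 0, 100
      ),
      PHQ9_pre = phq_pre,
      PHQ9_post = clamp01(
        phq_pre + per_class(prom_changes$PHQ9) + shift("PHQ9_change") +
          rnorm(n, 0, 3), 0, 27
      ),
      hearing_loss_pta4 = clamp01(rnorm(n, 20.6, 16.6), 0, 100),
      tinnitus_duration = rlnorm(n, meanlog = 4.60, sdlog = 0.79),
      extraversion = clamp01(rnorm(n, 39.3, 6.8), 12, 60),
      agreeableness = clamp01(rnorm(n, 47.2, 6.2), 12, 60),
      conscientiousness = clamp01(rnorm(n, 46.9, 8.1), 12, 60),
      neuroticism = clamp01(rnorm(n, 34.2, 8.3), 12, 60),
      openness = clamp01(rnorm(n, 43.7, 7.5), 12, 60),
      n_comorbidities = rpois(n, 2.28),
      n_prior_treatments = rpois(n, 0.32)
    )
  })
}

#' Write an EMA panel to CSV
#'
#' Long format with header `subject_id,day,item,value`; missing subject-days
#' are simply absent rows.
#'
#' @param panel Long EMA tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ema_long <- function(panel, path) {
  readr::write_csv(panel[, c("subject_id", "day", "item", "value")], path)
  invisible(path)
}
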