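#' Holm step-down adjustment of p values
#'
#' Sorts the raw p values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity with a running maximum, caps at 1 and
#' restores the input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1].")
  m <- length(p)
  ord <- order(p)
  mult <- (m - seq_len(m) + 1) * p[ord]
  adj <- pmin(cummax(mult), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Baseline contrasts across latent classes
#'
#' Tests whether baseline variables differ between the latent classes:
#' chi-square tests of independence for categorical variables (one test per
#' variable, however many levels) and one-way ANOVA (classical F) for
#' continuous variables, with a single Holm family over all testable
#' variables.  Constant or single-level variables are reported as
#' untestable and excluded from the Holm family.
#'
#' @param baseline Tibble with one row per subject including `subject_id`.
#' @param assignments Tibble `subject_id, class` (e.g. from
#'   [augment.lcgmm_fit()] renaming `.class`), or a named vector.
#' @param variables Variables to test; defaults to every column except
#'   `subject_id` and post-treatment scores (`*_post`).
#' @return Tibble with `variable`, `test`, `statistic`, `df`, `p_raw`,
#'   `p_adjusted`, `note`.
#' @export
contrast_baseline <- function(baseline, assignments, variables = NULL) {
  asg <- normalize_assignments(assignments)
  df <- dplyr::inner_join(baseline, asg, by = "subject_id")
  if (!nrow(df)) abort("No subjects shared between baseline table and assignments.")
  counts <- table(df$class)
  if (any(counts == 0)) abort("Every class must contain at least one subject.")
  if (length(counts) < 2) abort("Contrasts need at least 2 classes.")
  variables <- variables %||% setdiff(
    names(baseline),
    c("subject_id", grep("_post$", names(baseline), value = TRUE))
  )
  res <- purrr::map_dfr(variables, function(v) {
    x <- df[[v]]
    cls <- factor(df$class)
    if (is.numeric(x)) {
      if (sd(x) == 0) {
        return(tibble::tibble(
          variable = v, test = "anova", statistic = NA_real_,
          df = NA_real_, p_raw = NA_real_, note = "constant variable"
        ))
      }
      fit <- aov(x ~ cls)
      s <- summary(fit)[[1]]
      tibble::tibble(
        variable = v, test = "anova", statistic = s[["F value"]][1],
        df = s[["Df"]][1], p_raw = s[["Pr(>F)"]][1], note = NA_character_
      )
    } else {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2) {
        return(tibble::tibble(
          variable = v, test = "chi-square", statistic = NA_real_,
          df = NA_real_, p_raw = NA_real_, note = "single observed level"
        ))
      }
      tst <- suppressWarnings(chisq.test(table(x, cls), correct = FALSE))
      tibble::tibble(
        variable = v, test = "chi-square",
        statistic = unname(tst$statistic), df = unname(tst$parameter),
        p_raw = tst$p.value, note = NA_character_
      )
    }
  })
  testable <- !is.na(res$p_raw)
  res$p_adjusted <- NA_real_
  res$p_adjusted[testable] <- holm_adjust(res$p_raw[testable])
  res
}

#' Pre--post questionnaire changes per class against MCID thresholds
#'
#' For each latent class and instrument, computes the mean change from
#' baseline to the post-treatment visit, a paired t-test against zero
#' change (Holm-adjusted within the instrument's family of classes), and
#' whether the mean improvement reaches the instrument's minimal clinically
#' important difference (MCID); a mean improvement exactly at the threshold
#' counts as relevant.
#'
#' @param baseline Tibble with `subject_id` and `<instrument>_pre` /
#'   `<instrument>_post` columns.
#' @param assignments Tibble `subject_id, class` or named vector.
#' @param mcid Named vector of MCID thresholds
#'   (default `c(THI = 11, TFI = 9, PHQ9 = 6)`).
#' @param boundary_relevant Whether a mean improvement equal to the MCID
#'   counts as clinically relevant (default `TRUE`).
#' @return Tibble with `class`, `instrument`, `n`, `n_missing`,
#'   `mean_change`, `statistic`, `p_raw`, `p_adjusted`,
#'   `mcid_threshold`, `clinically_relevant`, `note`.
#' @export
prom_change_by_class <- function(baseline, assignments,
                                 mcid = c(THI = 11, TFI = 9, PHQ9 = 6),
                                 boundary_relevant = TRUE) {
  asg <- normalize_assignments(assignments)
  df <- dplyr::inner_join(baseline, asg, by = "subject_id")
  classes <- sort(unique(df$class))
  res <- purrr::map_dfr(names(mcid), function(inst) {
    pre <- df[[paste0(inst, "_pre")]]
    post <- df[[paste0(inst, "_post")]]
    if (is.null(pre) || is.null(post)) {
      abort(sprintf("Columns %s_pre/%s_post not found.", inst, inst))
    }
    purrr::map_dfr(classes, function(g) {
      in_class <- df$class == g
      change <- (post - pre)[in_class]
      n_missing <- sum(is.na(change))
      change <- change[!is.na(change)]
      if (length(change) < 2 || sd(change) == 0) {
        deg <- length(change) >= 2 # constant changes: t undefined unless 0
        stat <- if (deg && all(change == 0)) 0 else NA_real_
        p <- if (!is.na(stat)) 1 else NA_real_
        note <- if (deg) "constant change" else "fewer than 2 paired observations"
      } else {
        tt <- t.test(change)
        stat <- unname(tt$statistic)
        p <- tt$p.value
        note <- NA_character_
      }
      mean_change <- if (length(change)) mean(change) else NA_real_
      improvement <- -mean_change
      relevant <- if (boundary_relevant) {
        isTRUE(improvement >= mcid[[inst]])
      } else {
        isTRUE(improvement > mcid[[inst]])
      }
      tibble::tibble(
        class = g, instrument = inst, n = length(change),
        n_missing = n_missing, mean_change = mean_change,
        statistic = stat, p_raw = p,
        mcid_threshold = mcid[[inst]],
        clinically_relevant = relevant, note = note
      )
    })
  })
  # Holm family: the classes of one instrument
  res <- res |>
    dplyr::group_by(.data$instrument) |>
    dplyr::group_modify(function(d, key) {
      ok <- !is.na(d$p_raw)
      d$p_adjusted <- NA_real_
      d$p_adjusted[ok] <- holm_adjust(d$p_raw[ok])
      d
    }) |>
    dplyr::ungroup()
  dplyr::relocate(res, "p_adjusted", .after = "p_raw")
}

#' Class by treatment-arm contingency table
#'
#' Exported as counts only; cell sizes in a ten-arm design do not support
#' formal testing.
#'
#' @param arms Tibble `subject_id, arm`.
#' @param assignments Tibble `subject_id, class` or named vector.
#' @return Tibble of counts `class, arm, n`.
#' @export
class_by_arm_table <- function(arms, assignments) {
  asg <- normalize_assignments(assignments)
  dplyr::inner_join(arms, asg, by = "subject_id") |>
    dplyr::count(.data$class, .data$arm)
}

# accept tibble (subject_id, class / .class) or named vector
normalize_assignments <- function(assignments) {
  if (is.data.frame(assignments)) {
    nm <- names(assignments)
    cls_col <- if ("class" %in% nm) "class" else if (".class" %in% nm) ".class" else NULL
    if (is.null(cls_col) || !"subject_id" %in% nm) {
      abort("Assignments need columns `subject_id` and `class`.")
    }
    tibble::tibble(
      subject_id = assignments$subject_id,
      class = as.integer(assignments[[cls_col]])
    )
  } else {
    if (is.null(names(assignments))) abort("Assignment vectors must be named by subject id.")
    tibble::tibble(
      subject_id = names(assignments),
      class = as.integer(assignments)
    )
  }
}
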