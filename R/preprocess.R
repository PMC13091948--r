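#' Read a long-format EMA panel from CSV
#'
#' Expects the header `subject_id,day,item,value`; missing subject-days are
#' absent rows.  The panel is validated: duplicate `(subject, day, item)`
#' keys and values outside the 0--100 scale are rejected with the offending
#' rows named.
#'
#' @param path CSV file path.
#' @param n_days Optional number of study days; if given, days outside
#'   `0 .. n_days - 1` are rejected.
#' @return A validated tibble `subject_id, day, item, value`.
#' @export
read_ema_long <- function(path, n_days = NULL) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  validate_ema_panel(panel, n_days = n_days)
}

#' Validate a long-format EMA panel
#'
#' @param panel Tibble with columns `subject_id, day, item, value`.
#' @inheritParams read_ema_long
#' @return The panel, with canonical column types.
#' @export
validate_ema_panel <- function(panel, n_days = NULL) {
  need <- c("subject_id", "day", "item", "value")
  if (!all(need %in% names(panel))) {
    abort(paste0(
      "Malformed panel: expected columns ",
      paste(need, collapse = ", "), "."
    ))
  }
  panel <- tibble::as_tibble(panel)[, need]
  if (!is.numeric(panel$value)) abort("`value` must be numeric.")
  if (!is.numeric(panel$day)) abort("`day` must be numeric.")
  bad <- which(is.na(panel$value) | panel$value < 0 | panel$value > 100)
  if (length(bad)) {
    abort(sprintf(
      "Values outside [0, 100] (or NA) at rows: %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (!is.null(n_days)) {
    badday <- which(panel$day < 0 | panel$day > n_days - 1)
    if (length(badday)) {
      abort(sprintf(
        "Days outside 0..%d at rows: %s", n_days - 1,
        paste(head(badday, 5), collapse = ", ")
      ))
    }
  }
  key <- paste(panel$subject_id, panel$day, panel$item, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- panel[which(dup)[1], ]
    abort(sprintf(
      "Duplicate record for (subject %s, day %s, item %s).",
      first$subject_id, first$day, first$item
    ))
  }
  panel$day <- as.integer(panel$day)
  panel
}

#' Compliance threshold in number of observations
#'
#' Converts a compliance fraction into the minimum number of observed days,
#' rounding down: 50% of 84 days gives 42 observations and 10% gives 8.
#'
#' @param fraction Required compliance in `(0, 1]`.
#' @param days_total Number of scheduled days.
#' @return Integer threshold.
#' @export
#' @examples
#' min_observations(0.5, 84) # 42
#' min_observations(0.1, 84) # 8
min_observations <- function(fraction, days_total) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  as.integer(floor(fraction * days_total))
}

#' Filter subjects by EMA compliance
#'
#' Retains subjects with at least [min_observations()] non-missing records
#' of the given item; the ids of excluded subjects are returned for
#' reporting.
#'
#' @param panel Long EMA tibble.
#' @param item Item whose compliance is assessed.
#' @param fraction Compliance fraction in `(0, 1]`.
#' @param days_total Number of scheduled days.
#' @return List with `panel` (all items of retained subjects), `excluded`
#'   (character vector of dropped subject ids) and `threshold`.
#' @export
compliance_filter <- function(panel, item, fraction, days_total) {
  if (!item %in% panel$item) abort(sprintf("Unknown item '%s'.", item))
  thr <- min_observations(fraction, days_total)
  counts <- panel |>
    dplyr::filter(.data$item == !!item) |>
    dplyr::count(.data$subject_id)
  all_ids <- unique(panel$subject_id)
  keep <- counts$subject_id[counts$n >= thr]
  excluded <- setdiff(all_ids, keep)
  list(
    panel = dplyr::filter(panel, .data$subject_id %in% keep),
    excluded = excluded,
    threshold = thr
  )
}

# centred moving average of one gapped series on a full day grid;
# values: numeric vector with NA at unobserved days
roll_mean_centred <- function(values, window) {
  obs <- !is.na(values)
  v0 <- ifelse(obs, values, 0)
  half <- (window - 1L) %/% 2L
  n_raw <- as.numeric(zoo::rollapply(as.numeric(obs), window, sum,
    partial = TRUE, align = "center"
  ))
  total <- zoo::rollapply(v0, window, sum, partial = TRUE, align = "center")
  out <- ifelse(n_raw > 0, total / n_raw, NA_real_)
  list(value = out, n_raw = as.integer(n_raw))
}

#' Seven-day moving average of EMA series
#'
#' Smooths each subject-item series with a centred moving average over an
#' odd window (default seven days: days `t-3 .. t+3`, truncated at the study
#' edges).  The smoothed value at a day is the mean of the raw values
#' available in the window and is undefined (`NA`) only where the window
#' contains no observation, which is how the procedure fills most raw
#' missingness.
#'
#' @param panel Long EMA tibble.
#' @param n_days Number of study days; the output covers the full grid
#'   `0 .. n_days - 1`.
#' @param window Odd window width, default 7.
#' @param items Items to smooth; default all items present.
#' @return Tibble `subject_id, item, day, value, n_raw` over the full grid,
#'   with `NA` value where undefined.
#' @export
moving_average <- function(panel, n_days, window = 7L, items = NULL) {
  if (window %% 2L == 0L || window < 1L) {
    abort("`window` must be an odd positive integer.")
  }
  items <- items %||% unique(panel$item)
  grid <- tidyr::expand_grid(
    subject_id = unique(panel$subject_id),
    item = items,
    day = 0:(n_days - 1)
  )
  full <- grid |>
    dplyr::left_join(
      dplyr::filter(panel, .data$item %in% items),
      by = c("subject_id", "item", "day")
    ) |>
    dplyr::arrange(.data$subject_id, .data$item, .data$day)
  full |>
    dplyr::group_by(.data$subject_id, .data$item) |>
    dplyr::group_modify(function(df, key) {
      sm <- roll_mean_centred(df$value, window)
      tibble::tibble(day = df$day, value = sm$value, n_raw = sm$n_raw)
    }) |>
    dplyr::ungroup()
}

#' Flag outlying subjects from smoothed series
#'
#' Replaces the unreproducible "visual inspection" step with a deterministic
#' robust rule: a subject is flagged when the median of its smoothed series
#' lies more than `k` median-absolute-deviations (scaled, as in
#' [stats::mad()]) from the cohort median of those per-subject medians.
#' Flagged subjects are reported, not removed.
#'
#' @param smoothed Output of [moving_average()].
#' @param item Item to screen; default the first item present.
#' @param k Number of robust deviations, default 4.
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
flag_outlier_subjects <- function(smoothed, item = NULL, k = 4) {
  item <- item %||% smoothed$item[1]
  med <- smoothed |>
    dplyr::filter(.data$item == !!item, !is.na(.data$value)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(m = median(.data$value), .groups = "drop")
  if (nrow(med) < 3) abort("Outlier screening needs at least 3 subjects.")
  centre <- median(med$m)
  scale <- mad(med$m)
  if (scale == 0) return(character())
  med$subject_id[abs(med$m - centre) > k * scale]
}

#' Missingness before and after smoothing
#'
#' Fraction of undefined subject-day-item cells among
#' `subjects x days_total x items`, in the raw panel and after the
#' moving-average procedure.  Smoothing can only fill gaps, so the smoothed
#' fraction never exceeds the raw fraction.
#'
#' @param panel Raw long EMA tibble (missing = absent row).
#' @param smoothed Output of [moving_average()] on the same panel.
#' @param days_total Number of scheduled days.
#' @return List with `raw_fraction`, `smoothed_fraction`, `n_subjects`.
#' @export
missingness_report <- function(panel, smoothed, days_total) {
  subjects <- unique(smoothed$subject_id)
  items <- unique(smoothed$item)
  denom <- length(subjects) * days_total * length(items)
  raw_n <- panel |>
    dplyr::filter(
      .data$subject_id %in% subjects, .data$item %in% items,
      .data$day >= 0, .data$day <= days_total - 1
    ) |>
    nrow()
  smooth_missing <- sum(is.na(smoothed$value))
  list(
    raw_fraction = 1 - raw_n / denom,
    smoothed_fraction = smooth_missing / denom,
    n_subjects = length(subjects)
  )
}
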