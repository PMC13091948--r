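#' Reverse-code a 0--100 scale item
#'
#' Maps `value` to `scale_max - value` so that higher scores always mean
#' more burden (as done for the emotion item).
#'
#' @param x Numeric vector in `[0, scale_max]`.
#' @param scale_max Scale maximum, default 100.
#' @return Reversed values.
#' @export
#' @examples
#' reverse_code(c(0, 50, 100))
reverse_code <- function(x, scale_max = 100) {
  if (any(x < 0 | x > scale_max, na.rm = TRUE)) {
    abort(sprintf("Values must lie in [0, %s].", scale_max))
  }
  scale_max - x
}

#' Intra-individually standardized loudness--distress difference
#'
#' Computes, per subject and day, the raw difference
#' `d = loudness - distress` where both (smoothed) series are defined, and
#' standardizes it within subject: `z = (d - mean(d)) / sd(d)` with the
#' sample (n-1) standard deviation.  A value of 0 is the subject's average
#' difference; rising `z` over time means distress decouples from loudness
#' (the desired treatment effect).  Subjects with a constant difference
#' have undefined `z` and are reported via the `excluded` attribute.
#'
#' @param smoothed Output of [moving_average()] (or any tibble
#'   `subject_id, item, day, value`).
#' @param loudness_item,distress_item Item names.
#' @return Tibble `subject_id, day, d, z` (rows where both items defined);
#'   `attr(, "excluded")` holds ids with undefined `z`.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   subject_id = "s1", item = rep(c("a", "b"), each = 3),
#'   day = rep(0:2, 2), value = c(11, 22, 33, 10, 20, 30)
#' )
#' standardized_difference(df, "a", "b")$z
standardized_difference <- function(smoothed,
                                    loudness_item = "maximum_tinnitus_loudness",
                                    distress_item = "daily_tinnitus_distress") {
  for (it in c(loudness_item, distress_item)) {
    if (!it %in% smoothed$item) abort(sprintf("Unknown item '%s'.", it))
  }
  wide <- smoothed |>
    dplyr::filter(.data$item %in% c(loudness_item, distress_item)) |>
    dplyr::select("subject_id", "day", "item", "value") |>
    tidyr::pivot_wider(names_from = "item", values_from = "value") |>
    dplyr::filter(
      !is.na(.data[[loudness_item]]), !is.na(.data[[distress_item]])
    ) |>
    dplyr::mutate(d = .data[[loudness_item]] - .data[[distress_item]])
  out <- wide |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      z = if (dplyr::n() >= 2 && sd(.data$d) > 0) {
        (.data$d - mean(.data$d)) / sd(.data$d)
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "day", "d", "z")
  excluded <- unique(out$subject_id[is.na(out$z)])
  out <- dplyr::filter(out, !(.data$subject_id %in% excluded))
  attr(out, "excluded") <- excluded
  out
}

#' Class-level daily summary of the standardized difference
#'
#' Mean of the intra-individual `z` per class and day (subjects with
#' undefined `z` excluded), plus a local-polynomial smoothed trend.
#'
#' @param sdiff Output of [standardized_difference()].
#' @param assignments Tibble `subject_id, class` or named vector.
#' @param span Loess span for the trend, default 0.75.
#' @return Tibble `class, day, mean_z, n, trend`.
#' @export
standardized_difference_summary <- function(sdiff, assignments, span = 0.75) {
  asg <- normalize_assignments(assignments)
  daily <- sdiff |>
    dplyr::filter(!is.na(.data$z)) |>
    dplyr::inner_join(asg, by = "subject_id") |>
    dplyr::group_by(.data$class, .data$day) |>
    dplyr::summarise(mean_z = mean(.data$z), n = dplyr::n(), .groups = "drop")
  daily |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      d$trend <- if (nrow(d) >= 10) {
        as.vector(predict(loess(mean_z ~ day, data = d, span = span)))
      } else {
        d$mean_z
      }
      d
    }) |>
    dplyr::ungroup()
}

#' Weekly within-class correlation between two symptom streams
#'
#' Partitions the study days into weeks (days 0--6 are week 1, and so on)
#' and computes, per class and week, the Pearson correlation over all
#' (subject, day) pairs where both items are defined.  With
#' `by_subject = TRUE` the correlation is instead computed per subject and
#' averaged within the class-week.  `r` is absent when fewer than 3 pairs
#' are available or either stream is constant.
#'
#' @param panel Long tibble `subject_id, item, day, value` (smoothed values
#'   by default in the pipeline; raw values work equally).
#' @param item_a,item_b Item names.
#' @param assignments Tibble `subject_id, class` or named vector.
#' @param by_subject Average per-subject correlations instead of pooling.
#' @return Tibble `class, week, r, n_pairs`.
#' @export
weekly_class_correlation <- function(panel, item_a, item_b, assignments,
                                     by_subject = FALSE) {
  for (it in c(item_a, item_b)) {
    if (!it %in% panel$item) abort(sprintf("Unknown item '%s'.", it))
  }
  asg <- normalize_assignments(assignments)
  wide <- panel |>
    dplyr::filter(.data$item %in% c(item_a, item_b)) |>
    dplyr::select("subject_id", "day", "item", "value") |>
    tidyr::pivot_wider(names_from = "item", values_from = "value") |>
    dplyr::filter(!is.na(.data[[item_a]]), !is.na(.data[[item_b]])) |>
    dplyr::inner_join(asg, by = "subject_id") |>
    dplyr::mutate(week = .data$day %/% 7L + 1L)
  safe_cor <- function(a, b) {
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  if (!by_subject) {
    wide |>
      dplyr::group_by(.data$class, .data$week) |>
      dplyr::summarise(
        r = safe_cor(.data[[item_a]], .data[[item_b]]),
        n_pairs = dplyr::n(), .groups = "drop"
      )
  } else {
    wide |>
      dplyr::group_by(.data$class, .data$week, .data$subject_id) |>
      dplyr::summarise(
        r_i = safe_cor(.data[[item_a]], .data[[item_b]]),
        n_i = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::group_by(.data$class, .data$week) |>
      dplyr::summarise(
        r = mean(.data$r_i, na.rm = TRUE),
        n_pairs = sum(.data$n_i), .groups = "drop"
      )
  }
}

#' Per-class daily mean trajectories of an item
#'
#' Mean of the (smoothed) item per class and day over subjects with a
#' defined value, with the pointwise normal 95% confidence interval
#' `mean +/- 1.96 sd/sqrt(n)`.  Empty class-days are absent.
#'
#' @param panel Long tibble `subject_id, item, day, value` (typically
#'   smoothed).
#' @param assignments Tibble `subject_id, class` or named vector.
#' @param item Item name.
#' @param level Confidence level, default 0.95.
#' @return Tibble `class, day, mean, sd, n, conf_low, conf_high`.
#' @export
class_mean_trajectories <- function(panel, assignments, item, level = 0.95) {
  if (!item %in% panel$item) abort(sprintf("Unknown item '%s'.", item))
  asg <- normalize_assignments(assignments)
  z <- qnorm(1 - (1 - level) / 2)
  panel |>
    dplyr::filter(.data$item == !!item, !is.na(.data$value)) |>
    dplyr::inner_join(asg, by = "subject_id") |>
    dplyr::group_by(.data$class, .data$day) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sd = ifelse(is.na(.data$sd), 0, .data$sd),
      conf_low = .data$mean - z * .data$sd / sqrt(.data$n),
      conf_high = .data$mean + z * .data$sd / sqrt(.data$n)
    )
}

#' Plot class mean trajectories of one or more items
#'
#' @param panel Long (smoothed) tibble.
#' @param assignments Tibble `subject_id, class` or named vector.
#' @param items Items to plot.
#' @return A ggplot, one facet per item, coloured by class.
#' @export
plot_class_trajectories <- function(panel, assignments, items) {
  traj <- purrr::map_dfr(items, function(it) {
    dplyr::mutate(class_mean_trajectories(panel, assignments, it), item = it)
  }) |>
    dplyr::mutate(class = factor(.data$class))
  ggplot2::ggplot(traj, ggplot2::aes(
    .data$day, .data$mean,
    colour = .data$class, fill = .data$class
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$item) +
    ggplot2::labs(x = "Study day", y = "Mean (VAS 0-100)") +
    ggplot2::theme_minimal()
}
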