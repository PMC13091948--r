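#' Configuration of an end-to-end trajectory analysis run
#'
#' @param simulate A [sim_config()] describing the panel to generate, or
#'   `NULL` when `input_panel` is given.
#' @param input_panel,input_baseline Optional CSV paths for an existing
#'   panel / baseline table (used when `simulate` is `NULL`).
#' @param outcome_item Primary outcome item
#'   (default `"tinnitus_related_thoughts"`).
#' @param compliance_fraction Compliance threshold in `(0, 1]`
#'   (default 0.5; the sensitivity analysis uses 0.1).
#' @param window Moving-average window (odd, default 7).
#' @param G_range Class counts to enumerate (default `1:10`).
#' @param df Spline degrees of freedom (default 3).
#' @param n_starts,burn_iters,retry_starts Multi-start settings
#'   (defaults 30, 30, 50).
#' @param selection List of [select_model()] rule parameters.
#' @param mcid Named MCID thresholds.
#' @param outlier_k Robust-deviation multiplier for outlier flagging.
#' @param output_dir Optional directory for artifacts (CSV/JSON); nothing
#'   is written when `NULL`.
#' @param seed Integer seed for every stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = default_study_config(),
                       input_panel = NULL, input_baseline = NULL,
                       outcome_item = "tinnitus_related_thoughts",
                       compliance_fraction = 0.5,
                       window = 7L,
                       G_range = 1:10,
                       df = 3L,
                       n_starts = 30L, burn_iters = 30L, retry_starts = 50L,
                       selection = list(),
                       mcid = c(THI = 11, TFI = 9, PHQ9 = 6),
                       outlier_k = 4,
                       output_dir = NULL,
                       seed = 1L) {
  if (compliance_fraction <= 0 || compliance_fraction > 1) {
    abort("`compliance_fraction` must be in (0, 1].")
  }
  if (is.null(simulate) && is.null(input_panel)) {
    abort("Either a simulation block or an input panel is required.")
  }
  structure(
    list(
      simulate = simulate, input_panel = input_panel,
      input_baseline = input_baseline, outcome_item = outcome_item,
      compliance_fraction = compliance_fraction, window = as.integer(window),
      G_range = G_range, df = as.integer(df),
      n_starts = as.integer(n_starts), burn_iters = as.integer(burn_iters),
      retry_starts = as.integer(retry_starts),
      selection = selection, mcid = mcid, outlier_k = outlier_k,
      output_dir = output_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full trajectory analysis
#'
#' Executes the stages in order -- simulate (or read), compliance filter,
#' moving-average smoothing, outlier flagging, class enumeration,
#' triangulated selection, baseline contrasts, PROM/MCID changes and
#' symptom dynamics -- and returns a machine-readable run report.  Subject
#' counts are reconciled at every stage, and identical configuration and
#' seed give identical reports.  When `output_dir` is set, every
#' intermediate artifact is written as CSV/JSON.
#'
#' @param config A [run_config()].
#' @return A list of class `lcgmm_run` with elements `report` (counts,
#'   thresholds, missingness, seed), `selection`, `recommendation`, `fit`
#'   (the recommended model), `assignments`, `contrasts`, `prom_changes`,
#'   `dynamics` and the intermediate data (`panel`, `smoothed`,
#'   `baseline`, `truth` when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  truth <- NULL
  baseline <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      sc <- config$simulate
      sc$seed <- config$seed
      simulate_ema(sc)
    })
    panel <- sim$panel
    truth <- sim$truth
    n_days <- config$simulate$n_days
    baseline <- stage("simulate_baseline", simulate_baseline(truth, sim$config))
  } else {
    panel <- stage("read", read_ema_long(config$input_panel))
    n_days <- max(panel$day) + 1L
    if (!is.null(config$input_baseline)) {
      baseline <- readr::read_csv(config$input_baseline, show_col_types = FALSE)
    }
  }
  n_subjects_in <- dplyr::n_distinct(panel$subject_id)

  filt <- stage("compliance_filter", compliance_filter(
    panel, config$outcome_item, config$compliance_fraction, n_days
  ))
  smoothed <- stage("moving_average", moving_average(
    filt$panel, n_days = n_days, window = config$window
  ))
  outliers <- stage("outlier_flagging", flag_outlier_subjects(
    smoothed, item = config$outcome_item, k = config$outlier_k
  ))
  missing <- stage("missingness_report", missingness_report(
    filt$panel, smoothed, n_days
  ))

  outcome <- smoothed |>
    dplyr::filter(.data$item == config$outcome_item, !is.na(.data$value)) |>
    dplyr::select("subject_id", "day", "value")
  ldata <- stage("model_data", lcgmm_data(outcome, spline_basis_spec(config$df)))

  selection <- stage("enumerate_classes", enumerate_classes(
    ldata,
    G_range = config$G_range, seed = config$seed,
    n_starts = config$n_starts, burn_iters = config$burn_iters,
    retry_starts = config$retry_starts
  ))
  recommendation <- stage(
    "select_model",
    do.call(select_model, c(list(selection), config$selection))
  )
  G_star <- recommendation$recommended_G
  if (is.na(G_star)) abort("Stage 'select_model' failed: no admissible solution.")
  fit <- attr(selection, "fits")[[paste0("G", G_star)]]
  assignments <- tibble::tibble(
    subject_id = fit$subject_ids,
    class = as.integer(fit$assignment)
  )

  contrasts <- NULL
  prom_changes <- NULL
  if (!is.null(baseline) && G_star >= 2) {
    contrasts <- stage(
      "contrast_baseline",
      contrast_baseline(baseline, assignments)
    )
    prom_changes <- stage(
      "prom_change_by_class",
      prom_change_by_class(baseline, assignments, mcid = config$mcid)
    )
  }

  dyn_items <- setdiff(unique(smoothed$item), config$outcome_item)
  dynamics <- stage("symptom_dynamics", {
    out <- list()
    out$class_trajectories <- purrr::map_dfr(
      unique(smoothed$item),
      function(it) {
        dplyr::mutate(
          class_mean_trajectories(smoothed, assignments, it),
          item = it
        )
      }
    )
    if (all(c("maximum_tinnitus_loudness", "daily_tinnitus_distress")
    %in% dyn_items)) {
      out$weekly_correlation <- weekly_class_correlation(
        smoothed, "maximum_tinnitus_loudness", "daily_tinnitus_distress",
        assignments
      )
      sdiff <- standardized_difference(smoothed)
      out$standardized_difference <- sdiff
      out$standardized_difference_summary <-
        standardized_difference_summary(sdiff, assignments)
    }
    out
  })

  report <- list(
    seed = config$seed,
    outcome_item = config$outcome_item,
    compliance_fraction = config$compliance_fraction,
    compliance_threshold = filt$threshold,
    n_days = n_days,
    n_subjects_in = n_subjects_in,
    n_subjects_excluded = length(filt$excluded),
    n_subjects_analysed = dplyr::n_distinct(outcome$subject_id),
    n_observations_raw = nrow(panel),
    raw_missing_fraction = missing$raw_fraction,
    smoothed_missing_fraction = missing$smoothed_fraction,
    outlier_flags = outliers,
    G_range = config$G_range,
    recommended_G = G_star,
    class_proportions = as.vector(fit$params$pi),
    entropy = if (G_star >= 2) relative_entropy(fit$posterior) else NA_real_,
    ppm = ppm(fit$posterior, fit$assignment)
  )
  stopifnot(
    report$n_subjects_in ==
      report$n_subjects_excluded + dplyr::n_distinct(filt$panel$subject_id)
  )

  run <- structure(
    list(
      report = report, config = config,
      selection = selection, recommendation = recommendation,
      fit = fit, assignments = assignments,
      contrasts = contrasts, prom_changes = prom_changes,
      dynamics = dynamics,
      panel = panel, smoothed = smoothed,
      baseline = baseline, truth = truth
    ),
    class = "lcgmm_run"
  )
  if (!is.null(config$output_dir)) write_run_artifacts(run, config$output_dir)
  run
}

#' @export
print.lcgmm_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<lcgmm_run> %d/%d subjects analysed (threshold %d obs), G = %d\n",
    r$n_subjects_analysed, r$n_subjects_in, r$compliance_threshold,
    r$recommended_G
  ))
  cat(sprintf(
    "  missingness raw %.1f%% -> smoothed %.1f%%; entropy %.3f\n",
    100 * r$raw_missing_fraction, 100 * r$smoothed_missing_fraction,
    r$entropy
  ))
  invisible(x)
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$panel, file.path(dir, "panel_raw.csv"))
  readr::write_csv(run$smoothed, file.path(dir, "panel_smoothed.csv"))
  sel <- tibble::as_tibble(run$selection) |>
    dplyr::mutate(
      ppm = vapply(.data$ppm, paste, character(1), collapse = ";"),
      class_proportions = vapply(
        .data$class_proportions, paste, character(1),
        collapse = ";"
      )
    )
  readr::write_csv(sel, file.path(dir, "selection_table.csv"))
  jsonlite::write_json(
    run$recommendation[c("recommended_G", "candidate_order", "rules")],
    file.path(dir, "recommendation.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_lcgmm_json(run$fit, file.path(dir, "fit.json"))
  readr::write_csv(run$assignments, file.path(dir, "assignments.csv"))
  if (!is.null(run$contrasts)) {
    readr::write_csv(run$contrasts, file.path(dir, "baseline_contrasts.csv"))
  }
  if (!is.null(run$prom_changes)) {
    readr::write_csv(run$prom_changes, file.path(dir, "prom_changes.csv"))
  }
  if (!is.null(run$dynamics$class_trajectories)) {
    readr::write_csv(
      run$dynamics$class_trajectories,
      file.path(dir, "class_trajectories.csv")
    )
  }
  jsonlite::write_json(
    run$report, file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Compare two runs of the pipeline (sensitivity analysis)
#'
#' Aligns the classes of two runs on the same raw panel (e.g. 50% vs 10%
#' compliance thresholds) by minimising the summed distance between fitted
#' class mean curves under label permutation, then tabulates proportion and
#' curve differences.  Runs with different numbers of classes are aligned
#' by the best injective map and flagged.
#'
#' @param run_a,run_b `lcgmm_run` objects (or `lcgmm_fit`s).
#' @return Tibble `class_a, class_b, proportion_a, proportion_b,
#'   proportion_diff, curve_rmse`; `attr(, "G_mismatch")` marks unequal
#'   class counts.
#' @export
sensitivity_compare <- function(run_a, run_b) {
  fit_a <- if (inherits(run_a, "lcgmm_run")) run_a$fit else run_a
  fit_b <- if (inherits(run_b, "lcgmm_run")) run_b$fit else run_b
  Ga <- fit_a$spec$G
  Gb <- fit_b$spec$G
  swap <- Ga > Gb
  if (swap) {
    tmp <- fit_a
    fit_a <- fit_b
    fit_b <- tmp
    Ga <- fit_a$spec$G
    Gb <- fit_b$spec$G
  }
  b <- fit_a$spec$basis
  days <- seq(b$boundary_knots[1], b$boundary_knots[2], length.out = 50)
  ta <- predict_class_trajectory(fit_a, days)
  tb <- predict_class_trajectory(fit_b, days)
  curve <- function(tr, g) tr$estimate[tr$class == g]
  cost <- matrix(0, Ga, Gb)
  for (i in seq_len(Ga)) {
    for (j in seq_len(Gb)) {
      cost[i, j] <- sqrt(mean((curve(ta, i) - curve(tb, j))^2))
    }
  }
  map <- min_cost_assignment(cost)
  out <- tibble::tibble(
    class_a = seq_len(Ga),
    class_b = map,
    proportion_a = fit_a$params$pi,
    proportion_b = fit_b$params$pi[map],
    curve_rmse = cost[cbind(seq_len(Ga), map)]
  ) |>
    dplyr::mutate(
      proportion_diff = .data$proportion_a - .data$proportion_b
    )
  if (swap) {
    out <- dplyr::rename(out,
      class_b = "class_a", class_a = "class_b",
      proportion_b = "proportion_a", proportion_a = "proportion_b"
    ) |>
      dplyr::mutate(proportion_diff = -.data$proportion_diff) |>
      dplyr::select(
        "class_a", "class_b", "proportion_a", "proportion_b",
        "proportion_diff", "curve_rmse"
      )
  }
  attr(out, "G_mismatch") <- Ga != Gb
  out
}
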