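# small in-code fixtures shared across test files

# two well-separated flat classes, quick to fit
two_class_config <- function(n_subjects = 60, sigma_b = 3, sigma_eps = 5,
                             missing = 0, seed = 1L, n_days = 30) {
  sim_config(
    n_subjects = n_subjects, n_days = n_days,
    class_proportions = c(0.5, 0.5),
    class_anchor_curves = list(
      data.frame(day = c(0, n_days - 1), value = c(20, 20)),
      data.frame(day = c(0, n_days - 1), value = c(70, 70))
    ),
    sigma_b = sigma_b, sigma_eps = sigma_eps,
    missing_raw_fraction = missing, seed = seed
  )
}

# outcome-only tibble (subject_id, day, value) from a simulated panel
outcome_data <- function(sim) {
  dplyr::filter(sim$panel, item == sim$config$outcome_item) |>
    dplyr::select(subject_id, day, value)
}

# preprocess a simulated panel the way the pipeline does and return the
# smoothed outcome ready for fitting
smoothed_outcome <- function(sim, fraction = 0.5) {
  n_days <- sim$config$n_days
  filt <- compliance_filter(
    sim$panel, sim$config$outcome_item, fraction, n_days
  )
  sm <- moving_average(
    dplyr::filter(filt$panel, item == sim$config$outcome_item), n_days
  )
  dplyr::filter(sm, !is.na(value)) |>
    dplyr::select(subject_id, day, value)
}

# truth-aligned accuracy of a fit against simulation labels
fit_accuracy <- function(fit, truth) {
  idx <- match(fit$subject_ids, truth$subject_id)
  align_labels(
    as.integer(fit$assignment), truth$class_label[idx],
    G = max(fit$spec$G, max(truth$class_label))
  )
}

# random small panel with gaps for brute-force smoothing checks
random_gapped_panel <- function(n_subjects = 4, n_days = 20, p_miss = 0.3,
                                seed = 1) {
  withr::with_seed(seed, {
    full <- tidyr::expand_grid(
      subject_id = paste0("s", seq_len(n_subjects)),
      day = 0:(n_days - 1)
    )
    full$item <- "a"
    full$value <- round(runif(nrow(full), 0, 100), 1)
    full[runif(nrow(full)) > p_miss, ]
  })
}
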