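#' @export
print.lcgmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lcgmm_fit> G = %d classes, %d subjects, %d observations\n",
    x$spec$G, x$n_subjects, x$n_obs
  ))
  cat(sprintf(
    "  loglik %.2f (npar %d), %s after %d iterations\n",
    x$loglik, x$npar,
    if (x$converged) "converged" else "NOT converged", x$n_iterations
  ))
  cat(
    "  proportions:",
    paste(sprintf("%.3f", x$params$pi), collapse = ", "), "\n"
  )
  cat(sprintf(
    "  sigma_b %.3f, sigma_eps %.3f\n",
    x$params$sigma_b, x$params$sigma_eps
  ))
  if (!is.na(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Tidy a fitted latent-class trajectory model
#'
#' @param x An `lcgmm_fit`.
#' @param ... Unused.
#' @return Tibble with one row per class and coefficient: `class`, `term`,
#'   `estimate`, `std.error`.
#' @export
tidy.lcgmm_fit <- function(x, ...) {
  terms <- c("(Intercept)", paste0("ns", seq_len(x$spec$df)))
  purrr::map_dfr(seq_len(x$spec$G), function(g) {
    V <- x$beta_vcov[[g]]
    tibble::tibble(
      class = g,
      term = terms,
      estimate = x$params$beta[, g],
      std.error = sqrt(pmax(diag(V), 0))
    )
  })
}

#' One-row summary of a fitted latent-class trajectory model
#'
#' @param x An `lcgmm_fit`.
#' @param ... Unused.
#' @return Tibble with `G`, `loglik`, `npar`, `AIC`, `BIC`, `entropy`
#'   (`NA` for `G = 1`), `ppm_min`, `min_class_n`, `sigma_b`, `sigma_eps`,
#'   `n_subjects`, `n_obs`, `converged`, `n_iterations`.
#' @export
glance.lcgmm_fit <- function(x, ...) {
  ic <- information_criteria(x$loglik, x$npar, x$n_subjects)
  ppm_vals <- ppm(x$posterior, x$assignment)
  tibble::tibble(
    G = x$spec$G,
    loglik = x$loglik,
    npar = x$npar,
    AIC = ic[["AIC"]],
    BIC = ic[["BIC"]],
    entropy = if (x$spec$G >= 2) relative_entropy(x$posterior) else NA_real_,
    ppm_min = min(ppm_vals, na.rm = TRUE),
    min_class_n = min(tabulate(x$assignment, nbins = x$spec$G)),
    sigma_b = x$params$sigma_b,
    sigma_eps = x$params$sigma_eps,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    converged = x$converged,
    n_iterations = x$n_iterations
  )
}

#' Per-subject classification of a fitted model
#'
#' @param x An `lcgmm_fit`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, posterior probability columns
#'   `.posterior1 .. .posteriorG`, modal `.class` and its posterior
#'   `.class_prob`.
#' @export
augment.lcgmm_fit <- function(x, ...) {
  P <- x$posterior
  out <- tibble::as_tibble(P, .name_repair = ~ paste0(".posterior", seq_len(ncol(P))))
  dplyr::bind_cols(
    tibble::tibble(subject_id = x$subject_ids),
    out,
    tibble::tibble(
      .class = as.integer(x$assignment),
      .class_prob = P[cbind(seq_len(nrow(P)), x$assignment)]
    )
  )
}

#' Plot fitted class trajectories
#'
#' @param object An `lcgmm_fit`.
#' @param ... Passed to [predict_class_trajectory()].
#' @return A ggplot of the class mean curves with 95% confidence ribbons.
#' @export
autoplot.lcgmm_fit <- function(object, ...) {
  traj <- predict_class_trajectory(object, ...) |>
    dplyr::mutate(class = factor(.data$class))
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$day, y = .data$estimate,
    colour = .data$class, fill = .data$class
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(
      x = "Study day", y = "Fitted outcome (VAS 0-100)",
      colour = "Class", fill = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' Export a fitted model to JSON
#'
#' Serialises specification, parameters, convergence block, knots and
#' per-subject posteriors so a fit can be archived alongside pipeline
#' output.
#'
#' @param fit An `lcgmm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lcgmm_json <- function(fit, path) {
  out <- list(
    spec = list(
      G = fit$spec$G, df = fit$spec$df,
      interior_knots = fit$spec$basis$interior_knots,
      boundary_knots = fit$spec$basis$boundary_knots
    ),
    params = list(
      beta = unclass(fit$params$beta), sigma_b = fit$params$sigma_b,
      sigma_eps = fit$params$sigma_eps, pi = fit$params$pi
    ),
    loglik = fit$loglik, npar = fit$npar,
    convergence = list(
      converged = fit$converged, n_iterations = fit$n_iterations,
      best_start_index = fit$best_start_index, diagnostic = fit$diagnostic
    ),
    posterior = as.data.frame(fit$posterior),
    assignment = as.list(fit$assignment)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
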