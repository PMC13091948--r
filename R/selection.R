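#' Information criteria for a fitted mixture
#'
#' `AIC = -2 loglik + 2 npar`; `BIC = -2 loglik + log(n) npar` with the
#' number of subjects as the sample size (the convention for subject-level
#' mixtures).
#'
#' @param loglik Log-likelihood.
#' @param npar Number of free parameters.
#' @param n_subjects Number of subjects.
#' @return Named numeric vector `c(AIC =, BIC =)`.
#' @export
#' @examples
#' information_criteria(-100, 6, 147)
information_criteria <- function(loglik, npar, n_subjects) {
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  c(
    AIC = -2 * loglik + 2 * npar,
    BIC = -2 * loglik + log(n_subjects) * npar
  )
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p log p) / (N log G)`: 1 when every subject is classified with
#' certainty, 0 when every posterior is uniform.  Undefined for a single
#' class.
#'
#' @param posterior Matrix (subjects x classes) with rows summing to 1.
#' @return Value in `[0, 1]`.
#' @export
relative_entropy <- function(posterior) {
  G <- ncol(posterior)
  if (G < 2) abort("Relative entropy is undefined for G = 1.")
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    abort("Posterior rows must sum to 1.")
  }
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - sum(-plogp) / (nrow(posterior) * log(G))
}

#' Posterior probability of membership (PPM) per class
#'
#' For each class, the mean posterior probability of its modally assigned
#' members; a classification-accuracy diagnostic.  Empty classes are
#' reported as `NA`.
#'
#' @param posterior Matrix (subjects x classes).
#' @param assignment Modal class per subject (row argmax).
#' @return Numeric vector of length `G`.
#' @export
ppm <- function(posterior, assignment) {
  G <- ncol(posterior)
  vapply(seq_len(G), function(g) {
    members <- which(assignment == g)
    if (!length(members)) return(NA_real_)
    mean(posterior[members, g])
  }, numeric(1))
}

#' Enumerate candidate class counts
#'
#' Fits the model for each `G` in `G_range` with the multi-start search and
#' assembles the per-`G` fit and classification diagnostics.  Non-convergent
#' rows are flagged, never dropped.
#'
#' @param ldata An [lcgmm_data()] object (or tibble with `subject_id`,
#'   `day`, `value`, in which case `df` builds the basis).
#' @param G_range Integer vector of class counts (default `1:10`).
#' @param df Spline degrees of freedom when `ldata` is a tibble.
#' @param seed Base seed; each `G` uses a derived sub-seed.
#' @param ... Passed to [grid_search_fit()] (`n_starts`, `burn_iters`, ...).
#' @return A tibble of class `lcgmm_selection` with columns `G`, `loglik`,
#'   `npar`, `AIC`, `BIC`, `entropy`, `ppm` (list), `class_proportions`
#'   (list), `min_class_n`, `converged`; the fitted models are attached as
#'   `attr(, "fits")`.
#' @export
enumerate_classes <- function(ldata, G_range = 1:10, df = 3, seed = 1L, ...) {
  if (!inherits(ldata, "lcgmm_data")) {
    ldata <- lcgmm_data(ldata, spline_basis_spec(df))
  }
  fits <- lapply(G_range, function(G) {
    grid_search_fit(ldata, G, seed = derive_seed(seed, G), ...)
  })
  rows <- purrr::map2_dfr(fits, G_range, function(fit, G) {
    tibble::tibble(
      G = G,
      loglik = fit$loglik,
      npar = fit$npar,
      AIC = information_criteria(fit$loglik, fit$npar, fit$n_subjects)[["AIC"]],
      BIC = information_criteria(fit$loglik, fit$npar, fit$n_subjects)[["BIC"]],
      entropy = if (G >= 2) relative_entropy(fit$posterior) else NA_real_,
      ppm = list(ppm(fit$posterior, fit$assignment)),
      class_proportions = list(as.vector(fit$params$pi)),
      min_class_n = min(tabulate(fit$assignment, nbins = G)),
      max_pair_overlap = max_pair_overlap(fit),
      converged = fit$converged
    )
  })
  attr(rows, "fits") <- setNames(fits, paste0("G", G_range))
  class(rows) <- c("lcgmm_selection", class(rows))
  rows
}

# largest fraction of days, over class pairs, on which the two fitted mean
# curves lie within each other's pointwise 95% bands -- the "strongly
# overlapping trajectories" symptom of a redundant extra class
max_pair_overlap <- function(fit, level = 0.95) {
  G <- fit$spec$G
  if (G < 2 || !fit$converged) return(NA_real_)
  traj <- tryCatch(predict_class_trajectory(fit, level = level),
    error = function(e) NULL
  )
  if (is.null(traj)) return(NA_real_)
  z <- qnorm(1 - (1 - level) / 2)
  est <- split(traj$estimate, traj$class)
  se <- split(traj$se, traj$class)
  worst <- 0
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      frac <- mean(
        abs(est[[i]] - est[[j]]) < z * (se[[i]] + se[[j]])
      )
      worst <- max(worst, frac)
    }
  }
  worst
}

#' Triangulated model recommendation
#'
#' Encodes the judgment-based selection protocol as an explicit rule set:
#' solutions containing a class below `min_class_fraction` are flagged;
#' a solution containing a pair of classes whose mean curves overlap within
#' each other's confidence bands on most days is flagged as redundant
#' (the conservative "avoid overfitting" judgment).  Among unflagged
#' candidates with a preferred class count, solutions are ranked by
#' relative entropy, then mean PPM (each compared at a stated tolerance so
#' that near-ties fall through to the next criterion), then BIC.  The
#' report lists every candidate with reasons rather than emitting a silent
#' single answer.
#'
#' @param table An `lcgmm_selection` tibble from [enumerate_classes()].
#' @param min_class_fraction Smallest acceptable class proportion
#'   (default 0.05).
#' @param preferred_solutions Class counts inspected closely
#'   (default `c(3, 4, 5)`); ignored when none are available.
#' @param entropy_tol,ppm_tol Differences below these tolerances count as
#'   ties (defaults 0.01).
#' @param redundancy_overlap Flag solutions whose most-overlapping class
#'   pair has pointwise-CI overlap on more than this fraction of days
#'   (default 0.9); only applied when the table carries the
#'   `max_pair_overlap` column.
#' @return A list of class `lcgmm_recommendation` with `recommended_G`
#'   (`NA` if every row is flagged), `ranking` (tibble with reasons) and the
#'   rule parameters.
#' @export
select_model <- function(table, min_class_fraction = 0.05,
                         preferred_solutions = c(3, 4, 5),
                         entropy_tol = 0.01, ppm_tol = 0.01,
                         redundancy_overlap = 0.9) {
  if (!nrow(table)) abort("Empty selection table.")
  tab <- tibble::as_tibble(table)
  tab$ppm_mean <- vapply(tab$ppm, function(p) mean(p, na.rm = TRUE), numeric(1))
  tab$small_class <- vapply(
    tab$class_proportions,
    function(p) any(p < min_class_fraction), logical(1)
  )
  tab$redundant <- if ("max_pair_overlap" %in% names(tab)) {
    !is.na(tab$max_pair_overlap) & tab$max_pair_overlap > redundancy_overlap
  } else {
    FALSE
  }
  tab$flagged <- tab$small_class | tab$redundant | !tab$converged
  tab$reason <- dplyr::case_when(
    !tab$converged ~ "not converged",
    tab$small_class ~ sprintf("class below %.0f%%", 100 * min_class_fraction),
    tab$redundant ~ "redundant classes (overlapping trajectories)",
    TRUE ~ "candidate"
  )
  candidates <- tab[!tab$flagged & tab$G %in% preferred_solutions, ]
  if (!nrow(candidates)) candidates <- tab[!tab$flagged, ]
  recommended <- NA_integer_
  if (nrow(candidates)) {
    # tolerance-based triangulation: solutions within `entropy_tol` of the
    # best entropy advance to the PPM comparison, those within `ppm_tol` of
    # the best PPM advance to BIC, lowest BIC wins; full order for reporting
    ent <- ifelse(is.na(candidates$entropy), 1, candidates$entropy)
    key <- function(i) {
      in_ent <- ent[i] >= max(ent) - entropy_tol
      in_ppm <- in_ent &
        candidates$ppm_mean[i] >=
          max(candidates$ppm_mean[ent >= max(ent) - entropy_tol]) - ppm_tol
      c(!in_ent, !in_ppm)
    }
    keys <- t(vapply(seq_len(nrow(candidates)), key, logical(2)))
    ord <- order(keys[, 1], keys[, 2], candidates$BIC, -ent)
    candidates <- candidates[ord, ]
    recommended <- candidates$G[1]
  }
  ranking <- dplyr::select(
    tab, "G", "AIC", "BIC", "entropy", "ppm_mean",
    "min_class_n", "flagged", "reason"
  )
  structure(
    list(
      recommended_G = recommended,
      ranking = ranking,
      candidate_order = candidates$G,
      rules = list(
        min_class_fraction = min_class_fraction,
        preferred_solutions = preferred_solutions,
        entropy_tol = entropy_tol, ppm_tol = ppm_tol
      )
    ),
    class = "lcgmm_recommendation"
  )
}

#' @export
print.lcgmm_recommendation <- function(x, ...) {
  if (is.na(x$recommended_G)) {
    cat("<lcgmm_recommendation> no admissible solution (all rows flagged)\n")
  } else {
    cat(sprintf(
      "<lcgmm_recommendation> G = %d (candidate order: %s)\n",
      x$recommended_G, paste(x$candidate_order, collapse = " > ")
    ))
  }
  print(x$ranking)
  invisible(x)
}

#' Plot a class-enumeration table
#'
#' @param object An `lcgmm_selection` tibble.
#' @param ... Unused.
#' @return A ggplot of AIC/BIC and entropy against the number of classes.
#' @export
autoplot.lcgmm_selection <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("G", "AIC", "BIC", "entropy") |>
    tidyr::pivot_longer(-"G", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$G, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "Number of classes", y = NULL) +
    ggplot2::theme_minimal()
}
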