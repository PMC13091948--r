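# floor on the residual standard deviation, avoids degenerate likelihood spikes
SIGMA_EPS_FLOOR <- 1e-4

# one GLS M-step for the class-specific fixed effects given variance
# components and posterior weights P (nsub x G)
mstep_beta <- function(ldata, P, sigma_b, sigma_eps) {
  p <- ldata$p
  G <- ncol(P)
  ve <- sigma_eps^2
  vb <- sigma_b^2
  cc <- vb / (ve + ldata$n_i * vb)
  beta <- matrix(NA_real_, p, G)
  ok <- TRUE
  for (g in seq_len(G)) {
    w <- P[, g]
    A <- matrix(colSums(w * (ldata$XtX_flat - cc * ldata$SXSX_flat)), p, p,
      byrow = TRUE
    )
    b <- colSums(w * (ldata$Xty - cc * ldata$SX * ldata$Sy))
    bg <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(bg)) {
      ok <- FALSE
      break
    }
    beta[, g] <- bg
  }
  list(beta = beta, ok = ok)
}

# maximise the expected complete-data log-likelihood over the two variance
# components, beta fixed; returns updated (sigma_b, sigma_eps)
mstep_variances <- function(ldata, P, beta, sigma_b, sigma_eps) {
  rs <- residual_sums(ldata, beta)
  a_i <- rowSums(P * rs$SSR)
  b2_i <- rowSums(P * rs$S^2)
  n_i <- ldata$n_i
  negQ <- function(par) {
    vb <- exp(2 * par[1])
    ve <- max(exp(2 * par[2]), SIGMA_EPS_FLOOR^2)
    cc <- vb / (ve + n_i * vb)
    0.5 * sum(
      (n_i - 1) * log(ve) + log(ve + n_i * vb) + (a_i - cc * b2_i) / ve
    )
  }
  par0 <- c(log(max(sigma_b, 1e-6)), log(max(sigma_eps, SIGMA_EPS_FLOOR)))
  opt <- optim(par0, negQ,
    method = "Nelder-Mead",
    control = list(maxit = 300, reltol = 1e-12)
  )
  if (opt$value <= negQ(par0)) {
    list(
      sigma_b = exp(opt$par[1]),
      sigma_eps = max(exp(opt$par[2]), SIGMA_EPS_FLOOR)
    )
  } else {
    list(sigma_b = sigma_b, sigma_eps = sigma_eps)
  }
}

#' Fit the latent-class mixed model by EM from a given start
#'
#' Alternates E-steps (posterior class probabilities) with conditional
#' M-steps: a weighted generalised-least-squares update of the
#' class-specific spline coefficients under the compound-symmetry
#' covariance, the mean posterior for the mixing proportions, and numerical
#' maximisation of the expected complete-data likelihood over the two
#' variance components.  The observed-data log-likelihood is non-decreasing
#' across iterations; iteration stops when its relative change falls below
#' `tol`.
#'
#' @param ldata An [lcgmm_data()] object.
#' @param start An [lcgmm_params()] starting point.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change tolerance (default 1e-8).
#' @return An `lcgmm_fit` object (see [grid_search_fit()]).
#' @export
fit_em <- function(ldata, start, max_iter = 500L, tol = 1e-8) {
  params <- start
  G <- length(params$pi)
  trace <- numeric(0)
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  ll_prev <- -Inf
  P <- NULL
  repeat {
    ll_mat <- class_logliks(ldata, params)
    lw <- sweep(ll_mat, 2, log(params$pi), `+`)
    lse <- logsumexp_rows(lw)
    loglik <- sum(lse)
    P <- exp(lw - lse)
    trace <- c(trace, loglik)
    if (iter > 0 &&
      abs(loglik - ll_prev) < tol * (abs(ll_prev) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    mass <- colSums(P)
    if (any(mass < 1)) {
      diagnostic <- sprintf(
        "degenerate class (posterior mass %.3f < 1 subject)", min(mass)
      )
      break
    }
    ll_prev <- loglik
    iter <- iter + 1L
    # M-step
    bs <- mstep_beta(ldata, P, params$sigma_b, params$sigma_eps)
    if (!bs$ok) {
      diagnostic <- "singular GLS system in M-step"
      break
    }
    vs <- mstep_variances(ldata, P, bs$beta, params$sigma_b, params$sigma_eps)
    params <- lcgmm_params(
      beta = bs$beta, sigma_b = vs$sigma_b,
      sigma_eps = vs$sigma_eps, pi = mass / ldata$n_subjects
    )
  }
  new_lcgmm_fit(ldata, params,
    loglik = trace[length(trace)], posterior = P,
    converged = converged, n_iterations = iter,
    loglik_trace = trace, diagnostic = diagnostic
  )
}

# assemble a fit object (labels in optimizer order; relabelling done later)
new_lcgmm_fit <- function(ldata, params, loglik, posterior, converged,
                          n_iterations, loglik_trace,
                          diagnostic = NA_character_,
                          best_start_index = NA_integer_) {
  G <- length(params$pi)
  rownames(posterior) <- ldata$subject_ids
  assignment <- max.col(posterior, ties.method = "first")
  names(assignment) <- ldata$subject_ids
  structure(
    list(
      spec = list(G = G, basis = ldata$basis, df = ldata$basis$df),
      params = params,
      loglik = loglik,
      posterior = posterior,
      assignment = assignment,
      subject_ids = ldata$subject_ids,
      n_subjects = ldata$n_subjects,
      n_obs = ldata$n_obs,
      npar = count_parameters(G, ldata$basis$df),
      converged = converged,
      n_iterations = n_iterations,
      best_start_index = best_start_index,
      loglik_trace = loglik_trace,
      diagnostic = diagnostic,
      beta_vcov = beta_vcov_blocks(ldata, params, posterior),
      relabeling = seq_len(G)
    ),
    class = "lcgmm_fit"
  )
}

# per-class covariance of the spline coefficients from the weighted GLS
# information block (used for pointwise trajectory confidence bands)
beta_vcov_blocks <- function(ldata, params, P) {
  p <- ldata$p
  ve <- params$sigma_eps^2
  vb <- params$sigma_b^2
  cc <- vb / (ve + ldata$n_i * vb)
  lapply(seq_len(ncol(P)), function(g) {
    w <- P[, g]
    A <- matrix(colSums(w * (ldata$XtX_flat - cc * ldata$SXSX_flat)), p, p,
      byrow = TRUE
    ) / ve
    tryCatch(solve(A), error = function(e) matrix(NA_real_, p, p))
  })
}

#' Number of free parameters of the model
#'
#' `G` classes with intercept-plus-spline means of `df` degrees of freedom:
#' `G * (1 + df)` fixed effects, `G - 1` mixing parameters and two variance
#' components.
#'
#' @param G Number of classes.
#' @param df Spline degrees of freedom (>= 1).
#' @return Integer count.
#' @export
#' @examples
#' count_parameters(4, 3) # 21
count_parameters <- function(G, df = 3) {
  if (G < 1) abort("`G` must be at least 1.")
  if (df < 1) abort("`df` must be at least 1.")
  as.integer(G * (1 + df) + (G - 1) + 2)
}

#' Maximum-likelihood fit of the one-class linear mixed model
#'
#' Fits the random-intercept spline model without mixture structure (the
#' `G = 1` special case), which also provides the starting point and the
#' coefficient standard errors used to generate the multi-start grid for
#' mixture fits.
#'
#' @inheritParams fit_em
#' @return An `lcgmm_fit` with `G = 1`; the coefficient standard errors are
#'   stored as `$beta_se`.
#' @export
fit_one_class <- function(ldata, max_iter = 500L, tol = 1e-10) {
  if (ldata$n_obs < ldata$p + 2) {
    abort("Fewer observations than parameters.")
  }
  # OLS start with an even variance split
  XtX <- crossprod(ldata$X)
  beta0 <- solve(XtX, crossprod(ldata$X, ldata$y))
  resid <- ldata$y - ldata$X %*% beta0
  v <- max(var(as.vector(resid)), SIGMA_EPS_FLOOR^2 * 2)
  start <- lcgmm_params(
    beta = matrix(beta0, ncol = 1),
    sigma_b = sqrt(v / 2), sigma_eps = sqrt(v / 2), pi = 1
  )
  fit <- fit_em(ldata, start, max_iter = max_iter, tol = tol)
  V <- fit$beta_vcov[[1]]
  fit$beta_se <- sqrt(pmax(diag(V), 0))
  fit
}

#' Multi-start grid-search estimation of the latent-class model
#'
#' Mirrors the reference estimation protocol for mixtures: starting values
#' are generated by perturbing the one-class solution (each class's
#' coefficients are the one-class coefficients plus
#' `perturb_scale` standard-error-scaled Gaussian noise; mixing proportions
#' start uniform), each start is run for `burn_iters` EM iterations, and the
#' start with the highest log-likelihood is run to full convergence.  If
#' that run fails to converge, the search is repeated once with
#' `retry_starts` starts.  Results are deterministic given `seed`.
#'
#' @inheritParams fit_em
#' @param G Number of latent classes; `G = 1` delegates to
#'   [fit_one_class()].
#' @param n_starts Number of random starts (default 30).
#' @param burn_iters EM iterations per start before selection (default 30).
#' @param perturb_scale Scale of the start perturbation in coefficient
#'   standard errors (default 1).
#' @param retry_starts Starts used in the single retry after
#'   non-convergence (default 50).
#' @param seed Integer seed for start generation.
#' @param reorder Relabel classes by fitted mean at day 0, descending, for
#'   stable reporting (default `TRUE`); the applied permutation is stored as
#'   `$relabeling`.
#' @return An object of class `lcgmm_fit` with elements `spec`, `params`,
#'   `loglik`, `posterior` (subjects x classes), `assignment`, `npar`,
#'   `converged`, `n_iterations`, `best_start_index` and `loglik_trace`.
#' @export
grid_search_fit <- function(ldata, G, n_starts = 30L, burn_iters = 30L,
                            perturb_scale = 1, max_iter = 500L, tol = 1e-8,
                            retry_starts = 50L, seed = 1L, reorder = TRUE) {
  one <- fit_one_class(ldata)
  if (G == 1L) return(one)
  run_search <- function(n_starts, seed) {
    starts <- withr::with_seed(seed, {
      lapply(seq_len(n_starts), function(s) {
        beta <- matrix(
          rep(one$params$beta, G) +
            rnorm(ldata$p * G, 0, perturb_scale * rep(one$beta_se, G)),
          ldata$p, G
        )
        # the one-class intercept variance absorbs the between-class spread
        # the mixture is meant to explain; deflate it for the starts
        lcgmm_params(
          beta = beta, sigma_b = one$params$sigma_b / G,
          sigma_eps = one$params$sigma_eps, pi = rep(1 / G, G)
        )
      })
    })
    burns <- lapply(starts, function(st) {
      fit_em(ldata, st, max_iter = burn_iters, tol = tol)
    })
    lls <- vapply(burns, function(f) f$loglik, numeric(1))
    best <- which.max(lls)
    fit <- fit_em(ldata, burns[[best]]$params, max_iter = max_iter, tol = tol)
    fit$best_start_index <- best
    fit
  }
  fit <- run_search(n_starts, seed)
  if (!fit$converged) {
    fit <- run_search(retry_starts, derive_seed(seed, 1L))
    if (!fit$converged && !is.na(fit$diagnostic)) {
      warn(paste0("Grid search did not converge: ", fit$diagnostic))
    }
  }
  if (reorder) fit <- relabel_fit(fit) else fit
}

# relabel classes by fitted mean value at day 0, descending
relabel_fit <- function(fit) {
  b <- fit$spec$basis
  x0 <- c(1, ncs_basis(b$boundary_knots[1], b))
  day0 <- as.vector(x0 %*% fit$params$beta)
  ord <- order(day0, decreasing = TRUE)
  apply_relabeling(fit, ord)
}

# permute class labels of a fit: new class k = old class ord[k]
apply_relabeling <- function(fit, ord) {
  inv <- match(seq_along(ord), ord)
  fit$params$beta <- fit$params$beta[, ord, drop = FALSE]
  fit$params$pi <- fit$params$pi[ord]
  fit$posterior <- fit$posterior[, ord, drop = FALSE]
  fit$assignment <- setNames(inv[fit$assignment], names(fit$assignment))
  fit$beta_vcov <- fit$beta_vcov[ord]
  fit$relabeling <- ord
  fit
}

#' Convenience front-end: fit a latent-class trajectory model
#'
#' Prepares the data and runs the multi-start estimation.
#'
#' @param data Tibble with `subject_id`, `day`, `value`.
#' @param G Number of latent classes.
#' @param df Spline degrees of freedom.
#' @param ... Passed to [grid_search_fit()].
#' @return An `lcgmm_fit`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_ema(default_study_config(seed = 3, n_subjects = 40))
#' outcome <- dplyr::filter(sim$panel, item == "tinnitus_related_thoughts")
#' fit <- lcgmm(outcome, G = 2, n_starts = 5, seed = 1)
#' glance(fit)
#' }
lcgmm <- function(data, G, df = 3, ...) {
  ldata <- lcgmm_data(data, spline_basis_spec(df))
  grid_search_fit(ldata, G, ...)
}

#' Predicted class mean trajectories with confidence bands
#'
#' Evaluates each class's fitted mean curve on a day grid with pointwise
#' 95% confidence intervals from the weighted generalised-least-squares
#' covariance of the class coefficients (delta method).
#'
#' @param fit A converged `lcgmm_fit`.
#' @param days Day grid; defaults to the integer days spanned by the
#'   boundary knots.
#' @param level Confidence level (default 0.95).
#' @return Tibble `class, day, estimate, se, conf_low, conf_high`.
#' @export
predict_class_trajectory <- function(fit, days = NULL, level = 0.95) {
  if (!fit$converged) abort("Trajectories require a converged fit.")
  b <- fit$spec$basis
  days <- days %||% seq(floor(b$boundary_knots[1]), ceiling(b$boundary_knots[2]))
  Xn <- cbind(1, ncs_basis(days, b))
  z <- qnorm(1 - (1 - level) / 2)
  purrr::map_dfr(seq_len(fit$spec$G), function(g) {
    est <- as.vector(Xn %*% fit$params$beta[, g])
    V <- fit$beta_vcov[[g]]
    se <- sqrt(pmax(rowSums((Xn %*% V) * Xn), 0))
    tibble::tibble(
      class = g, day = days, estimate = est, se = se,
      conf_low = est - z * se, conf_high = est + z * se
    )
  })
}
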