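#' Prepare trajectory data for latent-class mixed-model fitting
#'
#' Builds the fixed-effect design (intercept plus natural cubic spline of
#' day) and caches the per-subject cross-products that make the EM
#' iterations cheap under the compound-symmetry covariance implied by a
#' shared random intercept.
#'
#' @param data Tibble with columns `subject_id`, `day` and `value` (one row
#'   per observed day; e.g. the smoothed primary outcome with undefined days
#'   dropped).
#' @param basis A [spline_basis_spec()]; unresolved knots are filled from
#'   the observed days.
#' @return An object of class `lcgmm_data`.
#' @export
lcgmm_data <- function(data, basis = spline_basis_spec(3)) {
  stopifnot(all(c("subject_id", "day", "value") %in% names(data)))
  data <- dplyr::arrange(data, .data$subject_id, .data$day)
  basis <- resolve_basis_spec(basis, data$day)
  X <- cbind(1, ncs_basis(data$day, basis))
  y <- data$value
  subject_ids <- unique(data$subject_id)
  subj <- match(data$subject_id, subject_ids)
  p <- ncol(X)
  n_i <- as.vector(rowsum(rep(1, length(y)), subj))
  SX <- rowsum(X, subj)
  Sy <- as.vector(rowsum(y, subj))
  Xty <- rowsum(X * y, subj)
  yty <- as.vector(rowsum(y^2, subj))
  # flattened per-subject X_i'X_i and (colsum X_i)(colsum X_i)'
  prod_cols <- matrix(0, length(y), p * p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      prod_cols[, (a - 1) * p + b] <- X[, a] * X[, b]
    }
  }
  XtX_flat <- rowsum(prod_cols, subj)
  SXSX_flat <- matrix(0, length(n_i), p * p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      SXSX_flat[, (a - 1) * p + b] <- SX[, a] * SX[, b]
    }
  }
  structure(
    list(
      y = y, X = X, subj = subj, day = data$day,
      subject_ids = subject_ids, n_subjects = length(subject_ids),
      n_obs = length(y), p = p, basis = basis,
      n_i = n_i, SX = SX, Sy = Sy, Xty = Xty, yty = yty,
      XtX_flat = XtX_flat, SXSX_flat = SXSX_flat
    ),
    class = "lcgmm_data"
  )
}

#' @export
print.lcgmm_data <- function(x, ...) {
  cat(sprintf(
    "<lcgmm_data> %d subjects, %d observations, spline df = %d\n",
    x$n_subjects, x$n_obs, x$basis$df
  ))
  invisible(x)
}

#' Parameter set of the latent-class linear mixed model
#'
#' @param beta Matrix of fixed-effect coefficients, one column per class;
#'   rows are intercept plus spline coefficients (VAS points).
#' @param sigma_b Random-intercept standard deviation (shared across
#'   classes), non-negative.
#' @param sigma_eps Residual standard deviation, positive (variance equal
#'   across classes).
#' @param pi Mixing proportions, summing to 1.
#' @return An object of class `lcgmm_params`.
#' @export
lcgmm_params <- function(beta, sigma_b, sigma_eps, pi) {
  beta <- as.matrix(beta)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) {
    abort("`pi` must be a probability vector.")
  }
  if (length(pi) != ncol(beta)) abort("One beta column per class is required.")
  if (sigma_b < 0) abort("`sigma_b` must be non-negative.")
  if (sigma_eps <= 0) abort("`sigma_eps` must be positive.")
  structure(
    list(
      beta = beta, sigma_b = sigma_b, sigma_eps = sigma_eps,
      pi = as.numeric(pi)
    ),
    class = "lcgmm_params"
  )
}

#' Gaussian log-likelihood under a compound-symmetry covariance
#'
#' Log-density of one subject's observation vector under mean `mu` and
#' covariance `sigma_b^2 J + sigma_eps^2 I` (shared random intercept plus
#' independent residuals), evaluated with the rank-one closed form for the
#' inverse and determinant rather than a dense factorisation.
#'
#' @param y Observed vector.
#' @param mu Mean vector of the same length.
#' @param sigma_b Random-intercept standard deviation.
#' @param sigma_eps Residual standard deviation (> 0).
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' cs_loglik(0, 0, 0, 1) # log standard-normal density at 0
cs_loglik <- function(y, mu, sigma_b, sigma_eps) {
  if (sigma_eps <= 0) abort("`sigma_eps` must be positive.")
  stopifnot(length(y) == length(mu))
  n <- length(y)
  r <- y - mu
  ve <- sigma_eps^2
  vb <- sigma_b^2
  s <- sum(r)
  ssr <- sum(r^2)
  cc <- vb / (ve + n * vb)
  -0.5 * (n * log(2 * pi) + (n - 1) * log(ve) + log(ve + n * vb) +
    (ssr - cc * s^2) / ve)
}

# per-subject residual sums for every class: list(S = nsub x G, SSR = nsub x G)
residual_sums <- function(ldata, beta) {
  G <- ncol(beta)
  S <- ldata$Sy - ldata$SX %*% beta
  SSR <- matrix(0, ldata$n_subjects, G)
  for (g in seq_len(G)) {
    bb <- as.vector(outer(beta[, g], beta[, g]))
    SSR[, g] <- ldata$yty - 2 * (ldata$Xty %*% beta[, g]) +
      ldata$XtX_flat %*% bb
  }
  # guard tiny negative values from cancellation
  SSR[SSR < 0] <- 0
  list(S = S, SSR = SSR)
}

# nsub x G matrix of per-subject class-conditional log-likelihoods
class_logliks <- function(ldata, params, rs = NULL) {
  rs <- rs %||% residual_sums(ldata, params$beta)
  ve <- params$sigma_eps^2
  vb <- params$sigma_b^2
  n_i <- ldata$n_i
  cc <- vb / (ve + n_i * vb)
  const <- -0.5 * (n_i * log(2 * pi) + (n_i - 1) * log(ve) +
    log(ve + n_i * vb))
  const - 0.5 * (rs$SSR - cc * rs$S^2) / ve
}

#' Observed-data log-likelihood of the mixture model
#'
#' Sum over subjects of the log of the class-probability-weighted
#' compound-symmetry Gaussian densities, computed with log-sum-exp
#' stabilisation.  With a single class this is the plain linear
#' mixed-model log-likelihood.
#'
#' @param ldata An [lcgmm_data()] object.
#' @param params An [lcgmm_params()] object.
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(ldata, params) {
  if (ldata$n_subjects == 0) abort("Empty data.")
  ll <- class_logliks(ldata, params)
  lw <- sweep(ll, 2, log(params$pi), `+`)
  sum(logsumexp_rows(lw))
}

#' Posterior class-membership probabilities
#'
#' For each subject, the conditional probability of belonging to each class
#' given its observed trajectory: proportional to the mixing proportion
#' times the class-conditional density, normalised per subject.
#'
#' @inheritParams mixture_loglik
#' @return Matrix (subjects x classes) with rows summing to 1 and
#'   `subject_ids` as row names.
#' @export
posterior_probs <- function(ldata, params) {
  ll <- class_logliks(ldata, params)
  lw <- sweep(ll, 2, log(params$pi), `+`)
  lse <- logsumexp_rows(lw)
  P <- exp(lw - lse)
  rownames(P) <- ldata$subject_ids
  P
}
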