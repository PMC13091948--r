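#' Natural cubic spline basis specification
#'
#' The class mean trajectories are natural cubic splines of time in days.
#' With `df` degrees of freedom the basis has `df` columns (the intercept is
#' carried separately), `df - 1` interior knots and two boundary knots; the
#' spline is linear beyond the boundary knots.  Unspecified knots are
#' resolved from the observed days when the model data are prepared:
#' interior knots at the `df`-tiles of pooled observed days, boundary knots
#' at the observed range.  Days are rescaled to `[0, 1]` before basis
#' construction for numerical conditioning.
#'
#' @param df Degrees of freedom, default 3.
#' @param interior_knots Optional interior knot positions in days
#'   (`df - 1` values strictly inside the boundary).
#' @param boundary_knots Optional `c(min, max)` day boundary.
#' @return An object of class `spline_basis_spec`.
#' @export
spline_basis_spec <- function(df = 3, interior_knots = NULL,
                              boundary_knots = NULL) {
  if (df < 1) abort("`df` must be at least 1.")
  if (!is.null(interior_knots) && length(interior_knots) != df - 1) {
    abort("A natural cubic spline with `df` basis columns needs df - 1 interior knots.")
  }
  if (!is.null(boundary_knots)) {
    stopifnot(length(boundary_knots) == 2, diff(boundary_knots) > 0)
    if (!is.null(interior_knots) &&
      (any(interior_knots <= boundary_knots[1]) ||
        any(interior_knots >= boundary_knots[2]))) {
      abort("Interior knots must lie strictly inside the boundary knots.")
    }
  }
  structure(
    list(
      df = as.integer(df),
      interior_knots = interior_knots,
      boundary_knots = boundary_knots
    ),
    class = "spline_basis_spec"
  )
}

# fill unspecified knots from observed days
resolve_basis_spec <- function(spec, days) {
  if (is.null(spec$boundary_knots)) {
    spec$boundary_knots <- range(days)
  }
  if (is.null(spec$interior_knots) && spec$df > 1) {
    probs <- seq_len(spec$df - 1) / spec$df
    spec$interior_knots <- as.numeric(quantile(days, probs, names = FALSE))
  }
  spec
}

#' Evaluate the natural cubic spline basis
#'
#' @param days Numeric vector of days.
#' @param spec A [spline_basis_spec()] with resolved knots (as stored in a
#'   fitted model or returned by model-data preparation); unresolved knots
#'   are filled from `days`.
#' @return Matrix with `df` columns.
#' @export
ncs_basis <- function(days, spec) {
  spec <- resolve_basis_spec(spec, days)
  b <- spec$boundary_knots
  span <- b[2] - b[1]
  tol <- 0.05 * span
  if (any(days < b[1] - tol) || any(days > b[2] + tol)) {
    abort("Days fall outside the (extended) boundary-knot range.")
  }
  t_scaled <- (days - b[1]) / span
  k_scaled <- if (spec$df > 1) (spec$interior_knots - b[1]) / span else NULL
  X <- splines::ns(t_scaled, knots = k_scaled, Boundary.knots = c(0, 1))
  attr(X, "spec") <- spec
  unname(X[, , drop = FALSE])
}
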