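#' Parametric utility families
#'
#' Five parametric utility functions on the normalized reward domain
#' `[0, 1]`, all mapping magnitudes to utilities in `[0, 1]`:
#'
#' * `power1` -- one-parameter power, `U(m) = m^alpha`: concave
#'   (risk-averse) for `alpha < 1`, convex (risk-seeking) for `alpha > 1`.
#' * `tversky1` -- one-parameter inverse-S form
#'   `U(m) = m^gamma / (m^gamma + (1 - m)^gamma)^(1/gamma)`.  The family is
#'   named after the one-parameter probability-weighting curve it borrows;
#'   the transplant to magnitudes is a reconstruction of a family known
#'   only by name, and is documented as such.
#' * `prelec2` -- two-parameter Prelec, `U(m) = exp(-beta * (-ln m)^alpha)`.
#'   `alpha` controls curvature (`alpha > 1` S-shaped, `alpha < 1`
#'   inverse-S); `beta` elevation.  With `alpha = 1` it reduces exactly to
#'   the power law `m^beta`.
#' * `scdf2` -- CDF of the two-sided power distribution,
#'   `U(m) = beta * (m/beta)^alpha` for `m <= beta` and
#'   `1 - (1-beta) * ((1-m)/(1-beta))^alpha` above; `alpha > 1` S-shaped
#'   with inflection at the knot `beta`.
#' * `power3` -- anchored three-parameter power: the piecewise prospect-
#'   theoretic power `U0(m) = (m-gamma)^alpha` for `m >= gamma`,
#'   `-beta * (gamma-m)^alpha` below, affinely rescaled so `U(0) = 0` and
#'   `U(1) = 1`.  `gamma` is the inflection, `beta` weights the lower limb.
#'
#' @details All anchored families return exactly 0 at `m = 0` and 1 at
#' `m = 1` (the Prelec value at 0 is defined by its limit).
#'
#' @param family one of `utility_families()`.
#' @param params numeric vector of parameter values, in the family's
#'   documented order (`alpha`; `gamma`; `alpha, beta`; `alpha, beta`;
#'   `alpha, beta, gamma`).  Names, if given, are checked.
#' @return an object of class `utility_curve`.
#' @examples
#' utility_curve("prelec2", c(alpha = 2, beta = 1))
#' @export
utility_curve <- function(family, params) {
  family <- match.arg(family, utility_families())
  info <- utility_param_bounds(family)
  params <- unlist(params)
  if (length(params) != length(info$names)) {
    stop(sprintf("family '%s' takes %d parameter(s) (%s)", family,
                 length(info$names), paste(info$names, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(names(params)) && any(nzchar(names(params))) &&
      !identical(names(params), info$names)) {
    params <- params[info$names]
    if (anyNA(params)) stop("parameter names do not match family", call. = FALSE)
  }
  names(params) <- info$names
  out <- params < info$lower - 1e-12 | params > info$upper + 1e-12
  if (any(out)) {
    stop(sprintf("parameter %s = %g outside bounds [%g, %g] for family '%s'",
                 info$names[which(out)[1]], params[which(out)[1]],
                 info$lower[which(out)[1]], info$upper[which(out)[1]], family),
         call. = FALSE)
  }
  structure(list(family = family, params = params), class = "utility_curve")
}

#' @export
print.utility_curve <- function(x, ...) {
  cat(sprintf("<utility_curve %s(%s)>\n", x$family,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname utility_curve
#' @export
utility_families <- function() {
  c("power1", "tversky1", "prelec2", "scdf2", "power3")
}

#' Parameter names and bounds of a utility family
#'
#' Bounds keep every curve monotone, finite and identifiable: power-type
#' exponents in `[0.05, 20]`, the Prelec elevation in `[0.05, 20]`, the
#' two-sided-power knot strictly inside `(0, 1)`, the Tversky exponent at
#' least 0.3 (the one-parameter form loses monotonicity below ~0.28) and
#' the three-parameter power inflection in `[0, 1]`.
#'
#' @param family one of `utility_families()`.
#' @return list with `names`, `lower`, `upper`.
#' @export
utility_param_bounds <- function(family) {
  family <- match.arg(family, utility_families())
  switch(family,
    power1   = list(names = "alpha", lower = 0.05, upper = 20),
    tversky1 = list(names = "gamma", lower = 0.3, upper = 10),
    prelec2  = list(names = c("alpha", "beta"),
                    lower = c(0.05, 0.05), upper = c(20, 20)),
    scdf2    = list(names = c("alpha", "beta"),
                    lower = c(0.05, 0.01), upper = c(20, 0.99)),
    power3   = list(names = c("alpha", "beta", "gamma"),
                    lower = c(0.05, 0.05, 0), upper = c(20, 20, 1))
  )
}

#' Evaluate a utility curve on the normalized domain
#'
#' @param curve a [utility_curve()].
#' @param m normalized magnitude(s) in `[0, 1]`.
#' @return utilities; anchored families give exactly 0 at `m = 0` and 1 at
#'   `m = 1`.
#' @examples
#' eval_utility(utility_curve("power1", 2), c(0, 0.5, 1))
#' @export
eval_utility <- function(curve, m) {
  stopifnot(inherits(curve, "utility_curve"))
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE)) {
    stop("magnitude outside the normalized domain [0, 1]", call. = FALSE)
  }
  m <- pmin(pmax(m, 0), 1)
  p <- curve$params
  switch(curve$family,
    power1 = m^p[["alpha"]],
    tversky1 = {
      g <- p[["gamma"]]
      mm <- pmin(pmax(m, 1e-12), 1 - 1e-12)
      u <- mm^g / (mm^g + (1 - mm)^g)^(1 / g)
      u[m <= 0] <- 0
      u[m >= 1] <- 1
      u
    },
    prelec2 = {
      # singular at m = 0 (-ln m -> Inf); value defined by the limit U(0) = 0
      mm <- pmax(m, 1e-12)
      u <- exp(-p[["beta"]] * (-log(mm))^p[["alpha"]])
      u[m <= 0] <- 0
      u
    },
    scdf2 = {
      a <- p[["alpha"]]; b <- p[["beta"]]
      ifelse(m <= b,
             b * (m / b)^a,
             1 - (1 - b) * ((1 - m) / (1 - b))^a)
    },
    power3 = {
      a <- p[["alpha"]]; b <- p[["beta"]]; g <- p[["gamma"]]
      raw <- ifelse(m >= g, (m - g)^a, -b * (g - m)^a)
      r0 <- -b * g^a
      r1 <- (1 - g)^a
      (raw - r0) / (r1 - r0)
    }
  )
}

as_utility_fn <- function(curve) {
  if (is.function(curve)) return(curve)
  stopifnot(inherits(curve, "utility_curve"))
  function(m) eval_utility(curve, m)
}

#' Curvature ratio: normalized area under a utility curve
#'
#' The curvature ratio (CR) is the integral of the utility over the
#' normalized domain, i.e. the area under the curve divided by the area of
#' the unit square.  A linear utility has CR 0.5; CR above 0.5 means the
#' curve lies mostly above the diagonal (net concavity, risk aversion),
#' below 0.5 net convexity (risk seeking).
#'
#' Computed by the composite trapezoid rule on a uniform grid (default
#' 10001 points; accuracy ~1e-8 for the smooth families, well inside the
#' package-wide 1e-5 quadrature tolerance).
#'
#' @param curve a [utility_curve()] or a plain function on `[0, 1]`.
#' @param n grid size.
#' @return CR in `(0, 1)` for monotone anchored curves.
#' @examples
#' curvature_ratio(utility_curve("power1", 1))  # 0.5
#' curvature_ratio(utility_curve("power1", 2))  # 1/3
#' @export
curvature_ratio <- function(curve, n = 10001L) {
  f <- as_utility_fn(curve)
  x <- seq(0, 1, length.out = n)
  u <- f(x)
  sum((u[-1] + u[-n]) / 2) / (n - 1)
}

#' Inflection point of a utility curve
#'
#' The inflection is the unique interior magnitude where the curve's
#' curvature reverses (second derivative changes sign; for an S-shape the
#' point of maximal slope).  It is the model-based proxy for the reference
#' point: risk attitude flips from seeking to averse (or vice versa) there.
#'
#' For the kinked families the inflection is the knot itself (`beta` for
#' `scdf2`, `gamma` for `power3`, provided `alpha != 1`); for the smooth
#' families it is found numerically by locating the sign change of a
#' central-finite-difference second derivative and refining the bracket
#' with [stats::uniroot()] to 1e-6.
#'
#' @param curve a [utility_curve()].
#' @param n scan-grid size for the numerical search.
#' @return the normalized inflection location, or `NA_real_` when the
#'   curvature never reverses in `(0, 1)` (e.g. any pure power curve).
#' @examples
#' inflection_point(utility_curve("prelec2", c(2, 1)))
#' inflection_point(utility_curve("power1", 2))  # NA: purely convex
#' @export
inflection_point <- function(curve, n = 2001L) {
  stopifnot(inherits(curve, "utility_curve"))
  p <- curve$params
  if (curve$family == "power1") return(NA_real_)
  if (curve$family == "scdf2") {
    if (abs(p[["alpha"]] - 1) < 1e-9) return(NA_real_)
    return(unname(p[["beta"]]))
  }
  if (curve$family == "power3") {
    if (abs(p[["alpha"]] - 1) < 1e-9) return(NA_real_)
    g <- unname(p[["gamma"]])
    if (g <= 0 || g >= 1) return(NA_real_)
    return(g)
  }
  numeric_inflection(as_utility_fn(curve), n = n)
}

# Sign-change search for U'' via central second differences.  h = 1e-4
# balances truncation against cancellation (both ~1e-8 for U of order 1);
# |d2| below `zero_tol` is treated as numerically zero so float noise cannot
# masquerade as a curvature reversal.
numeric_inflection <- function(f, n = 2001L, lower = 1e-3, upper = 1 - 1e-3,
                               h = 1e-4, zero_tol = 1e-5) {
  d2 <- function(x) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  x <- seq(lower, upper, length.out = n)
  v <- d2(x)
  s <- sign(v)
  s[abs(v) < zero_tol] <- 0
  nz <- which(s != 0)
  if (length(nz) < 2) return(NA_real_)
  flips <- which(diff(s[nz]) != 0)
  if (length(flips) == 0) return(NA_real_)
  # distinct brackets (collapse flips adjacent on the grid)
  lo_idx <- nz[flips]
  hi_idx <- nz[flips + 1]
  keep <- c(TRUE, diff(lo_idx) > 5)
  lo_idx <- lo_idx[keep]; hi_idx <- hi_idx[keep]
  if (length(lo_idx) > 1) {
    stop("multiple curvature reversals detected; inflection is ambiguous",
         call. = FALSE)
  }
  stats::uniroot(d2, lower = x[lo_idx], upper = x[hi_idx],
                 tol = 1e-6)$root
}

#' Shape metrics of a utility curve in a reward distribution
#'
#' Bundles the curve's inflection (normalized and in ml) and curvature
#' ratio, the two summaries used to compare utilities across reward
#' distributions.
#'
#' @param curve a [utility_curve()].
#' @param distribution a [reward_distribution()] providing the ml anchors.
#' @return list with `inflection_norm`, `inflection_ml`, `curvature_ratio`.
#' @export
shape_metrics <- function(curve, distribution) {
  stopifnot(is_reward_distribution(distribution))
  infl <- inflection_point(curve)
  list(
    inflection_norm = infl,
    inflection_ml = if (is.na(infl)) NA_real_ else to_ml(infl, distribution),
    curvature_ratio = curvature_ratio(curve)
  )
}

#' Serialize / deserialize a utility curve as JSON
#'
#' @param curve a [utility_curve()].
#' @param distribution optional [reward_distribution()] recorded alongside.
#' @return `curve_to_json()` a JSON string; `curve_from_json()` the curve
#'   (with a `distribution` attribute when one was stored).
#' @export
curve_to_json <- function(curve, distribution = NULL) {
  stopifnot(inherits(curve, "utility_curve"))
  x <- list(family = curve$family, params = as.list(curve$params))
  if (!is.null(distribution)) {
    x$distribution <- list(label = distribution$label,
                           min_ml = distribution$min_ml,
                           max_ml = distribution$max_ml)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname curve_to_json
#' @param json JSON string produced by `curve_to_json()`.
#' @export
curve_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  curve <- utility_curve(x$family, unlist(x$params))
  if (!is.null(x$distribution)) {
    attr(curve, "distribution") <- reward_distribution(
      x$distribution$label, x$distribution$min_ml, x$distribution$max_ml)
  }
  curve
}
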