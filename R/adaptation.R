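#' Median utility curve of a set of daily fits
#'
#' The distribution-level summary curve is built from the per-parameter
#' median of the daily estimates (parameter-wise median, not the pointwise
#' median of the curves -- the two differ for non-linear families; the
#' parameter-wise convention matches how daily fits are summarized
#' throughout this package).
#'
#' @param fits list of `dcm_fit` objects from one distribution, one family.
#' @return a [utility_curve()].
#' @export
median_curve <- function(fits) {
  stopifnot(length(fits) >= 1)
  fam <- unique(vapply(fits, function(f) f$family, character(1)))
  if (length(fam) != 1) stop("fits mix utility families", call. = FALSE)
  par_mat <- do.call(rbind, lapply(fits, function(f) f$utility$params))
  utility_curve(fam, apply(par_mat, 2, stats::median))
}

#' Sequential adaptation coefficient (SAC)
#'
#' Relative change in the curvature ratio between the utilities of two
#' consecutive reward distributions, both taken on the normalized domain:
#' `SAC = (CR_n - CR_prev) / CR_prev`.  Zero when the normalized shape is
#' unchanged (full adaptation); negative when the newer utility is more
#' convex (more risk-seeking), positive when more concave.
#'
#' @param curve_n,curve_prev [utility_curve()]s (or plain functions on
#'   `[0, 1]`) of distribution `n` and `n - 1`.
#' @param n quadrature grid size.
#' @return the SAC.
#' @examples
#' sac(utility_curve("power1", 2), utility_curve("power1", 1))  # -1/3
#' @export
sac <- function(curve_n, curve_prev, n = 10001L) {
  cr_prev <- curvature_ratio(curve_prev, n)
  if (cr_prev <= 0) stop("previous curve has non-positive area", call. = FALSE)
  (curvature_ratio(curve_n, n) - cr_prev) / cr_prev
}

# narrow sub-interval [a, b] of normalized full space + image anchors [c, d]
# (c = U_full(a), d = U_full(b): the narrow utility's 0 and 1 sit on the
# full curve's values at the narrow bounds)
gac_geometry <- function(full_curve, narrow_dist, full_dist) {
  if (narrow_dist$min_ml < full_dist$min_ml - 1e-9 ||
      narrow_dist$max_ml > full_dist$max_ml + 1e-9) {
    stop("narrow distribution must be nested inside the full one",
         call. = FALSE)
  }
  a <- normalize_ce(narrow_dist$min_ml, full_dist)
  b <- normalize_ce(narrow_dist$max_ml, full_dist)
  f <- as_utility_fn(full_curve)
  list(a = a, b = b, c = f(a), d = f(b), f_full = f)
}

#' Rescaled full-distribution template on a narrow range
#'
#' Builds `U_adapt`, the full-distribution utility rescaled to occupy a
#' narrow sub-range: on the narrow interval `[a, b]` of normalized full
#' space, `U_adapt(x) = c + (d - c) * U_full((x - a) / (b - a))` with image
#' anchors `c = U_full(a)`, `d = U_full(b)` (for a lower narrow range the
#' narrow maximum takes the full utility's value there; for an upper range
#' the narrow minimum does).  `U_adapt` is what a fully adapting
#' decision-maker's narrow-range utility would look like from the full
#' distribution's vantage point.
#'
#' @param full_curve [utility_curve()] of the full distribution.
#' @param narrow_dist,full_dist [reward_distribution()]s, narrow nested in
#'   full.
#' @return function of normalized full-space magnitude, with the interval
#'   and image anchors in attributes `a`, `b`, `c`, `d`.
#' @export
build_adapted_template <- function(full_curve, narrow_dist, full_dist) {
  geo <- gac_geometry(full_curve, narrow_dist, full_dist)
  f <- function(x) geo$c + (geo$d - geo$c) *
    geo$f_full((x - geo$a) / (geo$b - geo$a))
  attributes(f) <- c(attributes(f), geo[c("a", "b", "c", "d")])
  f
}

#' Narrow-range curve equal to a segment of the full curve
#'
#' The no-adaptation construction: the narrow-distribution utility that
#' coincides with the full curve restricted to the narrow range, expressed
#' on the narrow normalized domain.  Useful as the exact GAC = 0 control.
#'
#' @inheritParams build_adapted_template
#' @return function of normalized narrow-space magnitude in `[0, 1]`.
#' @export
segment_curve <- function(full_curve, narrow_dist, full_dist) {
  geo <- gac_geometry(full_curve, narrow_dist, full_dist)
  function(t) (geo$f_full(geo$a + t * (geo$b - geo$a)) - geo$c) /
    (geo$d - geo$c)
}

#' General adaptation coefficient (GAC)
#'
#' Positions a narrow-distribution utility between two anchors derived from
#' the full-distribution utility: the full curve's own segment over the
#' narrow range (no adaptation, GAC 0) and the fully rescaled template
#' `U_adapt` (full adaptation, GAC 1):
#' `GAC = (int U_partial - int U_full) / (int U_adapt - int U_full)`,
#' all integrals over the narrow sub-interval of normalized full space.
#' `U_partial` is the narrow curve mapped into full space with the same
#' domain/image convention as `U_adapt`.  Values strictly between 0 and 1
#' indicate partial adaptation.
#'
#' A linear full curve makes the template identical to its own segment
#' (denominator 0); the GAC is then undefined and an error of class
#' `utiladapt_undefined_gac` is signalled.
#'
#' @param narrow_curve the narrow distribution's [utility_curve()] (or a
#'   function on the normalized narrow domain).
#' @param full_curve the full distribution's [utility_curve()].
#' @param narrow_dist,full_dist [reward_distribution()]s, narrow nested in
#'   full.
#' @param n quadrature grid size on the sub-interval.
#' @return the GAC.
#' @export
gac <- function(narrow_curve, full_curve, narrow_dist, full_dist,
                n = 10001L) {
  geo <- gac_geometry(full_curve, narrow_dist, full_dist)
  f_narrow <- as_utility_fn(narrow_curve)
  x <- seq(geo$a, geo$b, length.out = n)
  t <- (x - geo$a) / (geo$b - geo$a)
  trap <- function(u) sum((u[-1] + u[-n]) / 2) * (geo$b - geo$a) / (n - 1)
  int_full <- trap(geo$f_full(x))
  int_adapt <- trap(geo$c + (geo$d - geo$c) * geo$f_full(t))
  int_partial <- trap(geo$c + (geo$d - geo$c) * f_narrow(t))
  denom <- int_adapt - int_full
  if (abs(denom) < 1e-9) {
    stop(structure(class = c("utiladapt_undefined_gac", "error", "condition"),
                   list(message = paste(
                     "GAC undefined: the full curve is self-similar on the",
                     "narrow range (template equals segment)"),
                     call = sys.call())))
  }
  (int_partial - int_full) / denom
}

#' Monte-Carlo null for the adaptation coefficients
#'
#' Quantifies what SAC/GAC values the estimation machinery itself produces
#' when the ground truth is known.  For each replicate, an agent carrying
#' the supplied full-distribution utility (anchored per `adaptation_mode`:
#' `"none"` reproduces the no-adaptation null, `"full"` the full-adaptation
#' control) re-chooses on fixed per-day trial templates; each day is refit
#' with the discrete choice model, daily parameter medians give each
#' distribution's curve, and the GAC of every narrow distribution against
#' the full curve (plus consecutive-pair SACs) is recorded.
#'
#' @param full_curve the full-distribution [utility_curve()] used as ground
#'   truth.
#' @param templates trial data frame of per-day option sequences for the
#'   narrow distributions (choices, if present, are ignored and
#'   re-simulated).
#' @param distributions named list of [reward_distribution()] objects
#'   covering every label in `templates`.
#' @param full_dist the full [reward_distribution()].
#' @param n_reps replicates.
#' @param seed master seed; replicate r re-seeds deterministically.
#' @param lambda,theta choice parameters of the simulated agent.
#' @param adaptation_mode `"none"` (null) or `"full"` (control).
#' @param fit_family family refit to each simulated day.
#' @param n_starts optimizer starts per daily refit.
#' @return data frame with one row per (replicate, narrow distribution):
#'   `rep`, `distribution`, `gac`, plus an attribute `sac` data frame of
#'   consecutive-pair SACs and `failure_rate` of daily refits.
#' @export
monte_carlo_no_adaptation <- function(full_curve, templates, distributions,
                                      full_dist, n_reps = 1000, seed = 1L,
                                      lambda = 10, theta = 0,
                                      adaptation_mode = c("none", "full"),
                                      fit_family = "prelec2", n_starts = 3) {
  adaptation_mode <- match.arg(adaptation_mode)
  labels <- unique(templates$distribution)
  days <- split(templates,
                list(templates$distribution, templates$day_index),
                drop = TRUE)
  rows <- list()
  sac_rows <- list()
  n_fail <- 0L; n_fit <- 0L
  for (r in seq_len(n_reps)) {
    agent <- agent_config(full_curve, lambda = lambda, theta = theta,
                          adaptation_mode = adaptation_mode,
                          reference = full_dist,
                          seed = session_seed(seed, r, salt = 3L))
    set.seed(agent$seed)
    fits_by_dist <- stats::setNames(
      replicate(length(labels), list(), simplify = FALSE), labels)
    for (day in days) {
      d <- distributions[[day$distribution[1]]]
      sim <- day
      anchors <- effective_anchors(agent, d)
      mats <- trial_matrices(sim, d)
      # utilities under the *agent's* anchors, not the session's
      u_of <- function(side) {
        ml1 <- to_ml(side$m1, d); ml2 <- to_ml(side$m2, d)
        side$p1 * agent_utility_of_ml(agent, ml1, anchors) +
          side$p2 * agent_utility_of_ml(agent, ml2, anchors)
      }
      p_left <- stats::plogis(lambda * (u_of(mats$left) - u_of(mats$right)) +
                                theta)
      sim$chosen <- ifelse(stats::runif(nrow(sim)) < p_left, "left", "right")
      n_fit <- n_fit + 1L
      fit <- tryCatch(fit_dcm(sim, fit_family, d, n_starts = n_starts),
                      error = function(e) NULL)
      if (is.null(fit)) { n_fail <- n_fail + 1L; next }
      fits_by_dist[[d$label]] <- c(fits_by_dist[[d$label]], list(fit))
    }
    med <- lapply(fits_by_dist, function(fl)
      if (length(fl)) median_curve(fl) else NULL)
    for (lab in labels) {
      if (is.null(med[[lab]])) next
      g <- tryCatch(gac(med[[lab]], full_curve, distributions[[lab]],
                        full_dist),
                    error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(rep = r, distribution = lab,
                                             gac = g)
    }
    present <- labels[!vapply(med, is.null, logical(1))]
    if (length(present) > 1) {
      for (i in seq_len(length(present) - 1)) {
        sac_rows[[length(sac_rows) + 1]] <- data.frame(
          rep = r, from = present[i], to = present[i + 1],
          sac = sac(med[[present[i + 1]]], med[[present[i]]]))
      }
    }
  }
  if (n_fail > 0.2 * n_fit) {
    warning(sprintf("daily refits failed in %d/%d cases", n_fail, n_fit))
  }
  out <- do.call(rbind, rows)
  attr(out, "sac") <- if (length(sac_rows)) do.call(rbind, sac_rows) else NULL
  attr(out, "failure_rate") <- n_fail / max(n_fit, 1L)
  out
}

#' Summarize utility adaptation across reward distributions
#'
#' Collects, per distribution, the parameter-wise median curve with its
#' inflection (in ml) and curvature ratio; the sequential adaptation
#' coefficient between consecutive distributions; the general adaptation
#' coefficient of every narrow distribution against the full one (when a
#' full distribution is present); and full-adaptation inflection
#' predictions rescaled between consecutive distributions with clip flags.
#'
#' @param fits_by_dist named list (in experienced order) of `dcm_fit` lists
#'   per distribution.
#' @param distributions named list of [reward_distribution()] objects.
#' @param full_label label of the full distribution, or `NULL` to skip GACs.
#' @return list of class `adaptation_report` with elements `curves`,
#'   `metrics` (data frame), `sac` (data frame), `gac` (data frame),
#'   `predicted_inflections` (data frame).
#' @export
adaptation_report <- function(fits_by_dist, distributions,
                              full_label = "full") {
  labels <- names(fits_by_dist)
  curves <- lapply(fits_by_dist, median_curve)
  metrics <- do.call(rbind, lapply(labels, function(lab) {
    sm <- shape_metrics(curves[[lab]], distributions[[lab]])
    data.frame(distribution = lab, inflection_ml = sm$inflection_ml,
               curvature_ratio = sm$curvature_ratio,
               n_days = length(fits_by_dist[[lab]]),
               stringsAsFactors = FALSE)
  }))
  sac_df <- NULL
  pred <- NULL
  if (length(labels) > 1) {
    sac_df <- do.call(rbind, lapply(seq_len(length(labels) - 1), function(i) {
      data.frame(from = labels[i], to = labels[i + 1],
                 sac = sac(curves[[labels[i + 1]]], curves[[labels[i]]]),
                 stringsAsFactors = FALSE)
    }))
    pred <- do.call(rbind, lapply(seq_len(length(labels) - 1), function(i) {
      infl <- metrics$inflection_ml[metrics$distribution == labels[i]]
      if (is.na(infl)) return(NULL)
      rs <- rescale_inflection(infl, distributions[[labels[i]]],
                               distributions[[labels[i + 1]]])
      data.frame(from = labels[i], to = labels[i + 1],
                 predicted_inflection_ml = rs$value_ml, clipped = rs$clipped,
                 stringsAsFactors = FALSE)
    }))
  }
  gac_df <- NULL
  if (!is.null(full_label) && full_label %in% labels) {
    narrow <- setdiff(labels, full_label)
    gac_df <- do.call(rbind, lapply(narrow, function(lab) {
      g <- tryCatch(gac(curves[[lab]], curves[[full_label]],
                        distributions[[lab]], distributions[[full_label]]),
                    utiladapt_undefined_gac = function(e) NA_real_,
                    error = function(e) NA_real_)
      data.frame(distribution = lab, gac = g, undefined = is.na(g),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(curves = curves, metrics = metrics, sac = sac_df,
                 gac = gac_df, predicted_inflections = pred),
            class = "adaptation_report")
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat("<adaptation_report>\n")
  print(x$metrics)
  if (!is.null(x$sac)) { cat("SAC:\n"); print(x$sac) }
  if (!is.null(x$gac)) { cat("GAC:\n"); print(x$gac) }
  invisible(x)
}
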