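#' Design the out-of-sample equivariant validation gambles
#'
#' Four equiprobable two-outcome gambles per distribution, each spreading
#' over 30% of the reward range and centered at 25, 45, 65 and 85% of the
#' range, so relative spreads and positions are equivalent across
#' distributions (0.15 ml spread in a 0.5 ml narrow range, 0.30 ml in a
#' 1.0 ml full range).  All outcomes must stay inside the distribution;
#' infeasible custom centers are refused rather than clipped.
#'
#' @param distribution a [reward_distribution()].
#' @param centers gamble centers as fractions of the range.
#' @param spread_frac outcome spread as a fraction of the range.
#' @return data frame with `center_frac`, `m1`, `m2`, `spread_ml`, `ev_ml`.
#' @examples
#' design_gambles(reward_distribution("full"))
#' @export
design_gambles <- function(distribution, centers = c(0.25, 0.45, 0.65, 0.85),
                           spread_frac = 0.30) {
  stopifnot(is_reward_distribution(distribution))
  r <- dist_range(distribution)
  spread <- spread_frac * r
  center_ml <- distribution$min_ml + centers * r
  m1 <- center_ml - spread / 2
  m2 <- center_ml + spread / 2
  if (any(m1 < distribution$min_ml - 1e-9) ||
      any(m2 > distribution$max_ml + 1e-9)) {
    stop("gamble outcomes would leave the distribution; choose feasible ",
         "centers/spread", call. = FALSE)
  }
  data.frame(center_frac = centers, m1 = pmax(m1, distribution$min_ml),
             m2 = pmin(m2, distribution$max_ml), spread_ml = spread,
             ev_ml = center_ml)
}

#' Risk attitude implied by a certainty equivalent
#'
#' The signed difference `CE - EV` between a gamble's certainty equivalent
#' and its expected value: positive means the decision-maker values the
#' gamble above its actuarial worth (risk-seeking), negative risk aversion.
#'
#' @param ce_ml measured certainty equivalent in ml.
#' @param gamble the [gamble()] the CE belongs to.
#' @return `ce_ml - EV` in ml.
#' @export
risk_attitude <- function(ce_ml, gamble) {
  stopifnot(inherits(gamble, "reward_option"), !gamble$is_safe)
  ce_ml - option_ev(gamble)
}

#' Measure validation-gamble certainty equivalents from trials
#'
#' Fits the psychometric function to each validation gamble's safe-ladder
#' choices and returns one row per gamble with its CE and risk attitude.
#' Degenerate fits are dropped.
#'
#' @param trials validation-sequence trials (tag `"validation"` rows are
#'   used; other rows are ignored).
#' @param distribution the session's [reward_distribution()].
#' @return data frame with `m1`, `m2`, `ev_ml`, `ce_ml`,
#'   `risk_attitude_ml`.
#' @export
measure_validation_ces <- function(trials, distribution) {
  sub <- trials[trials$sequence_tag == "validation", , drop = FALSE]
  if (nrow(sub) == 0) stop("no validation trials found", call. = FALSE)
  left_safe <- is.na(sub$left_m2)
  g_m1 <- ifelse(left_safe, sub$right_m1, sub$left_m1)
  g_m2 <- ifelse(left_safe, sub$right_m2, sub$left_m2)
  key <- paste(round(g_m1, 9), round(g_m2, 9))
  rows <- lapply(unique(key), function(kk) {
    i <- which(key == kk)[1]
    g <- gamble(g_m1[i], g_m2[i])
    fit <- tryCatch(
      fit_psychometric(choice_ratios(sub[key == kk, , drop = FALSE], g)),
      error = function(e) NULL)
    if (is.null(fit) || fit$degenerate) return(NULL)
    data.frame(m1 = g$m[1], m2 = g$m[2], ev_ml = option_ev(g),
               ce_ml = fit$x0, risk_attitude_ml = risk_attitude(fit$x0, g))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no validation gamble yielded a usable fit",
                         call. = FALSE)
  out[order(out$ev_ml), , drop = FALSE]
}

#' Inflection-anchored risk-attitude regression
#'
#' Ordinary least squares of `CE - EV` on `EV - inflection`:
#' `CE - EV = beta0 + beta1 * (EV - inflection)`.  `beta0` is the residual
#' risk attitude at the utility's inflection (the model-predicted point of
#' risk neutrality) and `beta1` mirrors the depth of the utility's
#' curvature -- negative for an S-shaped decision-maker, who is
#' risk-seeking below the inflection and risk-averse above it.
#'
#' @param points data frame with columns `ev_ml` and `ce_ml` (e.g. from
#'   [measure_validation_ces()]).
#' @param inflection_ml the utility curve's inflection in ml.
#' @return object of class `risk_regression`: `beta0`, `beta1`,
#'   `r_squared`, `n_points`, and the underlying [stats::lm] fit.
#' @export
fit_risk_regression <- function(points, inflection_ml) {
  stopifnot(all(c("ev_ml", "ce_ml") %in% names(points)))
  if (nrow(points) < 3 || length(unique(points$ev_ml)) < 3) {
    stop("need at least 3 points with distinct expected values",
         call. = FALSE)
  }
  df <- data.frame(y = points$ce_ml - points$ev_ml,
                   x = points$ev_ml - inflection_ml)
  if (stats::sd(df$x) < 1e-12) stop("expected values are collinear",
                                    call. = FALSE)
  fit <- stats::lm(y ~ x, data = df)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = nrow(points),
                 inflection_ml = inflection_ml,
                 model = fit),
            class = "risk_regression")
}

#' @export
print.risk_regression <- function(x, ...) {
  cat(sprintf(
    "<risk_regression beta0 = %.4f ml, beta1 = %.4f, R^2 = %.3f, n = %d>\n",
    x$beta0, x$beta1, x$r_squared, x$n_points))
  invisible(x)
}
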