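#' Aggregate choice ratios for one gamble
#'
#' Collapses the trials pairing a given gamble against varying safe rewards
#' into one row per distinct safe magnitude: the proportion of trials on
#' which the safe option was chosen, and the trial count.
#'
#' @param trials trial data frame; each row must pair the target gamble
#'   against a safe option (on either side).
#' @param gamble the [gamble()] to aggregate for; if `NULL` the trials must
#'   contain exactly one distinct gamble.
#' @return data frame with columns `safe_ml`, `proportion_safe`, `n`.
#' @export
choice_ratios <- function(trials, gamble = NULL) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trials supplied", call. = FALSE)
  }
  left_safe <- is.na(trials$left_m2)
  right_safe <- is.na(trials$right_m2)
  if (!all(xor(left_safe, right_safe))) {
    stop("each trial must pair exactly one safe option against a gamble",
         call. = FALSE)
  }
  g_m1 <- ifelse(left_safe, trials$right_m1, trials$left_m1)
  g_m2 <- ifelse(left_safe, trials$right_m2, trials$left_m2)
  if (!is.null(gamble)) {
    stopifnot(inherits(gamble, "reward_option"), !gamble$is_safe)
    hit <- abs(g_m1 - gamble$m[1]) < 1e-9 & abs(g_m2 - gamble$m[2]) < 1e-9
    if (!any(hit)) stop("no trials found for the given gamble", call. = FALSE)
    trials <- trials[hit, , drop = FALSE]
    left_safe <- left_safe[hit]
  } else {
    key <- paste(round(g_m1, 9), round(g_m2, 9))
    if (length(unique(key)) > 1) {
      stop("trials contain several gambles; pass `gamble` explicitly",
           call. = FALSE)
    }
  }
  safe_ml <- ifelse(left_safe, trials$left_m1, trials$right_m1)
  chose_safe <- (trials$chosen == "left") == left_safe
  agg <- stats::aggregate(chose_safe, by = list(safe_ml = safe_ml),
                          FUN = function(z) c(mean(z), length(z)))
  out <- data.frame(safe_ml = agg$safe_ml,
                    proportion_safe = agg$x[, 1],
                    n = as.integer(agg$x[, 2]))
  out[order(out$safe_ml), , drop = FALSE]
}

#' Fit the logistic psychometric function to choice ratios
#'
#' Fits `P(choose safe) = 1 / (1 + exp(-(safe_ml - x0) / sigma))` to the
#' per-magnitude safe-choice proportions.  The inflection `x0` is the safe
#' magnitude of choice indifference -- the gamble's certainty equivalent --
#' and `sigma` is the function's temperature in ml.
#'
#' The default objective is binomial maximum likelihood on the per-safe
#' counts (a logit GLM: Eq. reparametrized as intercept `-x0/sigma`, slope
#' `1/sigma`), which weights magnitudes by their trial counts; `method =
#' "ls"` minimizes count-weighted squared error on the ratios instead.
#' Data must contain at least `min_levels` distinct safe magnitudes each
#' tested at least `min_repeats` times.  A non-increasing or flat response
#' (slope <= 0) or a temperature above 10x the tested safe range marks the
#' fit degenerate; degenerate fits yield no certainty equivalent.
#'
#' @param ratios data frame from [choice_ratios()].
#' @param method `"ml"` (binomial likelihood, default) or `"ls"`.
#' @param min_levels,min_repeats inclusion filter on the design.
#' @return object of class `psychometric_fit`: `x0`, `sigma`, `n_points`,
#'   `deviance`, `degenerate`, `converged`, `method`.
#' @export
fit_psychometric <- function(ratios, method = c("ml", "ls"),
                             min_levels = 3, min_repeats = 4) {
  method <- match.arg(method)
  stopifnot(all(c("safe_ml", "proportion_safe", "n") %in% names(ratios)))
  qualified <- sum(ratios$n >= min_repeats)
  if (nrow(ratios) < min_levels || qualified < min_levels) {
    stop(sprintf(
      "insufficient data: need >= %d safe magnitudes repeated >= %d times",
      min_levels, min_repeats), call. = FALSE)
  }
  rng <- diff(range(ratios$safe_ml))
  if (method == "ml") {
    k <- ratios$proportion_safe * ratios$n
    fit <- suppressWarnings(stats::glm(
      cbind(k, ratios$n - k) ~ safe_ml, family = stats::binomial("logit"),
      data = ratios))
    b <- stats::coef(fit)
    slope <- unname(b[2]); intercept <- unname(b[1])
    x0 <- -intercept / slope
    sigma <- 1 / slope
    dev <- stats::deviance(fit)
    converged <- fit$converged
  } else {
    # least-squares on the ratios, weighted by trial count; x0 initialized at
    # the empirical 50% crossing, sigma at a quarter of the safe range
    crossing <- stats::approx(ratios$proportion_safe, ratios$safe_ml,
                              xout = 0.5, ties = "ordered")$y
    if (is.na(crossing)) crossing <- stats::median(ratios$safe_ml)
    obj <- function(par) {
      p <- stats::plogis((ratios$safe_ml - par[1]) / exp(par[2]))
      sum(ratios$n * (ratios$proportion_safe - p)^2)
    }
    res <- stats::optim(c(crossing, log(rng / 4)), obj, method = "BFGS")
    x0 <- res$par[1]; sigma <- exp(res$par[2])
    dev <- res$value
    converged <- res$convergence == 0
  }
  degenerate <- !is.finite(x0) || !is.finite(sigma) || sigma <= 0 ||
    sigma > 10 * rng
  structure(list(x0 = x0, sigma = sigma, n_points = nrow(ratios),
                 deviance = dev, degenerate = degenerate,
                 converged = converged, method = method),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit x0 = %.4f ml, sigma = %.4f ml (%s%s)>\n",
              x$x0, x$sigma, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# the utility level each fractile step elicits, in presentation order of the
# gambles' expected values (lower gamble first)
fractile_levels <- list(fractile_step1 = 0.5,
                        fractile_step2 = c(0.25, 0.75),
                        fractile_step3 = c(0.125, 0.875))

#' Run the fractile bookkeeping on one session's trials
#'
#' Walks the three-step fractile design: the step-1 certainty equivalent
#' (CE) of the min/max equiprobable gamble is assigned utility 0.5; step-2
#' CEs (gambles between the minimum and the step-1 CE, and between the
#' step-1 CE and the maximum) get 0.25 and 0.75; step-3 CEs get 0.125 and
#' 0.875.  Each CE is the fitted psychometric inflection for its gamble.
#'
#' Quality filters: psychometric fits need at least `min_levels` distinct
#' safe magnitudes repeated `min_repeats` times; degenerate fits and CEs
#' falling more than one ladder step outside the tested safe range are
#' rejected; sessions yielding fewer than three utility levels are
#' discarded (empty result flagged with `attr(, "discarded")`).
#'
#' @param trials one session's trials, tagged `fractile_step1..3` in
#'   `sequence_tag`.
#' @param distribution the session's [reward_distribution()].
#' @param step_ml safe-ladder increment used for the out-of-ladder check.
#' @param min_levels,min_repeats psychometric inclusion filter.
#' @param method psychometric objective, see [fit_psychometric()].
#' @return data frame of CE points: `session_id`, `day_index`,
#'   `distribution`, `step`, `utility_level`, `ce_ml`, `ce_norm`, `x0`,
#'   `sigma`, `n_points`.
#' @export
run_fractile <- function(trials, distribution, step_ml = 0.05,
                         min_levels = 3, min_repeats = 4,
                         method = c("ml", "ls")) {
  method <- match.arg(method)
  stopifnot(is_reward_distribution(distribution))
  steps <- intersect(names(fractile_levels), unique(trials$sequence_tag))
  if (!"fractile_step1" %in% steps) {
    stop("sequence is missing step-1 trials; fractile chaining is invalid",
         call. = FALSE)
  }
  rows <- list()
  for (step in steps) {
    sub <- trials[trials$sequence_tag == step, , drop = FALSE]
    left_safe <- is.na(sub$left_m2)
    g_m1 <- ifelse(left_safe, sub$right_m1, sub$left_m1)
    g_m2 <- ifelse(left_safe, sub$right_m2, sub$left_m2)
    key <- paste(round(g_m1, 9), round(g_m2, 9))
    gkeys <- unique(key)
    # order gambles by expected value so utility levels line up low -> high
    ev <- vapply(gkeys, function(kk) {
      i <- which(key == kk)[1]
      (g_m1[i] + g_m2[i]) / 2
    }, numeric(1))
    gkeys <- gkeys[order(ev)]
    levels_here <- fractile_levels[[step]]
    if (length(gkeys) > length(levels_here)) {
      stop("more gambles than utility levels in ", step, call. = FALSE)
    }
    for (gi in seq_along(gkeys)) {
      i <- which(key == gkeys[gi])[1]
      g <- gamble(min(g_m1[i], g_m2[i]), max(g_m1[i], g_m2[i]))
      ratios <- choice_ratios(sub[key == gkeys[gi], , drop = FALSE], g)
      fit <- tryCatch(
        fit_psychometric(ratios, method = method, min_levels = min_levels,
                         min_repeats = min_repeats),
        error = function(e) NULL)
      if (is.null(fit) || fit$degenerate) next
      ladder <- range(ratios$safe_ml)
      if (fit$x0 < ladder[1] - step_ml || fit$x0 > ladder[2] + step_ml) next
      ce <- min(max(fit$x0, distribution$min_ml), distribution$max_ml)
      # which level: for two gambles the lower-EV gamble carries the lower
      # level; with a single step-2/3 gamble use its EV side
      lev <- if (length(gkeys) == length(levels_here)) levels_here[gi]
             else levels_here[if (mean(g$m) <=
               (distribution$min_ml + distribution$max_ml) / 2) 1
               else length(levels_here)]
      rows[[length(rows) + 1]] <- data.frame(
        session_id = sub$session_id[1], day_index = sub$day_index[1],
        distribution = distribution$label,
        step = as.integer(sub("fractile_step", "", step)),
        utility_level = lev, ce_ml = ce,
        ce_norm = normalize_ce(ce, distribution),
        x0 = fit$x0, sigma = fit$sigma, n_points = fit$n_points,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(session_id = character(0), day_index = integer(0),
               distribution = character(0), step = integer(0),
               utility_level = numeric(0), ce_ml = numeric(0),
               ce_norm = numeric(0), x0 = numeric(0), sigma = numeric(0),
               n_points = integer(0))
  if (nrow(out) < 3) {
    attr(out, "discarded") <- TRUE
    out <- out[0, , drop = FALSE]
  } else {
    attr(out, "discarded") <- FALSE
  }
  out
}
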