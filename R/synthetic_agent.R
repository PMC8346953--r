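#' Configure a synthetic choice agent
#'
#' A simulated decision-maker whose choices follow the logit rule on
#' expected-utility differences: `P(left) = plogis(lambda * (EU_L - EU_R) +
#' theta)`.  The agent owns a ground-truth [utility_curve()] defined on the
#' normalized domain, and an adaptation mode deciding which reward range
#' anchors that curve:
#'
#' * `"full"` -- the utility re-anchors to each session's distribution
#'   (fully adapting preferences);
#' * `"none"` -- the utility stays anchored to a fixed `reference`
#'   distribution regardless of the session's range (a narrow session then
#'   only exercises a segment of the curve);
#' * `"partial"` -- the effective anchors interpolate between the current
#'   and reference ranges with weight `adapt_weight` on the current one.
#'
#' @param utility ground-truth [utility_curve()].
#' @param lambda logit temperature (>= 0).
#' @param theta additive side bias (positive favors the left option).
#' @param adaptation_mode `"full"`, `"none"` or `"partial"`.
#' @param reference [reward_distribution()] the utility is anchored to for
#'   the `"none"`/`"partial"` modes.
#' @param adapt_weight weight on the current distribution for `"partial"`.
#' @param seed integer master seed; per-session streams are derived from it
#'   deterministically (see [generate_fractile_session()]).
#' @return object of class `agent_config`.
#' @export
agent_config <- function(utility, lambda, theta = 0,
                         adaptation_mode = c("full", "none", "partial"),
                         reference = NULL, adapt_weight = NULL, seed = 1L) {
  adaptation_mode <- match.arg(adaptation_mode)
  stopifnot(inherits(utility, "utility_curve"), lambda >= 0,
            is.finite(theta))
  if (adaptation_mode %in% c("none", "partial") && is.null(reference)) {
    stop("adaptation_mode '", adaptation_mode,
         "' needs a reference distribution", call. = FALSE)
  }
  if (adaptation_mode == "partial") {
    stopifnot(is.numeric(adapt_weight), adapt_weight >= 0, adapt_weight <= 1)
  }
  structure(list(utility = utility, lambda = lambda, theta = theta,
                 adaptation_mode = adaptation_mode, reference = reference,
                 adapt_weight = adapt_weight, seed = as.integer(seed)),
            class = "agent_config")
}

# anchors (in ml) the agent's utility is normalized against in a session
effective_anchors <- function(agent, distribution) {
  switch(agent$adaptation_mode,
    full = c(distribution$min_ml, distribution$max_ml),
    none = c(agent$reference$min_ml, agent$reference$max_ml),
    partial = {
      w <- agent$adapt_weight
      c(w * distribution$min_ml + (1 - w) * agent$reference$min_ml,
        w * distribution$max_ml + (1 - w) * agent$reference$max_ml)
    })
}

agent_utility_of_ml <- function(agent, m, anchors) {
  v <- (m - anchors[1]) / (anchors[2] - anchors[1])
  eval_utility(agent$utility, pmin(pmax(v, 0), 1))
}

#' Probability that an agent chooses the left option
#'
#' Direct evaluation of the logit choice rule on the expected-utility
#' difference between the two options, under the agent's effective
#' normalization anchors for the session's distribution.
#'
#' @param agent an [agent_config()].
#' @param left,right [gamble()] / [safe()] options.
#' @param distribution the session's [reward_distribution()].
#' @return probability in `(0, 1)`.
#' @export
choice_probability <- function(agent, left, right, distribution) {
  anchors <- effective_anchors(agent, distribution)
  eu <- function(opt) sum(opt$p * agent_utility_of_ml(agent, opt$m, anchors))
  stats::plogis(agent$lambda * (eu(left) - eu(right)) + agent$theta)
}

#' Simulate one choice
#'
#' A Bernoulli draw from [choice_probability()] using the current RNG
#' stream; reproducible under `set.seed()`.
#'
#' @inheritParams choice_probability
#' @return `"left"` or `"right"`.
#' @export
simulate_choice <- function(agent, left, right, distribution) {
  p <- choice_probability(agent, left, right, distribution)
  if (stats::runif(1) < p) "left" else "right"
}

#' Build a multi-day schedule of reward distributions
#'
#' Distributions are experienced in consecutive-day blocks; this expands a
#' block list into the ordered day-by-day schedule.
#'
#' @param blocks list of `list(distribution =, n_days =)` entries (the
#'   distribution may be a preset label or a [reward_distribution()]).
#' @return data frame with `day_index` (0-based) and `distribution` label,
#'   plus the distribution objects in `attr(, "distributions")`.
#' @examples
#' build_schedule(list(list(distribution = "low", n_days = 2),
#'                     list(distribution = "high", n_days = 2)))
#' @export
build_schedule <- function(blocks) {
  if (length(blocks) == 0) stop("empty block list", call. = FALSE)
  dists <- list()
  rows <- list()
  day <- 0L
  for (b in blocks) {
    d <- if (is_reward_distribution(b$distribution)) b$distribution
         else reward_distribution(b$distribution)
    n_days <- as.integer(b$n_days)
    if (is.na(n_days) || n_days < 1) stop("n_days must be >= 1", call. = FALSE)
    dists[[d$label]] <- d
    rows[[length(rows) + 1]] <- data.frame(
      day_index = day + seq_len(n_days) - 1L,
      distribution = d$label, stringsAsFactors = FALSE)
    day <- day + n_days
  }
  out <- do.call(rbind, rows)
  attr(out, "distributions") <- dists
  out
}

# deterministic per-session RNG stream derived from the master seed
session_seed <- function(seed, day_index, salt = 0L) {
  (as.integer(seed) + 131071L * (as.integer(day_index) + 1L) +
     7919L * as.integer(salt)) %% 2147483647L
}

safe_ladder <- function(distribution, step_ml = 0.05) {
  k <- floor((dist_range(distribution)) / step_ml + 1e-9)
  distribution$min_ml + step_ml * (0:k)
}

# simulate one interwoven block: each gamble in `gambles` is paired with the
# whole safe ladder, each pairing repeated `repeats` times, presentation
# order and screen sides randomized
simulate_block <- function(agent, gambles, distribution, ladder, repeats,
                           tag, session_id, day_index) {
  anchors <- effective_anchors(agent, distribution)
  recs <- list()
  for (g in gambles) {
    s <- rep(ladder, each = repeats)
    eu_g <- sum(g$p * agent_utility_of_ml(agent, g$m, anchors))
    eu_s <- agent_utility_of_ml(agent, s, anchors)
    g_left <- stats::runif(length(s)) < 0.5
    eu_l <- ifelse(g_left, eu_g, eu_s)
    eu_r <- ifelse(g_left, eu_s, eu_g)
    p_left <- stats::plogis(agent$lambda * (eu_l - eu_r) + agent$theta)
    chosen <- ifelse(stats::runif(length(s)) < p_left, "left", "right")
    recs[[length(recs) + 1]] <- data.frame(
      session_id = session_id, day_index = as.integer(day_index),
      distribution = distribution$label,
      left_m1 = ifelse(g_left, g$m[1], s),
      left_p1 = ifelse(g_left, g$p[1], 1),
      left_m2 = ifelse(g_left, g$m[2], NA_real_),
      left_p2 = ifelse(g_left, g$p[2], NA_real_),
      right_m1 = ifelse(g_left, s, g$m[1]),
      right_p1 = ifelse(g_left, 1, g$p[1]),
      right_m2 = ifelse(g_left, NA_real_, g$m[2]),
      right_p2 = ifelse(g_left, NA_real_, g$p[2]),
      chosen = chosen, sequence_tag = tag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  out[sample(nrow(out)), , drop = FALSE]
}

# certainty equivalent the simulated choices imply for one gamble, read from
# the fitted psychometric inflection (continuous, not snapped to the ladder)
simulated_ce <- function(block, g, step_ml, distribution) {
  ratios <- choice_ratios(block, g)
  fit <- tryCatch(fit_psychometric(ratios), error = function(e) NULL)
  if (is.null(fit) || fit$degenerate) return(NULL)
  ce <- fit$x0
  if (ce < distribution$min_ml + step_ml / 2 ||
      ce > distribution$max_ml - step_ml / 2) {
    return(NULL)  # too close to a bound: the chained gamble degenerates
  }
  ce
}

#' Generate one fractile elicitation session
#'
#' Simulates the three-step fractile design for one day: step 1 pairs the
#' distribution's min/max equiprobable gamble against a ladder of safe
#' rewards in `step_ml` increments; the step-1 certainty equivalent (CE,
#' read from the fitted psychometric inflection of the simulated choices)
#' defines the two step-2 gambles (min--CE and CE--max), whose trials are
#' interwoven in one sequence; step-3 gambles chain from the step-2 CEs the
#' same way.  All magnitudes stay inside the distribution.
#'
#' If a simulated CE lands within half a ladder step of a distribution
#' bound the chain cannot continue reliably; the session is returned with
#' the steps generated so far and `attr(, "flagged") = TRUE`.
#'
#' The per-session RNG stream is derived from the agent's master seed as
#' `(seed + 131071 * (day_index + 1)) mod (2^31 - 1)`, so any single day is
#' reproducible in isolation.
#'
#' @param agent an [agent_config()].
#' @param distribution the session's [reward_distribution()].
#' @param day_index 0-based day; also salts the RNG stream.
#' @param session_id identifier written into the trials.
#' @param step_ml safe-ladder increment in ml.
#' @param repeats presentations of each gamble/safe pairing.
#' @return trial data frame; attributes `ce` (named list of simulated CEs
#'   by utility level) and `flagged`.
#' @export
generate_fractile_session <- function(agent, distribution, day_index = 0L,
                                      session_id = NULL, step_ml = 0.05,
                                      repeats = 4L) {
  stopifnot(is_reward_distribution(distribution), repeats >= 1)
  if (is.null(session_id)) {
    session_id <- sprintf("%s_day%03d", distribution$label, day_index)
  }
  set.seed(session_seed(agent$seed, day_index))
  ladder <- safe_ladder(distribution, step_ml)
  lo <- distribution$min_ml; hi <- distribution$max_ml
  ces <- list()
  flagged <- FALSE

  g1 <- gamble(lo, hi)
  trials <- simulate_block(agent, list(g1), distribution, ladder, repeats,
                           "fractile_step1", session_id, day_index)
  ce50 <- simulated_ce(trials, g1, step_ml, distribution)
  if (is.null(ce50)) {
    attr(trials, "ce") <- ces; attr(trials, "flagged") <- TRUE
    return(trials)
  }
  ces[["0.5"]] <- ce50

  g25 <- gamble(lo, ce50); g75 <- gamble(ce50, hi)
  step2 <- simulate_block(agent, list(g25, g75), distribution, ladder,
                          repeats, "fractile_step2", session_id, day_index)
  trials <- rbind(trials, step2)
  ce25 <- simulated_ce(step2, g25, step_ml, distribution)
  ce75 <- simulated_ce(step2, g75, step_ml, distribution)
  if (!is.null(ce25)) ces[["0.25"]] <- ce25
  if (!is.null(ce75)) ces[["0.75"]] <- ce75
  if (is.null(ce25) || is.null(ce75)) flagged <- TRUE

  g3 <- list()
  if (!is.null(ce25)) g3 <- c(g3, list(gamble(lo, ce25)))
  if (!is.null(ce75)) g3 <- c(g3, list(gamble(ce75, hi)))
  if (length(g3)) {
    step3 <- simulate_block(agent, g3, distribution, ladder, repeats,
                            "fractile_step3", session_id, day_index)
    trials <- rbind(trials, step3)
    if (!is.null(ce25)) {
      v <- simulated_ce(step3, g3[[1]], step_ml, distribution)
      if (!is.null(v)) ces[["0.125"]] <- v else flagged <- TRUE
    }
    if (!is.null(ce75)) {
      v <- simulated_ce(step3, g3[[length(g3)]], step_ml, distribution)
      if (!is.null(v)) ces[["0.875"]] <- v else flagged <- TRUE
    }
  }
  rownames(trials) <- NULL
  attr(trials, "ce") <- ces
  attr(trials, "flagged") <- flagged
  trials
}

#' Generate one out-of-sample validation session
#'
#' Pairs the four equivariant validation gambles of a distribution (spread
#' 30% of the range, centers at 25/45/65/85% of the range; see
#' [design_gambles()]) against the safe ladder, interwoven in one tagged
#' sequence.
#'
#' @inheritParams generate_fractile_session
#' @return trial data frame tagged `"validation"`.
#' @export
generate_validation_session <- function(agent, distribution, day_index = 0L,
                                        session_id = NULL, step_ml = 0.05,
                                        repeats = 4L) {
  stopifnot(is_reward_distribution(distribution))
  if (is.null(session_id)) {
    session_id <- sprintf("%s_val%03d", distribution$label, day_index)
  }
  set.seed(session_seed(agent$seed, day_index, salt = 1L))
  gs <- design_gambles(distribution)
  gambles <- lapply(seq_len(nrow(gs)),
                    function(i) gamble(gs$m1[i], gs$m2[i]))
  simulate_block(agent, gambles, distribution,
                 safe_ladder(distribution, step_ml), repeats,
                 "validation", session_id, day_index)
}

#' Generate an unstructured recovery schedule
#'
#' Random safe-versus-gamble trials spanning the whole reward range:
#' each trial pairs a uniformly drawn safe magnitude against an
#' equiprobable gamble with two uniformly drawn outcomes.  This schedule
#' spreads magnitudes over the full domain and is used for parameter- and
#' model-recovery studies, where identifiability matters more than fidelity
#' to the fractile presentation order.
#'
#' @inheritParams generate_fractile_session
#' @param n_trials number of trials.
#' @return trial data frame tagged `"random"`.
#' @export
generate_choice_trials <- function(agent, distribution, n_trials,
                                   day_index = 0L, session_id = "recovery") {
  stopifnot(is_reward_distribution(distribution), n_trials >= 1)
  set.seed(session_seed(agent$seed, day_index, salt = 2L))
  anchors <- effective_anchors(agent, distribution)
  lo <- distribution$min_ml; hi <- distribution$max_ml
  s <- stats::runif(n_trials, lo, hi)
  a <- stats::runif(n_trials, lo, hi)
  b <- stats::runif(n_trials, lo, hi)
  g1 <- pmin(a, b); g2 <- pmax(a, b)
  eu_g <- 0.5 * agent_utility_of_ml(agent, g1, anchors) +
          0.5 * agent_utility_of_ml(agent, g2, anchors)
  eu_s <- agent_utility_of_ml(agent, s, anchors)
  g_left <- stats::runif(n_trials) < 0.5
  p_left <- stats::plogis(agent$lambda *
                            (ifelse(g_left, eu_g, eu_s) -
                               ifelse(g_left, eu_s, eu_g)) + agent$theta)
  chosen <- ifelse(stats::runif(n_trials) < p_left, "left", "right")
  data.frame(
    session_id = session_id, day_index = as.integer(day_index),
    distribution = distribution$label,
    left_m1 = ifelse(g_left, g1, s),
    left_p1 = ifelse(g_left, 0.5, 1),
    left_m2 = ifelse(g_left, g2, NA_real_),
    left_p2 = ifelse(g_left, 0.5, NA_real_),
    right_m1 = ifelse(g_left, s, g1),
    right_p1 = ifelse(g_left, 1, 0.5),
    right_m2 = ifelse(g_left, NA_real_, g2),
    right_p2 = ifelse(g_left, NA_real_, 0.5),
    chosen = chosen, sequence_tag = "random", stringsAsFactors = FALSE)
}
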