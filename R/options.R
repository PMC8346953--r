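#' Reward options
#'
#' A reward option is either a safe (riskless) magnitude delivered with
#' probability 1, or an equiprobable two-outcome gamble.  Options are the
#' left/right alternatives of every binary choice trial.
#'
#' @param m1,m2 outcome magnitudes in ml.
#' @param p1 probability of the first outcome (`1 - p1` for the second).
#' @return list with fields `m` (magnitudes), `p` (probabilities) and
#'   `is_safe`.
#' @examples
#' gamble(0, 0.5)       # the min/max equiprobable gamble of a low block
#' safe(0.25)
#' @export
gamble <- function(m1, m2, p1 = 0.5) {
  stopifnot(is.numeric(m1), is.numeric(m2), m1 >= 0, m2 >= 0,
            p1 > 0, p1 < 1)
  structure(list(m = c(m1, m2), p = c(p1, 1 - p1), is_safe = FALSE),
            class = "reward_option")
}

#' @rdname gamble
#' @param m safe magnitude in ml.
#' @export
safe <- function(m) {
  stopifnot(is.numeric(m), m >= 0)
  structure(list(m = m, p = 1, is_safe = TRUE), class = "reward_option")
}

#' @export
print.reward_option <- function(x, ...) {
  if (x$is_safe) {
    cat(sprintf("<safe %.3f ml>\n", x$m))
  } else {
    cat(sprintf("<gamble %.3f/%.3f ml (p = %.2f/%.2f)>\n",
                x$m[1], x$m[2], x$p[1], x$p[2]))
  }
  invisible(x)
}

option_ev <- function(option) sum(option$p * option$m)

# one trial row in the canonical wide layout (safe options leave m2/p2 NA)
option_cols <- function(option, side) {
  out <- list(m1 = option$m[1], p1 = option$p[1],
              m2 = if (option$is_safe) NA_real_ else option$m[2],
              p2 = if (option$is_safe) NA_real_ else option$p[2])
  names(out) <- paste0(side, "_", names(out))
  out
}

make_trial <- function(session_id, day_index, distribution_label,
                       left, right, chosen, sequence_tag) {
  as.data.frame(c(
    list(session_id = session_id, day_index = as.integer(day_index),
         distribution = distribution_label),
    option_cols(left, "left"), option_cols(right, "right"),
    list(chosen = chosen, sequence_tag = sequence_tag)
  ), stringsAsFactors = FALSE)
}

trial_columns <- function() {
  c("session_id", "day_index", "distribution",
    "left_m1", "left_p1", "left_m2", "left_p2",
    "right_m1", "right_p1", "right_m2", "right_p2",
    "chosen", "sequence_tag")
}

# left/right option of one trial row, as a reward_option
row_option <- function(row, side) {
  m1 <- row[[paste0(side, "_m1")]]
  m2 <- row[[paste0(side, "_m2")]]
  if (is.na(m2)) safe(m1) else gamble(m1, m2, row[[paste0(side, "_p1")]])
}
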