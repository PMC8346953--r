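#' Reward distributions
#'
#' A reward distribution is the range of juice magnitudes (in ml) available
#' during a block of sessions.  Its minimum and maximum act as the anchors of
#' all utility normalization: the lowest magnitude carries utility 0 and the
#' highest utility 1, so every curve is compared on the normalized unit
#' square regardless of the absolute rewards on offer.
#'
#' Canonical presets follow the experimental blocks the package emulates:
#' `low` (0--0.5 ml), `high` (0.5--1.0 ml), `full` (0--1.0 ml) and the
#' alternate wide block `full_alt` (0.1--1.3 ml).
#'
#' @param label distribution label; one of the presets above, or any string
#'   when `min_ml`/`max_ml` are supplied explicitly.
#' @param min_ml,max_ml range bounds in ml; defaulted from the preset label.
#' @return an object of class `reward_distribution` with fields `label`,
#'   `min_ml`, `max_ml`.
#' @examples
#' reward_distribution("low")
#' reward_distribution("custom", 0.2, 0.8)
#' @export
reward_distribution <- function(label, min_ml = NULL, max_ml = NULL) {
  presets <- list(
    low      = c(0, 0.5),
    high     = c(0.5, 1.0),
    full     = c(0, 1.0),
    full_alt = c(0.1, 1.3)
  )
  if (is.null(min_ml) || is.null(max_ml)) {
    if (!label %in% names(presets)) {
      stop("unknown distribution preset '", label,
           "'; supply min_ml and max_ml explicitly", call. = FALSE)
    }
    min_ml <- presets[[label]][1]
    max_ml <- presets[[label]][2]
  }
  stopifnot(is.numeric(min_ml), is.numeric(max_ml), length(min_ml) == 1,
            length(max_ml) == 1, is.finite(min_ml), is.finite(max_ml))
  if (min_ml < 0) stop("min_ml must be non-negative", call. = FALSE)
  if (min_ml >= max_ml) stop("min_ml must be strictly below max_ml",
                             call. = FALSE)
  structure(list(label = as.character(label), min_ml = min_ml,
                 max_ml = max_ml),
            class = "reward_distribution")
}

#' @export
print.reward_distribution <- function(x, ...) {
  cat(sprintf("<reward_distribution '%s': %.3f-%.3f ml>\n",
              x$label, x$min_ml, x$max_ml))
  invisible(x)
}

#' @rdname reward_distribution
#' @export
is_reward_distribution <- function(label) {
  inherits(label, "reward_distribution")
}

dist_range <- function(dist) dist$max_ml - dist$min_ml

#' Normalize a magnitude to the unit interval of its distribution
#'
#' Maps a magnitude in ml onto `[0, 1]` relative to the minimum and maximum
#' of the reward distribution it was measured in; the affine map every
#' utility curve and certainty equivalent is defined on.
#'
#' @param ce_ml magnitude(s) in ml (typically a certainty equivalent).
#' @param distribution a [reward_distribution()].
#' @param tol out-of-range tolerance in ml.
#' @return normalized magnitude(s) in `[0, 1]`.
#' @examples
#' normalize_ce(0.25, reward_distribution("low"))   # 0.5
#' normalize_ce(0.46, reward_distribution("full_alt"))
#' @seealso [to_ml()] for the inverse map.
#' @export
normalize_ce <- function(ce_ml, distribution, tol = 1e-9) {
  stopifnot(is_reward_distribution(distribution))
  bad <- ce_ml < distribution$min_ml - tol | ce_ml > distribution$max_ml + tol
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("magnitude %.4f ml outside distribution [%g, %g]",
                 ce_ml[which(bad)[1]], distribution$min_ml,
                 distribution$max_ml), call. = FALSE)
  }
  v <- (ce_ml - distribution$min_ml) / dist_range(distribution)
  pmin(pmax(v, 0), 1)
}

#' Map a normalized value back to ml
#'
#' Inverse of [normalize_ce()]: places a value on `[0, 1]` back on the ml
#' scale of a reward distribution.
#'
#' @param value normalized value(s) in `[0, 1]`.
#' @param distribution a [reward_distribution()].
#' @return magnitude(s) in ml.
#' @examples
#' to_ml(0.3, reward_distribution("full_alt"))  # 0.46
#' @export
to_ml <- function(value, distribution) {
  stopifnot(is_reward_distribution(distribution))
  if (any(value < -1e-9 | value > 1 + 1e-9, na.rm = TRUE)) {
    stop("normalized value outside [0, 1]", call. = FALSE)
  }
  distribution$min_ml + pmin(pmax(value, 0), 1) * dist_range(distribution)
}

#' Rescale an inflection point between reward distributions
#'
#' Under full adaptation a utility curve keeps its shape on the normalized
#' domain, so the relative position of its inflection is preserved when the
#' reward range changes.  This maps an inflection measured in one
#' distribution onto another by preserving its relative position, clipping
#' into the target range when the prediction falls outside it (clipped
#' predictions are flagged rather than dropped).
#'
#' @param inflection_ml inflection in ml, inside `from_dist`.
#' @param from_dist,to_dist [reward_distribution()] objects.
#' @return list with `value_ml` (possibly clipped) and logical `clipped`.
#' @examples
#' full <- reward_distribution("full"); low <- reward_distribution("low")
#' rescale_inflection(0.3, full, low)  # 0.15 ml
#' @export
rescale_inflection <- function(inflection_ml, from_dist, to_dist) {
  stopifnot(is_reward_distribution(from_dist), is_reward_distribution(to_dist))
  # relative position is deliberately not clamped: a fit whose inflection sits
  # beyond the source range still yields a (clipped, flagged) prediction
  rel <- (inflection_ml - from_dist$min_ml) / dist_range(from_dist)
  raw <- to_dist$min_ml + rel * dist_range(to_dist)
  clipped <- raw < to_dist$min_ml || raw > to_dist$max_ml
  list(value_ml = min(max(raw, to_dist$min_ml), to_dist$max_ml),
       clipped = clipped)
}
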