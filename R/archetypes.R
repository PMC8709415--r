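#' Archetypal weekly activity patterns
#'
#' Each archetype is a parametric template for a 168-hour week of mean
#' activity (mg): a non-negative base level, a set of Gaussian bumps in
#' clock time (per weekday group), and a multiplicative weekend modifier.
#' The nine built-in archetypes emulate qualitatively distinct weekly
#' shapes seen in population accelerometer cohorts: commuter double peaks,
#' sustained activity, morning-only bursts, weekend-dominated patterns,
#' and graded low-activity profiles.
#'
#' @param name Archetype label.
#' @param base_level Background hourly level in mg (night-time floor).
#' @param peaks Data frame with columns `days` (list of weekday indices the
#'   bump applies to), `hour` (centre, fractional hours 0-24), `amplitude`
#'   (mg) and `width` (Gaussian sd in hours).
#' @param weekend_modifier Multiplier applied to Saturday/Sunday hours.
#' @return An `archetype_spec` object.
#' @export
archetype_spec <- function(name, base_level, peaks, weekend_modifier = 1) {
  stopifnot(base_level >= 0, weekend_modifier >= 0)
  if (nrow(peaks) > 0) {
    stopifnot(
      all(peaks$amplitude >= 0), all(peaks$width > 0),
      all(peaks$hour >= 0 & peaks$hour < 24)
    )
  }
  structure(
    list(
      name = name, base_level = base_level, peaks = peaks,
      weekend_modifier = weekend_modifier
    ),
    class = "archetype_spec"
  )
}

peak_row <- function(days, hour, amplitude, width) {
  data.frame(
    days = I(list(as.integer(days))), hour = hour,
    amplitude = amplitude, width = width
  )
}

WEEKDAY_IDX <- 1:5
WEEKEND_IDX <- 6:7
ALL_DAYS <- 1:7

#' Names of the nine built-in archetypes
#' @export
archetype_names <- function() {
  c(
    "active_9to5", "active", "morning_movers", "get_up_and_active",
    "live_for_weekend", "moderates", "leisurely_9to5", "sedate", "inactive"
  )
}

builtin_archetype <- function(name) {
  p <- switch(name,
    active_9to5 = list(
      base = 5,
      peaks = rbind(
        peak_row(WEEKDAY_IDX, 8.0, 45, 1.2),   # commute out
        peak_row(WEEKDAY_IDX, 17.5, 40, 1.5),  # commute home
        peak_row(WEEKDAY_IDX, 13.0, 18, 3.0),  # midday plateau
        peak_row(WEEKEND_IDX, 10.0, 35, 2.0),
        peak_row(WEEKEND_IDX, 14.5, 15, 3.5)
      ),
      wk = 1
    ),
    active = list(
      base = 5,
      peaks = rbind(
        peak_row(ALL_DAYS, 8.5, 25, 2.0),
        peak_row(ALL_DAYS, 13.5, 35, 4.5)      # sustained active day
      ),
      wk = 1
    ),
    morning_movers = list(
      base = 4,
      peaks = rbind(
        peak_row(ALL_DAYS, 8.5, 38, 1.8),      # burst, then tails off
        peak_row(ALL_DAYS, 12.5, 8, 3.0)
      ),
      wk = 1
    ),
    get_up_and_active = list(
      base = 4,
      peaks = rbind(
        peak_row(ALL_DAYS, 8.5, 35, 1.8),
        peak_row(ALL_DAYS, 14.0, 20, 4.5)      # moderate plateau after
      ),
      wk = 1
    ),
    live_for_weekend = list(
      base = 4,
      peaks = rbind(
        peak_row(WEEKDAY_IDX, 13.0, 16, 5.0),  # flat weekday plateau
        peak_row(6L, 12.0, 25, 3.5),
        peak_row(7L, 10.0, 40, 2.0)            # Sunday-morning spike
      ),
      wk = 1.3
    ),
    moderates = list(
      base = 4,
      peaks = peak_row(ALL_DAYS, 13.5, 20, 5.0),
      wk = 1
    ),
    leisurely_9to5 = list(
      base = 4,
      peaks = rbind(
        peak_row(WEEKDAY_IDX, 8.0, 22, 1.2),
        peak_row(WEEKDAY_IDX, 17.5, 20, 1.5),
        peak_row(WEEKDAY_IDX, 13.0, 9, 3.0),
        peak_row(WEEKEND_IDX, 13.0, 10, 4.0)   # no weekend spike
      ),
      wk = 1
    ),
    sedate = list(
      base = 3,
      peaks = rbind(
        peak_row(ALL_DAYS, 9.0, 15, 1.5),
        peak_row(ALL_DAYS, 12.0, 8, 3.0)
      ),
      wk = 1
    ),
    inactive = list(
      base = 3,
      peaks = peak_row(ALL_DAYS, 13.0, 6, 6.0),
      wk = 1
    ),
    stop("unknown archetype name: ", name)
  )
  archetype_spec(name, p$base, p$peaks, p$wk)
}

#' Evaluate an archetype as a 168-hour template
#'
#' Deterministically evaluates the parametric weekly shape on the canonical
#' Monday-aligned hour grid (hour 0 = Monday 00:00).  Each Gaussian bump
#' contributes `amplitude * exp(-((h - hour)/width)^2 / 2)` to the hours of
#' the weekdays it applies to; Saturday/Sunday hours are then scaled by the
#' weekend modifier.
#'
#' @param spec An `archetype_spec`, or the name of a built-in archetype.
#' @return Numeric vector of length 168, non-negative, in mg.
#' @export
make_archetype_template <- function(spec) {
  if (is.character(spec)) spec <- builtin_archetype(spec)
  stopifnot(inherits(spec, "archetype_spec"))
  tmpl <- matrix(spec$base_level, nrow = 24, ncol = 7)
  h <- 0:23
  if (nrow(spec$peaks) > 0) {
    for (i in seq_len(nrow(spec$peaks))) {
      pk <- spec$peaks[i, ]
      bump <- pk$amplitude * exp(-0.5 * ((h - pk$hour) / pk$width)^2)
      for (d in pk$days[[1]]) tmpl[, d] <- tmpl[, d] + bump
    }
  }
  tmpl[, WEEKEND_IDX] <- tmpl[, WEEKEND_IDX] * spec$weekend_modifier
  out <- as.vector(tmpl)
  stopifnot(length(out) == HOURS_PER_WEEK, all(out >= 0))
  out
}
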