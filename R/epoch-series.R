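#' Weekly epoch series
#'
#' The raw unit of input: one participant's week of fixed-length epoch
#' summaries of wrist acceleration (ENMO, milli-gravity units).  Missing
#' epochs are `NA`; epochs filled by upstream or package imputation carry
#' an imputed flag.
#'
#' @param participant_id Opaque id string.
#' @param start_day Weekday on which the series starts (name or 1..7,
#'   1 = Monday).  The series is assumed to start at 00:00 of that day.
#' @param epoch_seconds Epoch duration in seconds (5 for the source data).
#' @param values Numeric vector of magnitudes in mg; `NA` marks a missing
#'   (blank) epoch.  Present values must be non-negative.
#' @param imputed Logical vector, same length as `values`: `TRUE` where the
#'   value was imputed rather than measured.
#' @param source_notes Free-text provenance note.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, start_day, epoch_seconds, values,
                         imputed = logical(length(values)),
                         source_notes = "") {
  stopifnot(length(participant_id) == 1L, length(epoch_seconds) == 1L)
  values <- as.numeric(values)
  imputed <- as.logical(imputed)
  if (length(imputed) != length(values)) {
    stop("imputed flags must match values in length")
  }
  if (anyNA(imputed)) stop("imputed flags must be TRUE/FALSE, not NA")
  if (any(values < 0, na.rm = TRUE)) {
    stop("acceleration magnitudes must be >= 0 mg")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      start_day = weekday_index(start_day),
      epoch_seconds = epoch_seconds,
      values = values,
      imputed = imputed,
      source_notes = source_notes
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<epoch_series> %s: %d slots of %gs starting %s (%d missing, %d imputed)\n",
    x$participant_id, n, x$epoch_seconds, WEEKDAYS[x$start_day],
    sum(is.na(x$values)), sum(x$imputed)
  ))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

QUALITY_LEVELS <- c(
  "COMPLETE_PERFECT", "COMPLETE_IMPUTED", "RECOVERABLE",
  "DST_SPRING", "DST_AUTUMN", "UNUSABLE"
)

USABLE_QUALITIES <- QUALITY_LEVELS[1:5]

#' Quality categories for weekly series
#'
#' The five usable completeness categories plus `UNUSABLE`:
#' * `COMPLETE_PERFECT` - all epochs of the week present, none imputed.
#' * `COMPLETE_IMPUTED` - all epochs present, at least one imputed upstream.
#' * `RECOVERABLE` - exactly one blank epoch (typically the final one).
#' * `DST_SPRING` - clocks-forward week: one extra hour of slots, with at
#'   least one full hour blank.
#' * `DST_AUTUMN` - clocks-back week: one hour of slots short.
#' * `UNUSABLE` - anything else.
#'
#' @return Character vector of the six category labels.
#' @export
quality_levels <- function() QUALITY_LEVELS
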