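#' Classify the completeness quality of a weekly series
#'
#' Assigns one of the five usable quality categories, or `UNUSABLE`, from
#' slot and blank counts.  At 5 s resolution the defining counts are:
#' a complete week holds 120,960 epochs (720 per hour); a recoverable week
#' has 120,959 valid epochs plus exactly one blank; a spring (clocks
#' forward) DST week has 121,680 slots of which at least 720 are blank;
#' an autumn (clocks back) DST week has 120,240 slots.  All counts scale
#' with the configured epoch length.
#'
#' @param series An [epoch_series()].
#' @return A quality category string; see [quality_levels()].
#' @export
classify_quality <- function(series) {
  if (!inherits(series, "epoch_series")) {
    stop("classify_quality expects an epoch_series")
  }
  eph <- epochs_per_hour(series$epoch_seconds)
  epw <- epochs_per_week(series$epoch_seconds)
  n_slots <- length(series$values)
  n_blank <- sum(is.na(series$values))
  any_imp <- any(series$imputed)

  if (n_slots == epw && n_blank == 0L) {
    if (any_imp) "COMPLETE_IMPUTED" else "COMPLETE_PERFECT"
  } else if (n_slots == epw && n_blank == 1L) {
    "RECOVERABLE"
  } else if (n_slots == epw + eph && n_blank >= eph) {
    "DST_SPRING"
  } else if (n_slots == epw - eph) {
    "DST_AUTUMN"
  } else {
    "UNUSABLE"
  }
}

#' Repair a daylight-saving-time transition week
#'
#' Spring (clocks forward): the blank Sunday 01:00-01:59 hour is filled
#' epoch-wise with the average of readings in the same clock hour on the
#' other six days, and the extra hour of wear at the end of the series is
#' removed.  Autumn (clocks back): the missing final hour is appended,
#' filled the same way.  Either way the result has exactly one week of
#' slots and every filled epoch carries an imputed flag.
#'
#' @param series An [epoch_series()] classified as a DST case.
#' @param category Its quality category (`"DST_SPRING"` or `"DST_AUTUMN"`).
#' @return The repaired `epoch_series`.
#' @export
repair_dst <- function(series, category) {
  if (!category %in% c("DST_SPRING", "DST_AUTUMN")) {
    stop("repair_dst applies only to DST_SPRING / DST_AUTUMN series")
  }
  eph <- epochs_per_hour(series$epoch_seconds)
  epw <- epochs_per_week(series$epoch_seconds)

  if (category == "DST_SPRING") {
    if (length(series$values) != epw + eph) {
      stop("spring DST series must have one extra hour of slots")
    }
    # hours fully blank (the skipped clock hour); fill from other days
    by_hour <- matrix(is.na(series$values[seq_len(epw)]), nrow = eph)
    blank_hours <- which(colSums(by_hour) == eph) - 1L  # 0-based
    if (length(blank_hours) == 0L) stop("no fully blank hour to repair")
    for (h in blank_hours) {
      idx <- h * eph + seq_len(eph)
      series$values[idx] <- other_day_hour_values(series$values, eph, h)
      series$imputed[idx] <- TRUE
    }
    keep <- seq_len(epw)  # drop the extra trailing hour
    series$values <- series$values[keep]
    series$imputed <- series$imputed[keep]
  } else {
    if (length(series$values) != epw - eph) {
      stop("autumn DST series must be one hour of slots short")
    }
    final_hour <- HOURS_PER_WEEK - 1L  # 0-based
    fill <- other_day_hour_values(series$values, eph, final_hour)
    series$values <- c(series$values, fill)
    series$imputed <- c(series$imputed, rep(TRUE, eph))
  }
  if (anyNA(series$values[seq_len(epw)])) {
    stop("DST repair left blank epochs outside the transition hour")
  }
  series$source_notes <- paste(series$source_notes, "dst_repaired")
  series
}

#' Non-imputed wear time in hours
#'
#' Wear is accounted at the epoch level: epochs that are present and not
#' flagged imputed (by the upstream pipeline or by [repair_dst()]) count
#' towards wear.
#'
#' @param series An [epoch_series()].
#' @return Hours of non-imputed wear.
#' @export
nonimputed_wear_hours <- function(series) {
  sum(!is.na(series$values) & !series$imputed) * series$epoch_seconds / 3600
}

#' Aggregate a weekly series to 168 hourly means
#'
#' Each hour's mean is taken over its valid epochs (720 per hour at 5 s
#' resolution; one hour of a recoverable week averages 719 readings
#' rather than 720).  The per-hour epoch counts used are recorded.
#'
#' @param series A repaired [epoch_series()] with one week of slots.
#' @param quality Optional quality category to carry along.
#' @return An `hourly_profile`: list with `participant_id`, `hours`
#'   (168 means, index 1 = first hour of wear), `epochs_per_hour_used`,
#'   `quality`, `nonimputed_wear_hours`, `start_day` and an `aligned`
#'   flag.
#' @export
hourly_aggregate <- function(series, quality = NULL) {
  eph <- epochs_per_hour(series$epoch_seconds)
  epw <- epochs_per_week(series$epoch_seconds)
  if (length(series$values) != epw) {
    stop("hourly_aggregate requires exactly one week of slots; classify ",
         "and repair the series first")
  }
  m <- matrix(series$values, nrow = eph)
  counts <- colSums(!is.na(m))
  if (any(counts == 0L)) stop("an hour has no valid epochs to average")
  hours <- colMeans(m, na.rm = TRUE)
  structure(
    list(
      participant_id = series$participant_id,
      hours = hours,
      epochs_per_hour_used = as.integer(counts),
      quality = quality,
      nonimputed_wear_hours = nonimputed_wear_hours(series),
      start_day = series$start_day,
      aligned = FALSE
    ),
    class = "hourly_profile"
  )
}

#' Rotate an hourly profile to the canonical Monday-start week
#'
#' Circularly rotates the 168 hourly values so that index 1 is Monday
#' 00:00-00:59, using the recorded start weekday.  Aligning an already
#' aligned profile is the identity.
#'
#' @param profile An `hourly_profile` from [hourly_aggregate()].
#' @param start_day Optional override of the profile's start weekday.
#' @return The aligned `hourly_profile`.
#' @export
align_week <- function(profile, start_day = NULL) {
  stopifnot(inherits(profile, "hourly_profile"))
  if (isTRUE(profile$aligned)) return(profile)
  s <- weekday_index(if (is.null(start_day)) profile$start_day else start_day)
  idx <- ((0:167 - 24L * (s - 1L)) %% HOURS_PER_WEEK) + 1L
  profile$hours <- profile$hours[idx]
  profile$epochs_per_hour_used <- profile$epochs_per_hour_used[idx]
  profile$start_day <- 1L
  profile$aligned <- TRUE
  profile
}

#' Selection-funnel report
#'
#' Reconciles every stage of profile selection: supplied minus withdrawn
#' and age-ineligible participants gives the available pool; dropping the
#' unusable quality category gives the usable pool; removing high-mean
#' (at or above 100 mg) and low-wear (under 72 h) participants gives the
#' retained sample.  Percentages are printed at the precision the funnel
#' is conventionally reported at: availability to one decimal, the later
#' stages as whole percentages.
#'
#' @param n_supplied,n_withdrawn,n_age_ineligible Stage counts.
#' @param quality_counts Named counts over [quality_levels()] for the
#'   available pool.
#' @param n_mean_ge_100 Usable participants excluded for mean activity at
#'   or above the threshold.
#' @param n_wear_lt_72h Usable participants excluded for low non-imputed
#'   wear (not already excluded for mean activity).
#' @param reasons Optional per-participant reason-code list.
#' @return An `exclusion_report` with all counts and derived percentages.
#' @export
exclusion_report <- function(n_supplied, n_withdrawn, n_age_ineligible,
                             quality_counts, n_mean_ge_100, n_wear_lt_72h,
                             reasons = NULL) {
  qc <- setNames(rep(0, length(QUALITY_LEVELS)), QUALITY_LEVELS)
  qc[names(quality_counts)] <- quality_counts
  n_available <- n_supplied - n_withdrawn - n_age_ineligible
  if (sum(qc) != n_available) {
    stop("quality counts must sum to the available pool (",
         sum(qc), " vs ", n_available, ")")
  }
  n_usable <- n_available - qc[["UNUSABLE"]]
  n_retained <- n_usable - n_mean_ge_100 - n_wear_lt_72h
  if (n_retained < 0) stop("exclusion counts exceed the usable pool")
  structure(
    list(
      n_supplied = n_supplied,
      n_withdrawn = n_withdrawn,
      n_age_ineligible = n_age_ineligible,
      n_available = n_available,
      quality_counts = qc,
      n_usable = n_usable,
      n_mean_ge_100 = n_mean_ge_100,
      n_wear_lt_72h = n_wear_lt_72h,
      n_retained = n_retained,
      pct_available_of_supplied = round_half_up(100 * n_available / n_supplied, 1),
      pct_usable_of_available = round_half_up(100 * n_usable / n_available, 0),
      pct_retained_of_supplied = round_half_up(100 * n_retained / n_supplied, 0),
      pct_quality_of_available = round_half_up(100 * qc / n_available, 0),
      reasons = reasons
    ),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Selection funnel\n  supplied:        %d\n", x$n_supplied))
  cat(sprintf("  withdrawn:       %d\n  age-ineligible:  %d\n",
              x$n_withdrawn, x$n_age_ineligible))
  cat(sprintf("  available:       %d (%.1f%% of supplied)\n",
              x$n_available, x$pct_available_of_supplied))
  for (q in QUALITY_LEVELS) {
    cat(sprintf("    %-17s %d\n", paste0(tolower(q), ":"), x$quality_counts[[q]]))
  }
  cat(sprintf("  usable:          %d (%.0f%% of available)\n",
              x$n_usable, x$pct_usable_of_available))
  cat(sprintf("  mean >= 100 mg:  %d\n  wear < 72 h:     %d\n",
              x$n_mean_ge_100, x$n_wear_lt_72h))
  cat(sprintf("  retained:        %d (%.0f%% of supplied)\n",
              x$n_retained, x$pct_retained_of_supplied))
  invisible(x)
}

#' Apply the exclusion filters to a classified, repaired cohort
#'
#' Removes, in order: participants flagged withdrawn or age-ineligible in
#' the metadata; series whose quality is `UNUSABLE`; usable series whose
#' weekly mean activity is at or above `mean_threshold_mg`; and usable
#' series with less than `min_wear_hours` of non-imputed wear.  The mean
#' and wear filters are evaluated jointly and a participant failing both
#' carries both reason codes, but the funnel counts each participant once
#' (under the earlier stage) so the report reconciles exactly.
#'
#' @param series_list List of repaired [epoch_series()].
#' @param metadata Data frame with `participant_id`, `withdrawn`,
#'   `age_ineligible`; `NULL` to skip those stages.
#' @param qualities Optional pre-computed quality categories (recomputed
#'   via [classify_quality()] when omitted).
#' @param mean_threshold_mg Weekly-mean exclusion threshold (default 100).
#' @param min_wear_hours Minimum non-imputed wear (default 72; strictly
#'   less is excluded, exactly 72 h is retained).
#' @return List with `retained` (the surviving series), `qualities` (their
#'   categories) and `report` (an [exclusion_report()]).
#' @export
apply_exclusions <- function(series_list, metadata = NULL, qualities = NULL,
                             mean_threshold_mg = 100, min_wear_hours = 72) {
  ids <- vapply(series_list, function(s) s$participant_id, character(1))
  n <- length(series_list)
  if (is.null(qualities)) {
    qualities <- vapply(series_list, classify_quality, character(1))
  }
  withdrawn <- age_inelig <- rep(FALSE, n)
  if (!is.null(metadata)) {
    m <- match(ids, metadata$participant_id)
    if (anyNA(m)) stop("metadata missing for: ",
                       paste(head(ids[is.na(m)]), collapse = ", "))
    withdrawn <- as.logical(metadata$withdrawn[m])
    age_inelig <- !withdrawn & as.logical(metadata$age_ineligible[m])
  }
  available <- !withdrawn & !age_inelig
  unusable <- available & qualities == "UNUSABLE"
  usable <- available & !unusable

  week_mean <- vapply(series_list,
                      function(s) mean(s$values, na.rm = TRUE), numeric(1))
  wear <- vapply(series_list, nonimputed_wear_hours, numeric(1))
  fail_mean <- usable & week_mean >= mean_threshold_mg
  fail_wear <- usable & wear < min_wear_hours
  retained <- usable & !fail_mean & !fail_wear

  reasons <- lapply(seq_len(n), function(i) {
    r <- character(0)
    if (withdrawn[i]) r <- c(r, "withdrawn")
    if (age_inelig[i]) r <- c(r, "age_ineligible")
    if (unusable[i]) r <- c(r, "unusable_quality")
    if (fail_mean[i]) r <- c(r, "mean_ge_threshold")
    if (fail_wear[i]) r <- c(r, "wear_lt_min")
    r
  })
  names(reasons) <- ids

  report <- exclusion_report(
    n_supplied = n,
    n_withdrawn = sum(withdrawn),
    n_age_ineligible = sum(age_inelig),
    quality_counts = table(factor(qualities[available],
                                  levels = QUALITY_LEVELS)),
    n_mean_ge_100 = sum(fail_mean),
    n_wear_lt_72h = sum(fail_wear & !fail_mean),
    reasons = reasons
  )
  list(
    retained = series_list[retained],
    qualities = qualities[retained],
    report = report
  )
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Classifies every series, repairs the DST weeks, applies the exclusion
#' filters, aggregates the retained series to hourly profiles and (by
#' default) rotates them to the canonical Monday-start week.
#'
#' @param series_list List of raw [epoch_series()].
#' @param metadata Participant metadata (see [apply_exclusions()]).
#' @param mean_threshold_mg,min_wear_hours Exclusion thresholds.
#' @param align Rotate profiles to Monday start (default `TRUE`).
#' @return List with `profiles` (retained-participants x 168 matrix of
#'   hourly means, mg, row names = ids), `qualities`, `wear_hours` and
#'   `report`.
#' @export
preprocess_cohort <- function(series_list, metadata = NULL,
                              mean_threshold_mg = 100, min_wear_hours = 72,
                              align = TRUE) {
  qualities <- vapply(series_list, classify_quality, character(1))
  repaired <- Map(function(s, q) {
    if (q %in% c("DST_SPRING", "DST_AUTUMN")) repair_dst(s, q) else s
  }, series_list, qualities)
  excl <- apply_exclusions(repaired, metadata, qualities,
                           mean_threshold_mg, min_wear_hours)
  profs <- Map(hourly_aggregate, excl$retained, excl$qualities)
  if (align) profs <- lapply(profs, align_week)
  X <- do.call(rbind, lapply(profs, `[[`, "hours"))
  rownames(X) <- vapply(profs, `[[`, character(1), "participant_id")
  list(
    profiles = X,
    qualities = excl$qualities,
    wear_hours = vapply(profs, `[[`, numeric(1), "nonimputed_wear_hours"),
    report = excl$report
  )
}
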