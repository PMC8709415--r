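# Epoch files are plain delimited text: one row per epoch with columns
# participant_id, timestamp (ISO-8601, +00:00 offset), value_mg (empty =
# missing) and imputed (0/1). Rows are time-sorted and equally spaced per
# participant. Series carry a start weekday rather than a calendar date,
# so timestamps are written on a fixed reference week (Monday 2015-06-01,
# within the study's wear window) offset to the series' start day.

REFERENCE_MONDAY <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")

#' Write a list of epoch series to a delimited epoch file
#'
#' @param series_list List of [epoch_series()].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_epoch_file <- function(series_list, path) {
  tabs <- lapply(series_list, function(s) {
    n <- length(s$values)
    t0 <- REFERENCE_MONDAY + (s$start_day - 1L) * 86400
    data.table::data.table(
      participant_id = s$participant_id,
      timestamp = format(t0 + (seq_len(n) - 1L) * s$epoch_seconds,
                         "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC"),
      value_mg = s$values,
      imputed = as.integer(s$imputed)
    )
  })
  data.table::fwrite(data.table::rbindlist(tabs), path, na = "")
  invisible(path)
}

#' Read a delimited epoch file into epoch series
#'
#' Validates the schema and, per participant, that timestamps are sorted
#' and equally spaced; empty `value_mg` fields become missing epochs.
#'
#' @param path Epoch CSV path.
#' @return List of [epoch_series()], one per participant, in file order.
#' @export
read_epoch_file <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("participant_id", "timestamp")
  ))
  required <- c("participant_id", "timestamp", "value_mg", "imputed")
  if (!all(required %in% names(dt))) {
    stop("epoch file must have columns: ", paste(required, collapse = ", "))
  }
  if (!all(dt$imputed %in% c(0L, 1L))) {
    bad <- which(!(dt$imputed %in% c(0L, 1L)))
    stop("imputed flag must be 0/1; first bad row: ", bad[1] + 1L)
  }
  if (any(dt$value_mg < 0, na.rm = TRUE)) {
    bad <- which(dt$value_mg < 0)
    stop("negative magnitude; first bad row: ", bad[1] + 1L)
  }
  ids <- unique(dt$participant_id)
  lapply(ids, function(id) {
    sub <- dt[dt$participant_id == id, ]
    ts <- as.POSIXct(sub$timestamp, format = "%Y-%m-%dT%H:%M:%S+00:00",
                     tz = "UTC")
    if (anyNA(ts)) stop("unparseable timestamp for participant ", id)
    step <- diff(as.numeric(ts))
    if (any(step <= 0)) stop("timestamps not sorted for participant ", id)
    if (length(unique(step)) > 1L) {
      stop("mixed epoch spacing for participant ", id)
    }
    epoch_seconds <- if (length(step)) step[1] else 5
    start_day <- (as.integer(format(ts[1], "%u")))  # 1 = Monday
    epoch_series(id, start_day, epoch_seconds, sub$value_mg,
                 as.logical(sub$imputed), source_notes = path)
  })
}

#' Write a cohort (epochs, truth, metadata) to a directory
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_epoch_file(cohort$series, file.path(dir, "epochs.csv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  data.table::fwrite(cohort$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Write / read an hourly-profile matrix
#'
#' One row per participant: id, quality, then the 168 hourly means.
#'
#' @param X Profile matrix with participant-id row names.
#' @param qualities Quality category per row.
#' @param path CSV path.
#' @return `path` invisibly / a list with `profiles` and `qualities`.
#' @export
write_profile_matrix <- function(X, qualities, path) {
  dt <- data.table::data.table(
    participant_id = rownames(X),
    quality = qualities
  )
  hours <- data.table::as.data.table(X)
  names(hours) <- sprintf("h%03d", seq_len(ncol(X)) - 1L)
  data.table::fwrite(cbind(dt, hours), path)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  dt <- data.table::fread(path)
  X <- as.matrix(dt[, -(1:2)])
  rownames(X) <- dt$participant_id
  list(profiles = X, qualities = dt$quality)
}

#' Save / load a fitted medoid model as JSON
#'
#' The saved model (k, medoid ids and profiles, assignments, total
#' dissimilarity) is self-contained: reloading it is enough to label a
#' new cohort with [assign_profiles()] without refitting.
#'
#' @param solution A `medoid_solution`.
#' @param path JSON path.
#' @return `path` invisibly / the reloaded model list.
#' @export
write_medoid_model <- function(solution, path) {
  jsonlite::write_json(
    list(
      k = solution$k,
      medoid_ids = solution$medoid_ids,
      medoid_profiles = apply(solution$medoid_profiles, 1, identity,
                              simplify = FALSE),
      assignments = solution$assignments,
      total_dissimilarity = solution$total_dissimilarity
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_medoid_model
#' @export
read_medoid_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$medoid_profiles <- do.call(rbind, m$medoid_profiles)
  rownames(m$medoid_profiles) <- m$medoid_ids
  m
}

#' Write a scree curve as delimited text
#'
#' Columns k, dissimilarity, first_difference (blank at the smallest k).
#'
#' @param curve A `scree_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_scree <- function(curve, path) {
  data.table::fwrite(data.table::data.table(
    k = curve$k_values,
    dissimilarity = unname(curve$dissimilarities),
    first_difference = c(NA, unname(curve$first_differences))
  ), path, na = "")
  invisible(path)
}

#' Write a distance matrix in long format
#'
#' Columns id1, id2, distance; one row per unordered pair.
#'
#' @param d A `distance_matrix`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  ut <- upper.tri(d$entries)
  ij <- which(ut, arr.ind = TRUE)
  data.table::fwrite(data.table::data.table(
    id1 = d$ids[ij[, 1]], id2 = d$ids[ij[, 2]], distance = d$entries[ut]
  ), path)
  invisible(path)
}

#' Write an exclusion report as JSON
#'
#' @param report An [exclusion_report()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(
    report[setdiff(names(report), "reasons")],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Run configuration with defaults
#'
#' Thresholds and algorithm settings for a full pipeline run: epoch
#' length, the 100 mg mean-activity and 72 h wear exclusion thresholds,
#' the k range of the scree (1..18 by default, mirroring the scale of the
#' original sweep), restart count, the `select_k` threshold `tau`, the
#' optional DTW band, and the master seed.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of settings.
#' @export
run_config <- function(...) {
  defaults <- list(
    epoch_seconds = 5,
    mean_exclusion_mg = 100,
    min_wear_hours = 72,
    k_min = 1L,
    k_max = 18L,
    n_restarts = 1L,
    tau = 0.5,
    seed = 1L,
    dtw_band = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown settings: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, overrides)
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
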