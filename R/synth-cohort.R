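#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic weekly-accelerometer generator.
#' Defaults describe the emulated study conditions: 5 s epochs, a quality
#' mix matching the proportions observed in the source cohort (21 percent
#' perfect, 44 percent upstream-imputed, 21 percent recoverable, 1 percent
#' spring-DST, 2 percent autumn-DST, 11 percent unusable), a handful of
#' planted high-mean outliers and low-wear participants, and uniformly
#' distributed wear-start weekdays.
#'
#' @param n_per_archetype Participants generated per archetype.
#' @param epoch_seconds Epoch duration in seconds (must divide 3600).
#' @param noise_sd Epoch-level truncated-Gaussian noise sd in mg.
#' @param seed Master seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param missingness_mix Named probabilities over scenarios
#'   `none`, `imputed_blocks`, `trailing_blank`, `spring_dst`,
#'   `autumn_dst`, `random_gaps`; must sum to 1.
#' @param n_outliers_high_mean Planted participants whose weekly mean
#'   activity is at or above the 100 mg exclusion threshold.
#' @param n_low_wear Planted participants with under 72 h of non-imputed
#'   wear.
#' @param n_withdrawn,n_age_ineligible Participants flagged in metadata as
#'   withdrawn from the study / outside the 40-69 baseline age range.
#' @param start_day_distribution Probabilities over the 7 start weekdays
#'   (Monday first).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_archetype = 100,
                          epoch_seconds = 5,
                          noise_sd = 15,
                          seed = 1L,
                          missingness_mix = c(
                            none = 0.21, imputed_blocks = 0.44,
                            trailing_blank = 0.21, spring_dst = 0.01,
                            autumn_dst = 0.02, random_gaps = 0.11
                          ),
                          n_outliers_high_mean = 3,
                          n_low_wear = 5,
                          n_withdrawn = 2,
                          n_age_ineligible = 3,
                          start_day_distribution = rep(1 / 7, 7)) {
  scen <- c("none", "imputed_blocks", "trailing_blank", "spring_dst",
            "autumn_dst", "random_gaps")
  mix <- missingness_mix[scen]
  names(mix) <- scen
  mix[is.na(mix)] <- 0
  if (abs(sum(mix) - 1) > 1e-8) stop("missingness_mix must sum to 1")
  stopifnot(
    n_per_archetype >= 0, noise_sd >= 0, n_outliers_high_mean >= 0,
    n_low_wear >= 0, n_withdrawn >= 0, n_age_ineligible >= 0,
    length(start_day_distribution) == 7,
    abs(sum(start_day_distribution) - 1) < 1e-8
  )
  epochs_per_hour(epoch_seconds)  # validates divisibility
  structure(
    list(
      n_per_archetype = as.integer(n_per_archetype),
      epoch_seconds = epoch_seconds,
      noise_sd = noise_sd,
      seed = as.integer(seed),
      missingness_mix = mix,
      n_outliers_high_mean = as.integer(n_outliers_high_mean),
      n_low_wear = as.integer(n_low_wear),
      n_withdrawn = as.integer(n_withdrawn),
      n_age_ineligible = as.integer(n_age_ineligible),
      start_day_distribution = start_day_distribution
    ),
    class = "cohort_config"
  )
}

#' Simulate one participant's weekly epoch series
#'
#' The Monday-aligned hourly template is rotated to the participant's start
#' weekday, expanded to epochs, and perturbed with independent Gaussian
#' noise truncated at 0 mg.  With `noise_sd = 0` the hourly means of the
#' result reproduce the template exactly after week re-alignment.
#'
#' @param template 168-hour Monday-aligned template (mg).
#' @param epoch_seconds Epoch duration in seconds.
#' @param noise_sd Epoch-level noise sd in mg.
#' @param participant_seed Seed making this series reproducible on its own.
#' @param start_day Start weekday (name or 1..7).
#' @param participant_id Id string.
#' @return An [epoch_series()] covering a complete week.
#' @export
simulate_participant <- function(template, epoch_seconds, noise_sd,
                                 participant_seed, start_day,
                                 participant_id = "P1") {
  stopifnot(length(template) == HOURS_PER_WEEK, all(template >= 0))
  eph <- epochs_per_hour(epoch_seconds)
  s <- weekday_index(start_day)
  # participant hour i (0-based, from start day 00:00) = template hour
  # ((s-1)*24 + i) mod 168
  hour_means <- template[((s - 1L) * 24L + 0:167) %% HOURS_PER_WEEK + 1L]
  mu <- rep(hour_means, each = eph)
  set.seed(participant_seed)
  values <- if (noise_sd > 0) pmax(0, mu + rnorm(length(mu), 0, noise_sd)) else mu
  epoch_series(participant_id, s, epoch_seconds, values,
               source_notes = "synthetic")
}

hour_of_slot <- function(i, eph) (i - 1L) %/% eph  # 0-based hour from start

# mean of the same clock hour on the other days, epoch-offset-wise
other_day_hour_values <- function(values, eph, hour0) {
  epd <- 24L * eph
  day0 <- hour0 %/% 24L
  hod <- hour0 %% 24L
  sapply(seq_len(eph), function(off) {
    idx <- vapply(setdiff(0:6, day0), function(d) {
      d * epd + hod * eph + off
    }, numeric(1))
    idx <- idx[idx >= 1 & idx <= length(values)]
    mean(values[idx], na.rm = TRUE)
  })
}

#' Degrade a complete week with a missingness scenario
#'
#' Applies one of the generator's quality scenarios to a complete weekly
#' series:
#' * `none` - unchanged.
#' * `trailing_blank` - blanks the final epoch only.
#' * `spring_dst` - blanks the full Sunday 01:00-01:59 hour and appends one
#'   extra trailing hour of wear (clocks-forward week), giving one extra
#'   hour of slots in total.
#' * `autumn_dst` - removes the final hour of slots (clocks-back week).
#' * `imputed_blocks` - replaces a random 6 h block with the mean of the
#'   same clock hours on the other days and flags it imputed (emulating
#'   upstream imputation).
#' * `random_gaps` - blanks roughly 2 percent of epochs at random
#'   positions, making the series unusable.
#'
#' Placement randomness for `imputed_blocks` / `random_gaps` uses the
#' current RNG state.
#'
#' @param series A complete-week [epoch_series()].
#' @param scenario Scenario label.
#' @return The degraded `epoch_series`.
#' @export
inject_missingness <- function(series, scenario) {
  stopifnot(inherits(series, "epoch_series"))
  eph <- epochs_per_hour(series$epoch_seconds)
  epw <- epochs_per_week(series$epoch_seconds)
  if (length(series$values) != epw || anyNA(series$values)) {
    stop("inject_missingness requires a complete week of valid epochs")
  }
  switch(scenario,
    none = series,
    trailing_blank = {
      series$values[epw] <- NA_real_
      series
    },
    spring_dst = {
      # blank hour: Sunday 01:00, located relative to the start weekday
      days_to_sunday <- (7L - series$start_day) %% 7L
      hour0 <- days_to_sunday * 24L + 1L
      idx <- hour0 * eph + seq_len(eph)
      series$values[idx] <- NA_real_
      # final day's wear extended by one hour
      extra <- series$values[(epw - eph + 1L):epw]
      series$values <- c(series$values, extra)
      series$imputed <- c(series$imputed, rep(FALSE, eph))
      series$source_notes <- paste(series$source_notes, "spring_dst")
      series
    },
    autumn_dst = {
      keep <- seq_len(epw - eph)
      series$values <- series$values[keep]
      series$imputed <- series$imputed[keep]
      series$source_notes <- paste(series$source_notes, "autumn_dst")
      series
    },
    imputed_blocks = {
      start_hour <- sample(0:(HOURS_PER_WEEK - 6L), 1L)
      for (h in start_hour + 0:5) {
        fill <- other_day_hour_values(series$values, eph, h)
        idx <- h * eph + seq_len(eph)
        series$values[idx] <- fill
        series$imputed[idx] <- TRUE
      }
      series
    },
    random_gaps = {
      n_gap <- max(2L, round(0.02 * epw))
      idx <- sample.int(epw, n_gap)
      series$values[idx] <- NA_real_
      series
    },
    stop("unknown missingness scenario: ", scenario)
  )
}

flag_low_wear <- function(series, wear_hours = 60) {
  # flag everything beyond `wear_hours` as imputed so non-imputed wear
  # drops below the 72 h threshold while the series stays complete
  eph <- epochs_per_hour(series$epoch_seconds)
  cut <- round(wear_hours * eph)
  series$imputed[(cut + 1L):length(series$values)] <- TRUE
  series
}

#' Simulate a full synthetic cohort with known truth
#'
#' Generates `n_per_archetype` participants for each of the nine built-in
#' archetypes, assigns each a missingness scenario and start weekday drawn
#' from the configuration, and appends the planted high-mean outliers
#' (constant 150 mg weeks) and low-wear participants.  Participant
#' characteristics and outcome labels in the metadata are drawn with
#' archetype-dependent probabilities so that composition tables show
#' recoverable structure.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `series` (list of [epoch_series()]),
#'   `truth` (data frame: id, archetype, scenario, start day, planted
#'   role), and `metadata` (data frame of withdrawal/age flags, binary
#'   characteristics and outcome labels).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arche <- archetype_names()
  n_main <- length(arche) * config$n_per_archetype
  n_total <- n_main + config$n_outliers_high_mean + config$n_low_wear

  ids <- sprintf("P%04d", seq_len(n_total))
  archetype <- c(rep(arche, each = config$n_per_archetype),
                 rep(NA_character_, n_total - n_main))
  planted <- c(rep("normal", n_main),
               rep("outlier_high_mean", config$n_outliers_high_mean),
               rep("low_wear", config$n_low_wear))
  scenario <- rep("none", n_total)
  scenario[seq_len(n_main)] <- sample(
    names(config$missingness_mix), n_main,
    replace = TRUE, prob = config$missingness_mix
  )
  # low-wear participants reuse a sedentary template; keep scenario "none"
  low_arche <- rep("sedate", config$n_low_wear)
  start_day <- sample(1:7, n_total, replace = TRUE,
                      prob = config$start_day_distribution)
  pseed <- sample.int(.Machine$integer.max - 1L, n_total)

  templates <- lapply(arche, make_archetype_template)
  names(templates) <- arche
  outlier_template <- rep(150, HOURS_PER_WEEK)

  metadata <- simulate_metadata(ids, archetype, planted, start_day, config)

  series <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    tmpl <- if (planted[i] == "outlier_high_mean") {
      outlier_template
    } else if (planted[i] == "low_wear") {
      templates[[low_arche[i - n_main - config$n_outliers_high_mean]]]
    } else {
      templates[[archetype[i]]]
    }
    s <- simulate_participant(tmpl, config$epoch_seconds, config$noise_sd,
                              pseed[i], start_day[i], ids[i])
    s <- inject_missingness(s, scenario[i])
    if (planted[i] == "low_wear") s <- flag_low_wear(s)
    series[[i]] <- s
  }

  truth <- data.frame(
    participant_id = ids,
    archetype = archetype,
    scenario = scenario,
    start_day = WEEKDAYS[start_day],
    planted = planted,
    stringsAsFactors = FALSE
  )
  list(series = series, truth = truth, metadata = metadata)
}

# archetype-dependent probabilities loosely graded from most to least
# active so that composition/outcome tables have signal to recover
ARCHETYPE_PROBS <- data.frame(
  archetype = c("active_9to5", "active", "morning_movers",
                "get_up_and_active", "live_for_weekend", "moderates",
                "leisurely_9to5", "sedate", "inactive"),
  female = c(0.61, 0.60, 0.60, 0.61, 0.56, 0.58, 0.50, 0.53, 0.45),
  younger_40_54 = c(0.68, 0.46, 0.33, 0.32, 0.50, 0.36, 0.66, 0.18, 0.26),
  healthy_bmi = c(0.56, 0.54, 0.44, 0.43, 0.41, 0.34, 0.34, 0.27, 0.20),
  obese_share = c(0.20, 0.22, 0.30, 0.32, 0.35, 0.42, 0.42, 0.48, 0.55),
  spring_summer = c(0.54, 0.52, 0.50, 0.48, 0.51, 0.47, 0.50, 0.44, 0.45),
  alive = c(0.988, 0.986, 0.979, 0.977, 0.980, 0.969, 0.979, 0.954, 0.914),
  tested = c(0.161, 0.144, 0.161, 0.166, 0.173, 0.179, 0.171, 0.180, 0.208),
  positive = c(0.232, 0.204, 0.172, 0.146, 0.178, 0.157, 0.232, 0.128, 0.144),
  stringsAsFactors = FALSE
)

simulate_metadata <- function(ids, archetype, planted, start_day, config) {
  n <- length(ids)
  # planted participants borrow the least-active probability row
  row_of <- match(archetype, ARCHETYPE_PROBS$archetype)
  row_of[is.na(row_of)] <- nrow(ARCHETYPE_PROBS)
  p <- ARCHETYPE_PROBS[row_of, ]
  rb <- function(prob) runif(n) < prob
  female <- rb(p$female)
  younger <- rb(p$younger_40_54)
  healthy <- rb(p$healthy_bmi)
  obese <- !healthy & rb(p$obese_share)
  bmi_status <- ifelse(healthy, "healthy", ifelse(obese, "obese", "overweight"))
  alive <- rb(p$alive)
  tested <- alive & rb(p$tested)
  positive <- tested & rb(p$positive)

  withdrawn <- rep(FALSE, n)
  age_inelig <- rep(FALSE, n)
  normals <- which(planted == "normal")
  flagged <- sample(normals,
                    min(length(normals),
                        config$n_withdrawn + config$n_age_ineligible))
  withdrawn[head(flagged, config$n_withdrawn)] <- TRUE
  age_inelig[tail(flagged, length(flagged) - config$n_withdrawn)] <- TRUE

  data.frame(
    participant_id = ids,
    withdrawn = withdrawn,
    age_ineligible = age_inelig,
    female = female,
    younger_40_54 = younger,
    healthy_bmi = healthy,
    spring_summer_wear = rb(p$spring_summer),
    bmi_status = bmi_status,
    alive_flag = alive,
    tested_flag = tested,
    positive_flag = positive,
    stringsAsFactors = FALSE
  )
}
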