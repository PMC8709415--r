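test_that("quality classification matches the five category definitions", {
  s <- constant_week(30, 300)
  expect_identical(classify_quality(s), "COMPLETE_PERFECT")

  si <- s
  si$imputed[10] <- TRUE
  expect_identical(classify_quality(si), "COMPLETE_IMPUTED")

  expect_identical(
    classify_quality(inject_missingness(s, "trailing_blank")), "RECOVERABLE"
  )
  expect_identical(
    classify_quality(inject_missingness(s, "spring_dst")), "DST_SPRING"
  )
  expect_identical(
    classify_quality(inject_missingness(s, "autumn_dst")), "DST_AUTUMN"
  )
  set.seed(1)
  expect_identical(
    classify_quality(inject_missingness(s, "random_gaps")), "UNUSABLE"
  )
  expect_error(classify_quality(list(values = 1:5)), "epoch_series")
})

test_that("classification thresholds reproduce the 5 s slot counts", {
  s5 <- constant_week(30, 5)
  expect_length(s5$values, 120960)
  expect_identical(classify_quality(s5), "COMPLETE_PERFECT")
  sp <- inject_missingness(s5, "spring_dst")
  expect_identical(classify_quality(sp), "DST_SPRING")
  expect_length(sp$values, 121680)
})

test_that("DST repair fills from the same clock hour and restores the week", {
  epw <- epochs_per_week(300)
  eph <- epochs_per_hour(300)

  sp <- inject_missingness(constant_week(30, 300), "spring_dst")
  rep_sp <- repair_dst(sp, "DST_SPRING")
  expect_length(rep_sp$values, epw)
  expect_false(anyNA(rep_sp$values))
  expect_identical(sum(rep_sp$imputed), eph)
  expect_true(all(rep_sp$values[rep_sp$imputed] == 30))  # mean of constants
  expect_identical(classify_quality(rep_sp), "COMPLETE_IMPUTED")

  au <- inject_missingness(constant_week(30, 300), "autumn_dst")
  rep_au <- repair_dst(au, "DST_AUTUMN")
  expect_length(rep_au$values, epw)
  expect_identical(sum(rep_au$imputed), eph)
  expect_true(all(rep_au$values[rep_au$imputed] == 30))

  expect_error(repair_dst(constant_week(30, 300), "COMPLETE_PERFECT"),
               "DST_SPRING")
})

test_that("spring repair averages the same clock hour, not a global mean", {
  # distinct value per day so the imputed Sunday 01:00 hour must be the
  # mean of the other six days' 01:00 hours
  eph <- epochs_per_hour(300)
  vals <- rep(10 * (1:7), each = 24 * eph)  # day d has value 10d
  s <- epoch_series("D1", 1, 300, vals)
  sp <- inject_missingness(s, "spring_dst")
  fixed <- repair_dst(sp, "DST_SPRING")
  sunday_0100 <- fixed$values[(6 * 24 + 1) * eph + seq_len(eph)]
  expect_equal(unique(sunday_0100), mean(10 * (1:6)))
})

test_that("non-imputed wear accounting is proportional at epoch grain", {
  s <- constant_week(30, 300)
  expect_equal(nonimputed_wear_hours(s), 168)
  half <- s
  half$imputed[seq_len(length(half$values) / 2)] <- TRUE
  expect_equal(nonimputed_wear_hours(half), 84)
})

test_that("hourly aggregation averages valid epochs per hour", {
  expect_equal(unname(hourly_aggregate(constant_week(50, 300))$hours),
               rep(50, 168))

  rec <- inject_missingness(constant_week(50, 300), "trailing_blank")
  prof <- hourly_aggregate(rec, quality = "RECOVERABLE")
  eph <- epochs_per_hour(300)
  expect_identical(sum(prof$epochs_per_hour_used == eph - 1L), 1L)
  expect_identical(sum(prof$epochs_per_hour_used == eph), 167L)
  expect_equal(unname(prof$hours), rep(50, 168))

  # alternating 0/100 epochs average to 50
  eps <- epochs_per_week(300)
  alt <- epoch_series("A1", 1, 300, rep(c(0, 100), eps / 2))
  expect_equal(unname(hourly_aggregate(alt)$hours), rep(50, 168))

  expect_error(hourly_aggregate(inject_missingness(constant_week(1, 300),
                                                   "spring_dst")),
               "one week of slots")
})

test_that("hourly aggregation commutes with scalar scaling", {
  set.seed(8)
  eps <- epochs_per_week(300)
  s <- epoch_series("S1", 4, 300, runif(eps, 0, 80))
  h1 <- hourly_aggregate(s)$hours
  s3 <- s
  s3$values <- 3 * s3$values
  expect_equal(hourly_aggregate(s3)$hours, 3 * h1, tolerance = 1e-12)
})

test_that("week alignment rotates to Monday and is idempotent", {
  set.seed(9)
  eps <- epochs_per_week(300)
  mk <- function(day) {
    p <- hourly_aggregate(epoch_series("W1", day, 300, runif(eps, 0, 50)))
    p
  }
  mon <- mk(1)
  expect_equal(align_week(mon)$hours, mon$hours)

  wed <- mk(3)
  aligned <- align_week(wed)
  # starting Wednesday, the profile is rotated by 2 days (48 h)
  expect_equal(aligned$hours, wed$hours[((0:167 - 48) %% 168) + 1])
  expect_equal(align_week(aligned)$hours, aligned$hours)  # idempotent

  expect_error(align_week(mon, start_day = "Fooday"), "unknown weekday")
})

test_that("exclusion filters apply the documented boundaries", {
  eps <- epochs_per_week(300)
  mk <- function(id, value = 30, imputed_hours = 0) {
    s <- epoch_series(id, 1, 300, rep(value, eps))
    if (imputed_hours > 0) {
      s$imputed[seq_len(imputed_hours * epochs_per_hour(300))] <- TRUE
    }
    s
  }
  cohort <- list(
    mk("ok", 30),
    mk("at100", 100),      # mean exactly 100 -> excluded
    mk("just_under", 99.9),
    mk("wear72", imputed_hours = 96),    # exactly 72 h left -> retained
    mk("wear719", imputed_hours = 97)    # 71 h -> excluded
  )
  res <- apply_exclusions(cohort)
  ids <- vapply(res$retained, function(s) s$participant_id, character(1))
  expect_setequal(ids, c("ok", "just_under", "wear72"))
  expect_identical(res$report$n_mean_ge_100, 1L)
  expect_identical(res$report$n_wear_lt_72h, 1L)
  expect_identical(res$report$reasons[["at100"]], "mean_ge_threshold")
  expect_identical(res$report$reasons[["wear719"]], "wear_lt_min")
})

test_that("planted fixture exclusions are counted exactly", {
  co <- small_cohort(n_per_archetype = 3, seed = 21)
  pp <- preprocess_cohort(co$series, co$metadata)
  expect_identical(pp$report$n_mean_ge_100, 3L)
  expect_identical(pp$report$n_wear_lt_72h, 5L)
  expect_identical(pp$report$n_withdrawn, 2L)
  expect_identical(pp$report$n_age_ineligible, 3L)
})

test_that("the selection funnel conserves counts on fuzzed cohorts", {
  for (seed in 1:5) {
    co <- small_cohort(n_per_archetype = 2, seed = seed)
    pp <- preprocess_cohort(co$series, co$metadata)
    r <- pp$report
    expect_equal(
      r$n_supplied,
      r$n_retained + r$n_withdrawn + r$n_age_ineligible +
        unname(r$quality_counts[["UNUSABLE"]]) +
        r$n_mean_ge_100 + r$n_wear_lt_72h
    )
    expect_equal(sum(r$quality_counts), r$n_available)
    expect_equal(nrow(pp$profiles), r$n_retained)
  }
})

test_that("zero-noise cohorts reproduce archetype templates exactly", {
  co <- simulate_cohort(cohort_config(
    n_per_archetype = 1, epoch_seconds = 300, noise_sd = 0, seed = 2,
    missingness_mix = c(none = 1), n_outliers_high_mean = 0, n_low_wear = 0,
    n_withdrawn = 0, n_age_ineligible = 0
  ))
  pp <- preprocess_cohort(co$series, co$metadata)
  for (i in seq_len(nrow(pp$profiles))) {
    arch <- co$truth$archetype[match(rownames(pp$profiles)[i],
                                     co$truth$participant_id)]
    expect_equal(unname(pp$profiles[i, ]), make_archetype_template(arch),
                 tolerance = 1e-9)
  }
})
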