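test_that("cluster mean profiles are per-hour arithmetic means", {
  X <- matrix(runif(5 * 168, 0, 60), nrow = 5)
  lab <- c(1, 1, 2, 3, 3)
  cm <- cluster_mean_profiles(X, lab)
  expect_equal(unname(cm$means["2", ]), X[3, ])          # singleton
  expect_equal(unname(cm$means["1", ]), colMeans(X[1:2, ]))
  expect_identical(unname(cm$sizes), c(2L, 1L, 2L))
  # identical members reproduce their shared profile
  Y <- rbind(X[1, ], X[1, ])
  expect_equal(unname(cluster_mean_profiles(Y, c(1, 1))$means[1, ]), X[1, ])
  # means bounded by per-cluster hourly extremes
  expect_true(all(cm$means["1", ] <= pmax(X[1, ], X[2, ]) + 1e-12))
  expect_true(all(cm$means["1", ] >= pmin(X[1, ], X[2, ]) - 1e-12))
  expect_error(cluster_mean_profiles(X, factor(lab, levels = 1:4)),
               "at least one member")
})

test_that("zero-noise cluster means equal the archetype templates", {
  co <- simulate_cohort(cohort_config(
    n_per_archetype = 2, epoch_seconds = 300, noise_sd = 0, seed = 4,
    missingness_mix = c(none = 1), n_outliers_high_mean = 0, n_low_wear = 0,
    n_withdrawn = 0, n_age_ineligible = 0
  ))
  pp <- preprocess_cohort(co$series, co$metadata)
  arch <- co$truth$archetype[match(rownames(pp$profiles),
                                   co$truth$participant_id)]
  cm <- cluster_mean_profiles(pp$profiles, arch)
  for (a in rownames(cm$means)) {
    expect_equal(unname(cm$means[a, ]), make_archetype_template(a),
                 tolerance = 1e-9)
  }
})

test_that("composition table computes per-group percentages and extremes", {
  chars <- data.frame(
    participant_id = sprintf("P%d", 1:8),
    female = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    young = c(TRUE, FALSE, NA, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  grp <- c(rep("A", 4), rep("B", 4))
  ct <- composition_table(grp, chars)
  expect_equal(ct$percentages["female", "A"], 75)   # 3 of 4
  expect_equal(ct$percentages["female", "B"], 100)
  expect_equal(ct$percentages["female", "Overall"], 87.5)
  # NA young in group A: denominator drops to 3
  expect_equal(ct$denominators["young", "A"], 3)
  expect_equal(ct$percentages["young", "A"], 66.7)
  expect_identical(ct$max_col[["female"]], "B")
  expect_identical(ct$min_col[["female"]], "A")

  # all-female sample: 100 percent in every column, all columns tied
  allf <- data.frame(female = rep(TRUE, 6))
  ct2 <- composition_table(rep(c("A", "B", "C"), 2), allf)
  expect_true(all(ct2$percentages["female", ] == 100))
  expect_setequal(ct2$max_col[["female"]], c("A", "B", "C"))

  # pooled sample as a single group equals the overall column
  ct3 <- composition_table(rep("all", 8), chars)
  expect_equal(ct3$percentages[, "all"], ct3$percentages[, "Overall"])

  expect_error(composition_table(factor(grp, levels = c("A", "B", "C")),
                                 chars), "empty column group")
})

test_that("outcome difference rows sum to 100 and differences to ~0", {
  set.seed(19)
  cl <- sample(paste0("c", 1:5), 400, replace = TRUE)
  bmi <- sample(c("healthy", "overweight", "obese"), 400, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
  t3 <- outcome_difference_table(bmi, cl)
  expect_true(all(abs(rowSums(t3$percentages) - 100) <= 0.1))
  expect_true(all(abs(rowSums(t3$differences)) <= 0.2))
  expect_equal(sum(t3$overall), 100, tolerance = 0.1)

  # outcome distributed identically to the pool: all differences zero
  cl0 <- rep(c("a", "b"), each = 50)
  out0 <- rep(c("x", "y"), 50)
  t0 <- outcome_difference_table(out0, cl0)
  expect_true(all(t0$differences == 0))

  # single-cluster solution
  t1 <- outcome_difference_table(out0, rep("only", 100))
  expect_true(all(t1$percentages == 100))
  expect_true(all(t1$differences == 0))
})

test_that("difference vs overall reproduces printed-table arithmetic", {
  sizes <- c(a = 400, b = 350, c = 250)
  # overall share of cluster a = 40.0; a row with 44.5 is +4.5
  expect_equal(difference_vs_overall(44.5, sizes, "a"), 4.5)
  expect_equal(difference_vs_overall(35.0, sizes, "b"), 0)
})

test_that("covid outcome table uses the documented denominators", {
  cl <- rep("g1", 10)
  alive <- rep(TRUE, 10)
  tested <- c(TRUE, TRUE, rep(FALSE, 8))
  pos <- c(TRUE, rep(FALSE, 9))
  t4 <- covid_outcome_table(cl, alive, tested, pos)
  g <- t4[t4$cluster == "g1", ]
  expect_equal(g$pct_alive, 100)
  expect_equal(g$pct_alive_tested, 20)
  expect_equal(g$pct_alive_positive, 10)
  expect_equal(g$positivity_rate, 50)

  # no tests in a cluster: positivity undefined, not zero
  t5 <- covid_outcome_table(cl, alive, rep(FALSE, 10), rep(FALSE, 10))
  expect_true(is.na(t5$positivity_rate[1]))
  expect_equal(t5$pct_alive_tested[1], 0)

  # positivity ignores untested participants' other fields
  alive2 <- alive
  alive2[5:10] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  t6 <- covid_outcome_table(cl, alive2, tested, pos)
  expect_equal(t6$positivity_rate[1], 50)

  expect_error(covid_outcome_table(cl, alive, rep(FALSE, 10), pos),
               "positive implies tested")
})
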