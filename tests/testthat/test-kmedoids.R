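toy_1d <- function(v) matrix(v, ncol = 1)

test_that("total dissimilarity uses plain Euclidean distance", {
  X <- toy_1d(c(0, 1, 5))
  expect_equal(total_dissimilarity(X, medoid_indices = 2, assignments = rep(1, 3)),
               1 + 4)  # |0-1| + |1-1| + |5-1|
  expect_equal(total_dissimilarity(X, 1:3, 1:3), 0)          # k = n
  Xd <- toy_1d(c(2, 2))
  expect_equal(total_dissimilarity(Xd, 1, c(1, 1)), 0)       # duplicates
})

test_that("BUILD picks the 1-medoid minimiser and is deterministic", {
  X <- toy_1d(c(0, 1, 5))
  # brute force over the three candidates: medoid 1 costs 6, medoid 2
  # costs 5, medoid 3 costs 9
  expect_identical(pam_build(X, 1), 2L)
  expect_identical(sort(pam_build(X, 3)), 1:3)
  expect_equal(
    total_dissimilarity(
      X, pam_build(X, 3),
      assign_profiles(X, X[pam_build(X, 3), , drop = FALSE])$labels
    ),
    0
  )
  set.seed(10)
  Y <- matrix(runif(40), nrow = 10)
  expect_identical(pam_build(Y, 3), pam_build(Y, 3))
  expect_error(pam_build(Y, 11), "between 1")
})

test_that("fit recovers well-separated planted clusters", {
  set.seed(11)
  X <- rbind(
    matrix(rnorm(20 * 5, mean = 0), ncol = 5),
    matrix(rnorm(20 * 5, mean = 50), ncol = 5)
  )
  fit <- pam_fit(X, 2)
  truth <- rep(1:2, each = 20)
  expect_identical(length(unique(fit$assignments[1:20])), 1L)
  expect_identical(length(unique(fit$assignments[21:40])), 1L)
  expect_false(fit$assignments[1] == fit$assignments[40])
  expect_true(fit$converged)
})

test_that("fit attains the exhaustive optimum on tiny instances", {
  set.seed(12)
  hits <- 0L
  for (i in 1:30) {
    n <- sample(4:7, 1)
    k <- sample(2:3, 1)
    X <- matrix(runif(n * 3, 0, 10), nrow = n)
    diss <- as.matrix(dist(X))
    fit <- pam_fit(X, k, seed = i, n_restarts = 5)
    if (isTRUE(all.equal(fit$total_dissimilarity,
                         pam_brute_force(diss, k), tolerance = 1e-9))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 29L)  # PAM is a heuristic; near-universal optimality
})

test_that("every accepted swap strictly decreases total dissimilarity", {
  set.seed(13)
  for (i in 1:10) {
    X <- matrix(runif(30 * 4, 0, 10), nrow = 30)
    fit <- pam_fit(X, 4)
    expect_true(all(diff(fit$td_trace) < 0))
    # nearest-medoid optimality of the final assignment
    dm <- as.matrix(dist(X))[, fit$medoid_indices, drop = FALSE]
    expect_true(all(
      dm[cbind(1:30, fit$assignments)] <= apply(dm, 1, min) + 1e-12
    ))
    # objective equals the recomputed total dissimilarity
    expect_equal(fit$total_dissimilarity,
                 total_dissimilarity(X, fit$medoid_indices, fit$assignments),
                 tolerance = 1e-9)
  }
})

test_that("duplicating every point leaves the medoid values unchanged", {
  set.seed(14)
  X <- matrix(runif(12 * 3, 0, 10), nrow = 12)
  fit1 <- pam_fit(X, 3)
  fit2 <- pam_fit(rbind(X, X), 3)
  m1 <- fit1$medoid_profiles[order(fit1$medoid_profiles[, 1]), ]
  m2 <- fit2$medoid_profiles[order(fit2$medoid_profiles[, 1]), ]
  expect_equal(unname(m1), unname(m2))
})

test_that("fit agrees with an independent PAM implementation", {
  set.seed(15)
  # well-separated clouds where the optimum is unambiguous
  X <- rbind(
    matrix(rnorm(15 * 4, 0), ncol = 4),
    matrix(rnorm(15 * 4, 30), ncol = 4),
    matrix(rnorm(15 * 4, 60), ncol = 4)
  )
  ours <- pam_fit(X, 3)
  ref <- cluster::pam(dist(X), k = 3)
  expect_setequal(ours$medoid_indices, as.integer(ref$id.med))
  expect_equal(ours$total_dissimilarity,
               ref$objective[["swap"]] * nrow(X), tolerance = 1e-9)
})

test_that("the scree is non-increasing with non-negative first differences", {
  set.seed(16)
  X <- matrix(runif(40 * 6, 0, 10), nrow = 40)
  sc <- scree_curve(X, 1, 10, seed = 1)
  expect_true(all(diff(unname(sc$dissimilarities)) <= 1e-9))
  expect_true(all(sc$first_differences >= -1e-9))
  expect_identical(sc$k_values, 1:10)
})

test_that("select_k applies the tau-median last-sizeable-drop rule", {
  fake_curve <- function(deltas, k_min = 1) {
    ks <- seq.int(k_min, k_min + length(deltas))
    dis <- c(1000, 1000 - cumsum(deltas))
    structure(
      list(
        k_values = ks,
        dissimilarities = setNames(dis, ks),
        first_differences = setNames(deltas, ks[-1]),
        fits = NULL
      ),
      class = "scree_curve"
    )
  }
  # perfectly flat curve: no sizeable reduction, fall back to k_min
  expect_identical(select_k(fake_curve(rep(5, 6))), 1L)
  # last delta exceeding 1.5x the median of the later deltas:
  # delta(5) = 5 > 1.5 * median(1, 1, 1), so k = 5 is the last
  # qualifying drop under the rule
  expect_identical(select_k(fake_curve(c(100, 50, 40, 5, 1, 1, 1))), 5L)
  # with the bigger drop removed the tail is flat after k = 4
  expect_identical(select_k(fake_curve(c(100, 50, 40, 1, 1, 1, 1))), 4L)
  expect_error(select_k(fake_curve(50)), "at least 3")
})

test_that("assignment uses nearest medoid with lowest-index tie-breaking", {
  med <- rbind(c(0, 0), c(10, 0), c(20, 0))
  # a medoid labels itself at distance zero
  res <- assign_profiles(med, med)
  expect_identical(res$labels, 1:3)
  expect_equal(res$distances, c(0, 0, 0))
  # equidistant between medoids 1 and 2 -> lower index wins
  tie <- matrix(c(5, 0), nrow = 1)
  expect_identical(assign_profiles(tie, med)$labels, 1L)
  # translation invariance
  set.seed(17)
  P <- matrix(runif(10 * 2, 0, 30), ncol = 2)
  l0 <- assign_profiles(P, med)$labels
  l7 <- assign_profiles(P + 7, med + 7)$labels
  expect_identical(l0, l7)
})
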