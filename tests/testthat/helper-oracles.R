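# Independent oracles used to check the package's own implementations.

# DTW by explicit enumeration of all monotone warping paths from (1,1) to
# (n,m) with steps (1,0), (0,1), (1,1); cost = sum of |a_i - b_j| over the
# visited cells. Exponential: only for tiny inputs.
dtw_brute_force <- function(a, b) {
  n <- length(a)
  m <- length(b)
  walk <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == n && j == m) return(cost)
    branches <- c(
      if (i < n) walk(i + 1, j),
      if (j < m) walk(i, j + 1),
      if (i < n && j < m) walk(i + 1, j + 1)
    )
    cost + min(branches)
  }
  walk(1, 1)
}

# Exhaustive k-medoids: minimum total dissimilarity over all C(n, k)
# medoid subsets.
pam_brute_force <- function(diss, k) {
  n <- nrow(diss)
  best <- Inf
  subsets <- utils::combn(n, k)
  for (s in seq_len(ncol(subsets))) {
    med <- subsets[, s]
    td <- sum(apply(diss[, med, drop = FALSE], 1, min))
    if (td < best) best <- td
  }
  best
}

# A small cohort at coarse (300 s) epochs for fast pipeline tests.
small_cohort <- function(n_per_archetype = 4, seed = 42, ...) {
  simulate_cohort(cohort_config(
    n_per_archetype = n_per_archetype, epoch_seconds = 300, seed = seed, ...
  ))
}

# A complete constant-valued week at the given epoch length.
constant_week <- function(value = 30, epoch_seconds = 300, start_day = 1,
                          id = "C1") {
  epoch_series(id, start_day, epoch_seconds,
               rep(value, epochs_per_week(epoch_seconds)))
}
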