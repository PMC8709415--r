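euclidean_diss <- function(X) as.matrix(dist(X, method = "euclidean"))

#' Total dissimilarity of a medoid clustering
#'
#' Sum over participants of the plain Euclidean distance to the medoid of
#' their assigned cluster.  Plain rather than squared distance keeps the
#' influence of outlying profiles down; it is the objective minimised by
#' [pam_fit()].
#'
#' @param X Profile matrix (participants x hours).
#' @param medoid_indices Row indices of the k medoids.
#' @param assignments Cluster label (1..k, indexing `medoid_indices`) per
#'   participant.
#' @return The summed distance.
#' @export
total_dissimilarity <- function(X, medoid_indices, assignments) {
  stopifnot(length(assignments) == nrow(X),
            all(assignments %in% seq_along(medoid_indices)))
  sum(vapply(seq_len(nrow(X)), function(i) {
    euclidean_distance(X[i, ], X[medoid_indices[assignments[i]], ])
  }, numeric(1)))
}

#' Greedy BUILD initialisation for PAM
#'
#' The first medoid minimises the total distance to all points; each
#' subsequent medoid is the point whose addition most reduces the total
#' dissimilarity.  BUILD is deterministic in the data.
#'
#' @param X Profile matrix, or `NULL` if `diss` is given.
#' @param k Number of medoids, `1 <= k <= n`.
#' @param diss Optional precomputed dissimilarity matrix.
#' @return Integer vector of k distinct medoid row indices.
#' @export
pam_build <- function(X, k, diss = NULL) {
  if (is.null(diss)) diss <- euclidean_diss(X)
  n <- nrow(diss)
  if (k < 1 || k > n) stop("k must be between 1 and the number of profiles")
  pam_build_cpp(diss, as.integer(k)) + 1L
}

nearest_assign <- function(diss, medoids) {
  # ties broken toward the lowest cluster index (max.col on negated
  # distances with ties.method = "first")
  dm <- diss[, medoids, drop = FALSE]
  max.col(-dm, ties.method = "first")
}

#' Fit k-medoids by PAM (BUILD + SWAP)
#'
#' Initialises with greedy BUILD (plus optional seeded random restarts and
#' caller-supplied initial medoid sets), then applies SWAP steepest
#' descent: the best single medoid/non-medoid exchange is accepted while
#' it strictly decreases the total dissimilarity.  Cluster centres are
#' actual profiles, so the fitted medoids double as a portable classifier
#' via [assign_profiles()].
#'
#' @param X Profile matrix (participants x hours).
#' @param k Number of clusters.
#' @param seed Seed for random restarts (unused when `n_restarts = 1`;
#'   BUILD itself is deterministic).
#' @param max_iter Maximum accepted swaps per start (default 100).
#' @param n_restarts Number of starts: the first is BUILD, the rest are
#'   seeded random medoid sets; the best final solution is returned.
#' @param diss Optional precomputed dissimilarity matrix for `X`.
#' @param extra_inits Optional list of additional initial medoid-index
#'   sets to try (used by [scree_curve()] for warm starts).
#' @return A `medoid_solution`: `k`, `medoid_indices`, `medoid_ids`,
#'   `medoid_profiles`, `assignments`, `total_dissimilarity`,
#'   `n_iterations`, `converged`, `td_trace` (objective after each
#'   accepted swap of the winning start) and `seed`.
#' @export
pam_fit <- function(X, k, seed = NULL, max_iter = 100L, n_restarts = 1L,
                    diss = NULL, extra_inits = NULL) {
  stopifnot(is.matrix(X))
  if (is.null(diss)) diss <- euclidean_diss(X)
  n <- nrow(diss)
  if (k < 1 || k > n) stop("k must be between 1 and the number of profiles")

  inits <- list(pam_build_cpp(diss, as.integer(k)))
  if (n_restarts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts - 1L)) {
      inits <- c(inits, list(sort(sample.int(n, k)) - 1L))
    }
  }
  for (ini in extra_inits) {
    stopifnot(length(ini) == k, !anyDuplicated(ini))
    inits <- c(inits, list(as.integer(ini) - 1L))
  }

  best <- NULL
  for (ini in inits) {
    res <- pam_swap_cpp(diss, as.integer(ini), as.integer(max_iter))
    if (is.null(best) || tail(res$trace, 1) < tail(best$trace, 1)) best <- res
  }
  if (!best$converged) {
    warning("PAM SWAP did not converge within max_iter accepted swaps")
  }

  medoids <- best$medoids + 1L
  assignments <- nearest_assign(diss, medoids)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(
    list(
      k = as.integer(k),
      medoid_indices = medoids,
      medoid_ids = ids[medoids],
      medoid_profiles = X[medoids, , drop = FALSE],
      assignments = assignments,
      total_dissimilarity = tail(best$trace, 1),
      n_iterations = best$n_iterations,
      converged = best$converged,
      td_trace = best$trace,
      seed = seed
    ),
    class = "medoid_solution"
  )
}

#' @export
print.medoid_solution <- function(x, ...) {
  cat(sprintf(
    "<medoid_solution> k = %d, n = %d, total dissimilarity = %.2f (%s)\n",
    x$k, length(x$assignments), x$total_dissimilarity,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(table(x$assignments))
  invisible(x)
}

#' Dissimilarity scree over a range of k
#'
#' Fits PAM for each k in `k_min..k_max` and records the total
#' dissimilarity and its first differences.  To make the curve comparable
#' across k, every fit shares the same restart seeds, and each k is
#' additionally warm-started from the previous k's medoids plus the best
#' extra point, which guarantees the curve is non-increasing in k.
#'
#' @param X Profile matrix.
#' @param k_min,k_max Range of cluster counts.
#' @param seed Seed shared by the random restarts of every k.
#' @param max_iter,n_restarts Passed to [pam_fit()].
#' @return A `scree_curve`: `k_values`, `dissimilarities`,
#'   `first_differences` (named by the k moved to), and `fits` (the
#'   `medoid_solution` per k).
#' @export
scree_curve <- function(X, k_min = 1L, k_max, seed = NULL,
                        max_iter = 100L, n_restarts = 1L) {
  stopifnot(k_min >= 1L, k_max <= nrow(X), k_min <= k_max)
  diss <- euclidean_diss(X)
  ks <- seq.int(k_min, k_max)
  fits <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    extra <- NULL
    if (!is.null(prev)) {
      # previous medoids plus the point with the largest BUILD-style gain
      nearest <- apply(diss[, prev$medoid_indices, drop = FALSE], 1, min)
      gain <- colSums(pmax(nearest - diss, 0))
      gain[prev$medoid_indices] <- -Inf
      extra <- list(c(prev$medoid_indices, which.max(gain)))
    }
    fits[[i]] <- pam_fit(X, k, seed = seed, max_iter = max_iter,
                         n_restarts = n_restarts, diss = diss,
                         extra_inits = extra)
    prev <- fits[[i]]
  }
  dissim <- vapply(fits, `[[`, numeric(1), "total_dissimilarity")
  fd <- if (length(ks) > 1) -diff(dissim) else numeric(0)
  names(fd) <- if (length(ks) > 1) ks[-1] else character(0)
  structure(
    list(
      k_values = ks,
      dissimilarities = setNames(dissim, ks),
      first_differences = fd,
      fits = fits
    ),
    class = "scree_curve"
  )
}

#' @export
print.scree_curve <- function(x, ...) {
  df <- data.frame(
    k = x$k_values,
    dissimilarity = round(unname(x$dissimilarities), 2),
    first_difference = c(NA, round(unname(x$first_differences), 2))
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Suggest the number of clusters from a scree curve
#'
#' Formalises the "last sizeable reduction" reading of a first-difference
#' plot: the suggested k is the largest k whose dissimilarity reduction
#' `delta(k) = D(k-1) - D(k)` exceeds `(1 + tau)` times the median of the
#' reductions at all later k.  After the true number of clusters the
#' reductions level off, so the median of the tail estimates the
#' noise-level reduction and `tau` sets how far above it a drop must
#' stand to count as sizeable.  When no reduction qualifies, `k_min` is
#' returned (a flat curve suggests no cluster structure beyond the
#' smallest k examined).
#'
#' @param curve A `scree_curve` covering at least 3 values of k.
#' @param tau Relative threshold (default 0.5).
#' @return The suggested k.
#' @export
select_k <- function(curve, tau = 0.5) {
  stopifnot(inherits(curve, "scree_curve"))
  ks <- curve$k_values
  if (length(ks) < 3L) stop("scree curve must cover at least 3 values of k")
  fd <- curve$first_differences  # named by the k moved to
  fk <- as.integer(names(fd))
  qualifies <- vapply(seq_along(fd), function(i) {
    later <- fd[fk > fk[i]]
    length(later) > 0 && fd[i] > (1 + tau) * median(later)
  }, logical(1))
  if (!any(qualifies)) return(ks[1])
  max(fk[qualifies])
}

#' Label new profiles with fitted medoids
#'
#' Assigns each profile to its nearest medoid under Euclidean distance,
#' with ties broken toward the lowest medoid index.  This is the portable
#' classifier: a saved set of medoids can label a new cohort without
#' refitting.
#'
#' @param profiles Matrix of profiles to label (m x hours).
#' @param medoid_profiles Matrix of k medoid profiles, or a
#'   `medoid_solution`.
#' @return List with `labels` (1..k) and `distances` (distance to the
#'   assigned medoid).
#' @export
assign_profiles <- function(profiles, medoid_profiles) {
  if (inherits(medoid_profiles, "medoid_solution")) {
    medoid_profiles <- medoid_profiles$medoid_profiles
  }
  stopifnot(ncol(profiles) == ncol(medoid_profiles))
  cross <- vapply(seq_len(nrow(medoid_profiles)), function(c) {
    sqrt(rowSums((profiles - matrix(medoid_profiles[c, ],
                                    nrow = nrow(profiles),
                                    ncol = ncol(profiles),
                                    byrow = TRUE))^2))
  }, numeric(nrow(profiles)))
  cross <- matrix(cross, nrow = nrow(profiles))
  labels <- max.col(-cross, ties.method = "first")
  list(
    labels = labels,
    distances = cross[cbind(seq_len(nrow(profiles)), labels)]
  )
}
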