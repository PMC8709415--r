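#' Euclidean distance between two hourly profiles
#'
#' Plain (not squared) Euclidean distance, the dissimilarity used for
#' clustering throughout.
#'
#' @param a,b Numeric vectors of equal length (168 for weekly profiles).
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  sqrt(sum((a - b)^2))
}

#' Dynamic time warping distance
#'
#' Classical DTW with absolute-difference local cost and unit steps
#' (match, insert, delete), without path-length normalisation.  An
#' optional Sakoe-Chiba band restricts the alignment to a diagonal
#' corridor of the given half-width (in hours); the unconstrained default
#' matches the full-warping comparison used when checking that DTW and
#' Euclidean distances rank profile pairs similarly.
#'
#' @param a,b Non-empty numeric vectors (may differ in length).
#' @param band Optional band half-width, `>= 1`; must be at least the
#'   length difference of the inputs for an alignment to exist.
#' @return Non-negative DTW distance; 0 iff the vectors are identical.
#' @export
dtw_distance <- function(a, b, band = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("inputs must be non-empty")
  if (is.null(band)) {
    band_i <- -1L
  } else {
    if (band < 1) stop("band half-width must be >= 1")
    if (band < abs(length(a) - length(b))) {
      stop("band narrower than the length difference: no feasible alignment")
    }
    band_i <- as.integer(band)
  }
  dtw_cost_cpp(as.numeric(a), as.numeric(b), band_i)
}

#' Pairwise distance matrix over profiles
#'
#' Computes all unordered pairwise distances between the rows of a
#' profile matrix under the Euclidean or DTW metric, optionally on a
#' seeded random subsample of participants (e.g. a 40-profile comparison
#' sample).
#'
#' @param X Numeric matrix, one 168-hour profile per row; row names are
#'   participant ids.
#' @param metric `"euclidean"` or `"dtw"`.
#' @param sample_size Optional number of rows to subsample.
#' @param seed Seed for the subsample draw.
#' @param band Optional DTW band half-width (hours).
#' @return A `distance_matrix`: list with `ids`, `metric`, `entries`
#'   (symmetric matrix with zero diagonal) and `band`.
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "dtw"),
                               sample_size = NULL, seed = NULL,
                               band = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (!is.null(sample_size)) {
    if (sample_size > nrow(X)) stop("sample_size exceeds number of profiles")
    if (!is.null(seed)) set.seed(seed)
    keep <- sort(sample.int(nrow(X), sample_size))
    X <- X[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  entries <- if (metric == "euclidean") {
    as.matrix(dist(X, method = "euclidean"))
  } else {
    dtw_pairwise_cpp(X, if (is.null(band)) -1L else as.integer(band))
  }
  dimnames(entries) <- list(ids, ids)
  structure(
    list(ids = ids, metric = metric, entries = entries, band = band),
    class = "distance_matrix"
  )
}

#' Agreement between two distance matrices
#'
#' Quantifies whether two metrics rank participant pairs similarly: the
#' Spearman rank correlation of the vectorised upper triangles, plus a
#' per-pair table for scatter plotting.  A rank statistic formalises
#' "similar patterns": profiles far apart under one metric should be far
#' apart under the other, regardless of scale.
#'
#' @param d1,d2 `distance_matrix` objects over the same ids in the same
#'   order.
#' @return A `metric_agreement` list: `spearman`, `n_pairs`, `metrics`,
#'   and `pairs` (data frame id1, id2, distance under each metric).
#' @export
metric_agreement <- function(d1, d2) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  if (!identical(d1$ids, d2$ids)) {
    stop("distance matrices cover different participants or orderings")
  }
  ut <- upper.tri(d1$entries)
  ij <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(
    id1 = d1$ids[ij[, 1]],
    id2 = d1$ids[ij[, 2]],
    d1 = d1$entries[ut],
    d2 = d2$entries[ut],
    stringsAsFactors = FALSE
  )
  names(pairs)[3:4] <- c(d1$metric, d2$metric)
  structure(
    list(
      spearman = cor(d1$entries[ut], d2$entries[ut], method = "spearman"),
      n_pairs = nrow(pairs),
      metrics = c(d1$metric, d2$metric),
      pairs = pairs
    ),
    class = "metric_agreement"
  )
}

#' @export
print.metric_agreement <- function(x, ...) {
  cat(sprintf(
    "Metric agreement (%s vs %s): Spearman rho = %.3f over %d pairs\n",
    x$metrics[1], x$metrics[2], x$spearman, x$n_pairs
  ))
  invisible(x)
}
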