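#' Per-cluster average weekly profiles
#'
#' Arithmetic mean of the 168 hourly values over the members of each
#' cluster, with cluster sizes, suitable for plotting the average activity
#' pattern of each group.
#'
#' @param X Profile matrix (participants x 168).
#' @param labels Cluster label per participant (any atomic type).
#' @return List with `means` (clusters x 168 matrix, row names = cluster
#'   labels) and `sizes` (named counts).
#' @export
cluster_mean_profiles <- function(X, labels) {
  stopifnot(nrow(X) == length(labels))
  f <- if (is.factor(labels)) labels else factor(labels)
  sizes <- table(f)
  if (any(sizes == 0)) stop("every cluster must have at least one member")
  means <- rowsum(X, f) / as.vector(sizes)
  list(means = means, sizes = c(sizes))
}

#' Percentage share of each cluster
#'
#' @param sizes Named cluster sizes (counts).
#' @param digits Decimal digits for the printed percentage (half-up).
#' @return Named percentages summing to ~100.
#' @export
cluster_shares <- function(sizes, digits = 1) {
  round_half_up(100 * sizes / sum(sizes), digits)
}

pct_cell <- function(flag, digits = 1) {
  # per-cell denominator: participants with a non-missing value
  n <- sum(!is.na(flag))
  if (n == 0L) stop("empty column group (no non-missing values)")
  round_half_up(100 * sum(flag, na.rm = TRUE) / n, digits)
}

#' Characteristics-by-group composition table
#'
#' For each group (cluster, or any sample membership) and each binary
#' characteristic, the percentage of the group's participants with the
#' characteristic, plus a pooled overall column.  Missing characteristic
#' values are excluded from both numerator and denominator of their cell,
#' with the per-cell denominators reported.  Each row is annotated with
#' its extreme columns (strictly largest and smallest among the group
#' columns; ties mark all tied columns), the machine-readable form of the
#' red/blue heat-mapping used when such tables are displayed.
#'
#' @param membership Group label per participant.
#' @param characteristics Data frame of logical columns (one per
#'   characteristic), rows matching `membership`; a `participant_id`
#'   column is ignored.
#' @param overall_label Name for the pooled column.
#' @return A `composition_table`: `percentages` (characteristics x
#'   groups+overall), `denominators`, `sizes`, `max_col`, `min_col`.
#' @export
composition_table <- function(membership, characteristics,
                              overall_label = "Overall") {
  chars <- characteristics[, setdiff(names(characteristics), "participant_id"),
                           drop = FALSE]
  keep <- vapply(chars, is.logical, logical(1))
  chars <- chars[, keep, drop = FALSE]
  if (ncol(chars) == 0L) stop("no logical characteristic columns found")
  stopifnot(nrow(chars) == length(membership))
  f <- if (is.factor(membership)) membership else factor(membership)
  groups <- levels(f)
  if (any(table(f) == 0)) stop("empty column group")

  cols <- c(groups, overall_label)
  pct <- matrix(NA_real_, nrow = ncol(chars), ncol = length(cols),
                dimnames = list(names(chars), cols))
  den <- pct
  for (ch in names(chars)) {
    v <- chars[[ch]]
    for (g in groups) {
      vg <- v[f == g]
      pct[ch, g] <- pct_cell(vg)
      den[ch, g] <- sum(!is.na(vg))
    }
    pct[ch, overall_label] <- pct_cell(v)
    den[ch, overall_label] <- sum(!is.na(v))
  }
  gp <- pct[, groups, drop = FALSE]
  max_col <- apply(gp, 1, function(r) groups[r == max(r)], simplify = FALSE)
  min_col <- apply(gp, 1, function(r) groups[r == min(r)], simplify = FALSE)
  structure(
    list(
      percentages = pct,
      denominators = den,
      sizes = c(table(f)),
      max_col = max_col,
      min_col = min_col,
      overall_label = overall_label
    ),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  print(round(x$percentages, 1))
  invisible(x)
}

#' Outcome-by-cluster difference table
#'
#' For each outcome category, the percentage distribution of its
#' participants across the clusters, alongside the difference from the
#' cluster shares of all participants pooled.  A positive difference
#' means the outcome is over-represented in that cluster.  Differences
#' are computed on unrounded percentages and then rounded, so each
#' printed row's differences sum to ~0.
#'
#' @param outcome Outcome category per participant (e.g. BMI status).
#'   `NA` outcomes are dropped from the rows but still count toward the
#'   overall cluster shares.
#' @param cluster Cluster label per participant.
#' @param digits Decimal digits (half-up, default 1).
#' @return An `outcome_difference_table`: `percentages` (outcomes x
#'   clusters), `differences`, `overall` (pooled cluster shares) and
#'   `counts`.
#' @export
outcome_difference_table <- function(outcome, cluster, digits = 1) {
  stopifnot(length(outcome) == length(cluster))
  fc <- factor(cluster)
  fo <- factor(outcome)
  overall_raw <- 100 * table(fc) / length(fc)
  counts <- table(fo, fc)
  row_raw <- 100 * sweep(counts, 1, rowSums(counts), "/")
  diffs <- sweep(row_raw, 2, overall_raw, "-")
  structure(
    list(
      percentages = round_half_up(unclass(row_raw), digits),
      differences = round_half_up(unclass(diffs), digits),
      overall = round_half_up(c(overall_raw), digits),
      counts = unclass(counts)
    ),
    class = "outcome_difference_table"
  )
}

#' @export
print.outcome_difference_table <- function(x, ...) {
  m <- matrix(
    sprintf("%.1f%% (%+.1f%%)", x$percentages, x$differences),
    nrow = nrow(x$percentages), dimnames = dimnames(x$percentages)
  )
  print(rbind(m, All = sprintf("%.1f%%", x$overall)), quote = FALSE)
  invisible(x)
}

#' Difference of a printed row percentage from the pooled cluster share
#'
#' Helper for recomputing difference entries when only the printed row
#' percentages and the cluster sizes are at hand: the pooled share is
#' derived from the sizes unrounded, subtracted, then rounded half-up.
#'
#' @param row_pct Percentage of the outcome group in one cluster.
#' @param sizes Named cluster sizes.
#' @param cluster Which cluster `row_pct` refers to.
#' @param digits Decimal digits (default 1).
#' @return The rounded difference in percentage points.
#' @export
difference_vs_overall <- function(row_pct, sizes, cluster, digits = 1) {
  share <- 100 * sizes[[cluster]] / sum(sizes)
  round_half_up(row_pct - share, digits)
}

#' COVID-19 testing outcomes by cluster
#'
#' Per cluster: the number and percentage of participants alive at the
#' reference date, the percentage of the cluster alive and tested, the
#' percentage alive and tested positive, and the positivity rate among
#' tests.  Denominators follow the reporting convention: percent alive
#' uses the cluster size, percent tested and percent positive use the
#' alive count, positivity uses the tested count (undefined, `NA`, when
#' no one in the cluster was tested).
#'
#' @param cluster Cluster label per participant.
#' @param alive,tested,positive Logical status flags per participant;
#'   `positive` implies `tested`.
#' @param digits Decimal digits (half-up, default 1).
#' @return A data frame, one row per cluster plus a pooled `Overall` row.
#' @export
covid_outcome_table <- function(cluster, alive, tested, positive,
                                digits = 1) {
  stopifnot(
    length(alive) == length(cluster), length(tested) == length(cluster),
    length(positive) == length(cluster)
  )
  if (any(positive & !tested, na.rm = TRUE)) {
    stop("inconsistent flags: positive implies tested")
  }
  if (any(tested & !alive, na.rm = TRUE)) {
    stop("inconsistent flags: tested implies alive at the reference date")
  }
  f <- factor(cluster)
  one <- function(idx) {
    n <- length(idx)
    n_alive <- sum(alive[idx])
    n_tested <- sum(tested[idx])
    n_pos <- sum(positive[idx])
    data.frame(
      n = n,
      n_alive = n_alive,
      pct_alive = round_half_up(100 * n_alive / n, digits),
      pct_alive_tested = round_half_up(100 * n_tested / n_alive, digits),
      pct_alive_positive = round_half_up(100 * n_pos / n_alive, digits),
      positivity_rate = if (n_tested == 0) NA_real_ else
        round_half_up(100 * n_pos / n_tested, digits)
    )
  }
  rows <- lapply(levels(f), function(g) one(which(f == g)))
  out <- do.call(rbind, c(rows, list(one(seq_along(cluster)))))
  out <- cbind(cluster = c(levels(f), "Overall"), out)
  rownames(out) <- NULL
  out
}
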