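#' Normalised QSep resolution matrix
#'
#' Divides each raw cluster distance by the *reference* cluster's average
#' within-cluster distance: entry `(i, j)` of the result is
#' `raw(i, j) / raw(i, i)`, i.e. rows are normalised by their diagonal.
#' The diagonal becomes exactly 1 and the matrix is in general no longer
#' symmetric: row `i` reads "how many times further is cluster `j` than
#' cluster `i` is wide". Large off-diagonal values indicate tight,
#' well-separated clusters -- good sub-cellular resolution.
#'
#' @param raw a `ClusterDistanceMatrix` with strictly positive diagonal.
#' @return a `QSepMatrix` (list with `values`, `labels`).
#' @examples
#' # raw [[2,10],[10,2]] normalises to [[1,5],[5,1]]
#' @export
qsep_normalize <- function(raw) {
  stopifnot(inherits(raw, "ClusterDistanceMatrix"))
  w <- diag(raw$values)
  if (any(w <= 0))
    stop("zero within-cluster distance for cluster(s): ",
         paste(raw$labels[w <= 0], collapse = ", "),
         "; normalisation undefined")
  vals <- sweep(raw$values, 1L, w, "/")
  diag(vals) <- 1
  structure(list(values = vals, labels = raw$labels), class = "QSepMatrix")
}

#' @export
print.QSepMatrix <- function(x, ...) {
  cat(sprintf("QSepMatrix: %d clusters, median between = %.3f\n",
              length(x$labels), stats::median(off_diagonal(x))))
  print(round(x$values, 3))
  invisible(x)
}

#' Off-diagonal (between-cluster) entries of a QSep matrix
#'
#' Returns all `k * (k - 1)` ordered normalised between-cluster distances
#' (both `(i, j)` and `(j, i)`, which generally differ).
#'
#' @param q a `QSepMatrix`.
#' @return numeric vector of length `k * (k - 1)`.
#' @export
off_diagonal <- function(q) {
  v <- q$values
  v[row(v) != col(v)]
}

#' Summarise a QSep matrix
#'
#' The headline statistic is the experiment-wide *median* normalised
#' between-cluster distance, pooled over all `k * (k - 1)` ordered
#' off-diagonal entries (the diagonal 1s are excluded). Per-reference-
#' cluster distributions are retained for boxplots.
#'
#' @param q a `QSepMatrix`.
#' @return a `QSepSummary`: list with `median_between`, `per_cluster`
#'   (named list of each reference cluster's normalised distances to the
#'   other clusters), `n_clusters`.
#' @export
qsep_summary <- function(q) {
  stopifnot(inherits(q, "QSepMatrix"))
  k <- length(q$labels)
  if (k < 2L) stop("need at least two clusters")
  per <- lapply(seq_len(k), function(i) q$values[i, -i])
  names(per) <- q$labels
  structure(list(median_between = stats::median(off_diagonal(q)),
                 per_cluster = per, n_clusters = k),
            class = "QSepSummary")
}

#' @export
print.QSepSummary <- function(x, ...) {
  cat(sprintf("QSepSummary: %d clusters, median between = %.3f\n",
              x$n_clusters, x$median_between))
  invisible(x)
}

#' One-call QSep pipeline
#'
#' Convenience wrapper: filter markers to a minimum cluster size, compute
#' the raw cluster distance matrix, normalise, summarise.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`; defaults to the experiment's markers.
#' @param min_markers minimum markers per cluster (default 7); clusters
#'   below the threshold are dissolved before scoring. Use `min_markers =
#'   2` to keep every scoreable cluster.
#' @return list with `raw` (`ClusterDistanceMatrix`), `qsep`
#'   (`QSepMatrix`), `summary` (`QSepSummary`) and `markers` (the filtered
#'   annotation).
#' @export
qsep_score <- function(exp, mk = markers(exp), min_markers = 7L) {
  mk <- filter_min_markers(mk, exp, min_n = min_markers)
  raw <- cluster_distance_matrix(exp, mk)
  q <- qsep_normalize(raw)
  list(raw = raw, qsep = q, summary = qsep_summary(q), markers = mk)
}

#' Compare two QSep score distributions
#'
#' Welch two-sample t-test on the natural-log-transformed off-diagonal
#' normalised distances of two experiments. The log transform makes the
#' ratio-scale QSep scores roughly symmetric; Welch's form is used because
#' the two experiments need not have comparable spread or cluster count.
#'
#' @param a,b `QSepMatrix` objects.
#' @return list with `statistic`, `p_value`, `df`, `mean_log` (group means
#'   on the log scale) and `n` (sample sizes).
#' @export
compare_qsep <- function(a, b) {
  stopifnot(inherits(a, "QSepMatrix"), inherits(b, "QSepMatrix"))
  xa <- off_diagonal(a)
  xb <- off_diagonal(b)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each matrix needs at least two off-diagonal entries")
  if (any(xa <= 0) || any(xb <= 0))
    stop("non-positive normalised distance; log transform undefined")
  tt <- stats::t.test(log(xa), log(xb), var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_log = c(a = mean(log(xa)), b = mean(log(xb))),
       n = c(a = length(xa), b = length(xb)))
}

#' Subset a QSep or raw distance matrix to surviving clusters
#'
#' Because marker-to-marker distances do not depend on other clusters,
#' removing clusters commutes with computing the raw matrix: subsetting
#' the raw matrix and renormalising equals recomputing from profiles
#' restricted to the surviving clusters. This makes removal scans cheap.
#'
#' @param raw a `ClusterDistanceMatrix`.
#' @param keep labels of the clusters to keep (>= 2).
#' @return a `ClusterDistanceMatrix` on `keep`.
#' @export
subset_clusters <- function(raw, keep) {
  stopifnot(inherits(raw, "ClusterDistanceMatrix"))
  if (!all(keep %in% raw$labels))
    stop("unknown cluster label(s): ",
         paste(setdiff(keep, raw$labels), collapse = ", "))
  if (length(keep) < 2L) stop("need at least two surviving clusters")
  structure(list(values = raw$values[keep, keep, drop = FALSE],
                 pair_counts = raw$pair_counts[keep, keep, drop = FALSE],
                 labels = keep),
            class = "ClusterDistanceMatrix")
}

#' Export a QSep summary as JSON
#'
#' @param s a `QSepSummary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qsep_summary <- function(s, path) {
  stopifnot(inherits(s, "QSepSummary"))
  qs <- lapply(s$per_cluster, function(v)
    as.list(stats::quantile(v, c(0, .25, .5, .75, 1))))
  jsonlite::write_json(
    list(n_clusters = s$n_clusters,
         median_between = s$median_between,
         per_cluster_quantiles = qs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
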