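#' Class-removal robustness scan
#'
#' Measures how stable the experiment-wide QSep median is to the choice
#' of annotated sub-cellular classes. For every `r` in `0..max_removed`
#' and every `r`-subset of clusters, the median normalised
#' between-cluster distance is recomputed on the surviving clusters. A
#' resolution metric that merely counts clusters would drift with `r`; a
#' robust one shows medians fluctuating around the full-data baseline,
#' i.e. a near-zero slope of median against number of classes removed.
#'
#' Removal only requires subsetting the raw distance matrix (marker
#' pairwise distances do not depend on other clusters), so the exhaustive
#' scan is cheap: `sum(choose(k, 0:max_removed))` renormalisations.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`; defaults to the experiment's markers.
#' @param max_removed largest number of classes removed (default 3);
#'   requires `k - max_removed >= 2`.
#' @param include_baseline include the zero-removal record in the
#'   least-squares fit (default `TRUE`).
#' @param min_markers minimum markers per cluster before scanning.
#' @return a `RemovalScanResult`: list with `records` (data.frame with
#'   `n_removed`, `removed` label string, `median_between`),
#'   `baseline_median`, `slope`, `intercept`, `max_removed`.
#' @export
class_removal_scan <- function(exp, mk = markers(exp), max_removed = 3L,
                               include_baseline = TRUE, min_markers = 7L) {
  mk <- filter_min_markers(mk, exp, min_n = min_markers)
  raw <- cluster_distance_matrix(exp, mk)
  removal_scan_from_raw(raw, max_removed = max_removed,
                        include_baseline = include_baseline)
}

#' @rdname class_removal_scan
#' @param raw a precomputed `ClusterDistanceMatrix`.
#' @export
removal_scan_from_raw <- function(raw, max_removed = 3L,
                                  include_baseline = TRUE) {
  stopifnot(inherits(raw, "ClusterDistanceMatrix"))
  k <- length(raw$labels)
  if (k - max_removed < 2L)
    stop("removing ", max_removed, " of ", k,
         " clusters leaves fewer than 2")
  med_of <- function(keep)
    stats::median(off_diagonal(qsep_normalize(subset_clusters(raw, keep))))
  recs <- list(data.frame(n_removed = 0L, removed = "",
                          median_between = med_of(raw$labels),
                          stringsAsFactors = FALSE))
  for (r in seq_len(max_removed)) {
    sets <- utils::combn(raw$labels, r, simplify = FALSE)
    recs[[r + 1L]] <- data.frame(
      n_removed = r,
      removed = vapply(sets, paste, character(1), collapse = ";"),
      median_between = vapply(sets, function(s)
        med_of(setdiff(raw$labels, s)), numeric(1)),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  fit_data <- if (include_baseline) records
              else records[records$n_removed > 0L, ]
  fit <- stats::lm(median_between ~ n_removed, data = fit_data)
  structure(list(records = records,
                 baseline_median = records$median_between[1L],
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 max_removed = max_removed),
            class = "RemovalScanResult")
}

#' @export
print.RemovalScanResult <- function(x, ...) {
  cat(sprintf(paste0("RemovalScanResult: %d records (up to %d removed), ",
                     "baseline median %.3f, slope %.4f\n"),
              nrow(x$records), x$max_removed, x$baseline_median, x$slope))
  invisible(x)
}

#' Export removal-scan records as TSV
#'
#' @param scan a `RemovalScanResult`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_removal_scan <- function(scan, path) {
  utils::write.table(scan$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
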