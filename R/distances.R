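#' Euclidean profile distance with missing values
#'
#' Distance between two occupancy profiles of length `p`. When both
#' entries are present in only `m < p` fractions, the sum of squares over
#' the complete fractions is scaled up by `p / m` before taking the square
#' root:
#' \deqn{d(x, y) = \sqrt{\frac{p}{m} \sum_{f \in complete} (x_f - y_f)^2}}
#' so that distances computed on partially observed profiles remain
#' comparable to fully observed ones. With no overlapping fractions
#' (`m = 0`) the distance is undefined and `NA` is returned with a
#' warning; downstream averages drop such pairs. With no missing values
#' this is the textbook Euclidean distance, and the convention coincides
#' with [stats::dist()]'s handling of `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return a non-negative number, or `NA` if the profiles share no
#'   observed fraction.
#' @examples
#' profile_distance(c(0, 0, 0, 0), c(1, 1, 1, 1))        # 2
#' profile_distance(c(1, 2, NA, 4), c(1, 0, 5, 1))       # sqrt(52 / 3)
#' @export
profile_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles have different lengths (", length(x), " vs ",
         length(y), ")")
  p <- length(x)
  ok <- !is.na(x) & !is.na(y)
  m <- sum(ok)
  if (m == 0L) {
    warning("no overlapping observed fractions; distance undefined")
    return(NA_real_)
  }
  sqrt(p / m * sum((x[ok] - y[ok])^2))
}

## All pairwise profile distances for the rows of X, vectorised via the
## cross-product identity sum_complete (x - y)^2 =
##   (X0^2 M') + (M (X0^2)') - 2 X0 X0'  restricted to jointly observed
## fractions, where M masks observed entries and X0 zeroes the missing
## ones. Returns a symmetric n x n matrix with NA where no fraction is
## jointly observed; the diagonal is 0.
.pairwise_distances <- function(X) {
  p <- ncol(X)
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  S <- X0^2
  m <- tcrossprod(M * 1)                    # joint observation counts
  ss <- tcrossprod(S, M) + tcrossprod(M, S) - 2 * tcrossprod(X0)
  ss[ss < 0] <- 0                           # numerical guard
  d <- sqrt(p / m * ss)                     # m == 0 yields NaN -> NA below
  d[m == 0] <- NA_real_
  diag(d) <- ifelse(diag(m) > 0, 0, NA_real_)
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Raw within/between cluster distance matrix
#'
#' Computes, for every pair of marker clusters, the average
#' [profile_distance()] between their member profiles. Diagonal entry
#' `(i, i)` averages over the unordered marker pairs within cluster `i`
#' (self-distances excluded); off-diagonal entry `(i, j)` averages over
#' all cross pairs. The result is symmetric. Pairs whose distance is
#' undefined (no jointly observed fraction) are dropped from both the
#' numerator and the denominator; the effective pair counts are kept in
#' `pair_counts`.
#'
#' Distances are always computed on the raw matrix: missing values are
#' *retained*, not zero-imputed.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`; defaults to the experiment's own
#'   markers.
#' @return a `ClusterDistanceMatrix`: list with `values` and `pair_counts`
#'   (k x k matrices) and `labels`.
#' @seealso [qsep_normalize()] for the normalised resolution matrix.
#' @export
cluster_distance_matrix <- function(exp, mk = markers(exp)) {
  stopifnot(inherits(exp, "ProfileExperiment"),
            inherits(mk, "MarkerAnnotation"))
  labs <- cluster_labels(mk)
  if (length(labs) < 2L)
    stop("need at least two marker clusters")
  asn <- unclass(mk)
  idx <- lapply(labs, function(l) {
    ids <- names(asn)[asn == l]
    ids[ids %in% protein_ids(exp)]
  })
  names(idx) <- labs
  small <- labs[vapply(idx, length, integer(1)) < 2L]
  if (length(small))
    stop("cluster(s) with fewer than 2 markers in the experiment: ",
         paste(small, collapse = ", "))
  all_ids <- unlist(idx, use.names = FALSE)
  D <- .pairwise_distances(exp$values[all_ids, , drop = FALSE])
  k <- length(labs)
  vals <- cnt <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    di <- D[idx[[i]], idx[[i]], drop = FALSE]
    dvec <- di[upper.tri(di)]
    vals[i, i] <- mean(dvec, na.rm = TRUE)
    cnt[i, i] <- sum(!is.na(dvec))
    for (j in seq_len(k)[-seq_len(i)]) {
      dij <- D[idx[[i]], idx[[j]], drop = FALSE]
      vals[i, j] <- vals[j, i] <- mean(dij, na.rm = TRUE)
      cnt[i, j] <- cnt[j, i] <- sum(!is.na(dij))
    }
  }
  if (any(cnt == 0))
    stop("cluster pair(s) with no defined pairwise distance: ",
         paste(apply(which(cnt == 0, arr.ind = TRUE), 1,
                     function(ij) paste(labs[ij], collapse = "/")),
               collapse = ", "))
  structure(list(values = vals, pair_counts = cnt, labels = labs),
            class = "ClusterDistanceMatrix")
}

#' @export
print.ClusterDistanceMatrix <- function(x, ...) {
  cat(sprintf("ClusterDistanceMatrix: %d clusters\n", length(x$labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' Export a cluster distance matrix as TSV
#'
#' Writes the distance values (and, alongside, the per-cell pair counts)
#' with cluster labels as header row and first column.
#'
#' @param x a `ClusterDistanceMatrix` or `QSepMatrix`.
#' @param path output file for the values.
#' @param counts_path optional output file for `pair_counts` (ignored for
#'   `QSepMatrix`).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(x, path, counts_path = NULL) {
  .write_mat <- function(m, f)
    utils::write.table(data.frame(cluster = rownames(m), m,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_mat(x$values, path)
  if (!is.null(counts_path) && !is.null(x$pair_counts))
    .write_mat(x$pair_counts, counts_path)
  invisible(path)
}
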