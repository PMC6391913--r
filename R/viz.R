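#' Principal component projection of occupancy profiles
#'
#' Projects the zero-imputed profile matrix (see [zero_imputed_view()];
#' PCA cannot digest missing values) onto its principal components.
#' Profiles are mean-centred per fraction and, by default, not variance
#' scaled -- the quantitation scale is meaningful in fractionation data.
#' Component signs are fixed deterministically by making each component's
#' largest-magnitude loading positive, so projections are stable across
#' platforms. In a well-resolved experiment the first two components
#' typically carry upwards of 70% of the total variance, and the marker
#' clusters sit at the periphery of the point cloud.
#'
#' @param exp a `ProfileExperiment`.
#' @param n_components number of components to retain
#'   (default `min(p, n)`).
#' @param scale also scale fractions to unit variance (default `FALSE`).
#' @return a `PCAResult`: list with `scores` (proteins x components),
#'   `loadings`, `variance_fraction` (per retained component, relative to
#'   the *total* variance), `components_plotted = c(1, 2)`.
#' @export
pca_project <- function(exp, n_components = NULL, scale = FALSE) {
  stopifnot(inherits(exp, "ProfileExperiment"))
  X <- zero_imputed_view(exp)$values
  nc_max <- min(dim(X))
  if (is.null(n_components)) n_components <- nc_max
  if (n_components < 1L || n_components > nc_max)
    stop("'n_components' must be in 1..", nc_max)
  total_var <- sum(apply(X, 2L, stats::var))
  if (total_var == 0)
    stop("profile matrix is constant; PCA undefined")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale, rank. = n_components)
  if (scale) total_var <- ncol(X)
  ## deterministic sign: largest-|loading| positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, "*")
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = pc$sdev[seq_len(n_components)]^2 /
                   total_var,
                 total_variance = total_var,
                 components_plotted = c(1L, 2L)),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d proteins, %d components; PC1+PC2 = %.2f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$variance_fraction[1:min(2, length(x$variance_fraction))])))
  invisible(x)
}

## open a graphics device chosen by file extension; NULL file = no device
.open_device <- function(file, width = 7, height = 7) {
  if (is.null(file)) return(FALSE)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height,
                              units = "in", res = 150),
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         stop("unsupported figure format: .", ext))
  TRUE
}

.pc_lab <- function(res, i)
  sprintf("PC%d (%.2f%%)", i, 100 * res$variance_fraction[i])

## assign points to a hexagonal lattice (two interleaved rectangular
## lattices, spacing dx horizontally and dx*sqrt(3) vertically, offset by
## half a cell; all six neighbours then sit at distance dx and the Voronoi
## cells are regular hexagons). Returns centres and counts.
.hex_bin <- function(x, y, gridsize = 40) {
  dx <- diff(range(x)) / gridsize
  if (dx == 0) dx <- 1
  dy <- dx * sqrt(3)
  ix1 <- round(x / dx);       iy1 <- round(y / dy)
  ix2 <- round(x / dx - 0.5); iy2 <- round(y / dy - 0.5)
  c1x <- ix1 * dx;           c1y <- iy1 * dy
  c2x <- (ix2 + 0.5) * dx;   c2y <- (iy2 + 0.5) * dy
  use2 <- (x - c2x)^2 + (y - c2y)^2 < (x - c1x)^2 + (y - c1y)^2
  cx <- ifelse(use2, c2x, c1x)
  cy <- ifelse(use2, c2y, c1y)
  key <- paste(signif(cx, 12), signif(cy, 12))
  cnt <- table(key)
  first <- !duplicated(key)
  ord <- match(names(cnt), key[first])
  data.frame(x = cx[first][ord], y = cy[first][ord],
             count = as.integer(cnt), dx = dx, dy = dy)
}

.draw_hex <- function(cx, cy, dx, col) {
  a <- (30 + seq(0, 300, by = 60)) * pi / 180   # pointy-top hexagon
  r <- dx / sqrt(3)                             # circumradius
  for (i in seq_along(cx))
    graphics::polygon(cx[i] + r * cos(a), cy[i] + r * sin(a),
                      col = col[i], border = NA)
}

#' Plot a PCA projection
#'
#' Four diagnostic styles on the same projection: `"plain"` scatter,
#' `"alpha"` (transparency highlights dense cloud structure without any
#' annotation), `"hexbin"` (hexagonal density binning with a count key),
#' and `"annotated"` (markers coloured by cluster, unannotated proteins
#' in grey). Axes are labelled with each component's percentage of total
#' variance. The styles share identical point coordinates -- they differ
#' only in rendering.
#'
#' @param res a `PCAResult`.
#' @param mk a `MarkerAnnotation`; required for `style = "annotated"`.
#' @param style one of `"plain"`, `"alpha"`, `"hexbin"`, `"annotated"`.
#' @param file output figure path (`.png`, `.pdf` or `.svg`), or `NULL`
#'   to draw on the current device.
#' @param components which two components to display (default `c(1, 2)`).
#' @param gridsize hexagons across the x range for `"hexbin"`.
#' @param alpha point opacity for `"alpha"`.
#' @return invisibly, the plot's data layer: a list with the plotted
#'   `x`, `y` (and for hexbin the bin table, for annotated the `legend`
#'   labels), so tests can assert on data rather than pixels.
#' @export
plot_pca <- function(res, mk = NULL,
                     style = c("plain", "alpha", "hexbin", "annotated"),
                     file = NULL, components = NULL, gridsize = 40,
                     alpha = 0.3) {
  stopifnot(inherits(res, "PCAResult"))
  style <- match.arg(style)
  if (style == "annotated" && is.null(mk))
    stop("'annotated' style requires a marker annotation")
  pcs <- if (is.null(components)) res$components_plotted else components
  if (any(pcs > ncol(res$scores)))
    stop("requested components not retained in the projection")
  x <- res$scores[, pcs[1L]]
  y <- res$scores[, pcs[2L]]
  opened <- .open_device(file)
  if (opened) on.exit(grDevices::dev.off())
  xl <- .pc_lab(res, pcs[1L]); yl <- .pc_lab(res, pcs[2L])
  layer <- list(x = x, y = y, style = style)
  if (style == "plain") {
    graphics::plot(x, y, pch = 16, cex = 0.6, xlab = xl, ylab = yl)
  } else if (style == "alpha") {
    graphics::plot(x, y, pch = 16, cex = 0.6, xlab = xl, ylab = yl,
                   col = grDevices::rgb(0, 0, 0, alpha))
  } else if (style == "hexbin") {
    bins <- .hex_bin(x, y, gridsize)
    pal <- grDevices::colorRampPalette(c("grey95", "steelblue",
                                         "darkblue"))(64)
    cols <- pal[pmax(1L, ceiling(64 * bins$count / max(bins$count)))]
    graphics::plot(range(x), range(y), type = "n", xlab = xl, ylab = yl)
    .draw_hex(bins$x, bins$y, bins$dx[1L], cols)
    graphics::legend("topright", title = "count",
                     legend = round(seq(1, max(bins$count), length.out = 4)),
                     fill = pal[round(seq(1, 64, length.out = 4))],
                     bty = "n", cex = 0.8)
    layer$bins <- bins
  } else { # annotated
    lab <- rep(unknown_label(mk), length(x))
    hit <- match(rownames(res$scores), names(mk))
    lab[!is.na(hit)] <- unclass(mk)[hit[!is.na(hit)]]
    labs <- cluster_labels(mk)
    pal <- grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")
    col <- rep("grey80", length(x))
    pch <- rep(1L, length(x))
    for (ci in seq_along(labs)) {
      col[lab == labs[ci]] <- pal[ci]
      pch[lab == labs[ci]] <- 16L
    }
    ## unknowns drawn first so markers sit on top
    ord <- order(lab != unknown_label(mk))
    graphics::plot(x[ord], y[ord], col = col[ord], pch = pch[ord],
                   cex = 0.7, xlab = xl, ylab = yl)
    legend <- c(labs, unknown_label(mk))
    graphics::legend("topright", legend = legend,
                     col = c(pal[seq_along(labs)], "grey80"),
                     pch = c(rep(16L, length(labs)), 1L),
                     bty = "n", cex = 0.7)
    layer$legend <- legend
    layer$colour <- col
  }
  invisible(layer)
}

#' Line plots of full marker profiles
#'
#' Draws one line per marker protein across the ordered fractions,
#' coloured by cluster. Overlaying two or more clusters shows in *which*
#' fractions they differ -- organelles that overlap in a 2-D projection
#' (e.g. mitochondrion vs peroxisome) often separate in a handful of
#' specific fractions.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`.
#' @param clusters character vector (>= 1) of cluster labels to draw.
#' @param file output figure path or `NULL`.
#' @return invisibly, the data layer: list with the plotted profile
#'   `matrix`, per-line `cluster`, and `legend`.
#' @export
plot_profiles <- function(exp, mk = markers(exp), clusters, file = NULL) {
  stopifnot(inherits(exp, "ProfileExperiment"))
  if (missing(clusters) || length(clusters) == 0L)
    stop("at least one cluster label is required")
  bad <- setdiff(clusters, cluster_labels(mk))
  if (length(bad))
    stop("unknown cluster label(s): ", paste(bad, collapse = ", "))
  asn <- unclass(mk)
  ids <- names(asn)[asn %in% clusters]
  ids <- ids[ids %in% protein_ids(exp)]
  M <- exp$values[ids, , drop = FALSE]
  cl <- asn[ids]
  pal <- grDevices::hcl.colors(max(3L, length(clusters)), "Dark 3")
  col <- pal[match(cl, clusters)]
  opened <- .open_device(file, width = 8, height = 5)
  if (opened) on.exit(grDevices::dev.off())
  graphics::matplot(t(M), type = "l", lty = 1,
                    col = grDevices::adjustcolor(col, 0.5),
                    xlab = "fraction", ylab = "relative intensity",
                    xaxt = "n")
  graphics::axis(1, at = seq_len(ncol(M)), labels = fraction_ids(exp),
                 las = 2, cex.axis = 0.7)
  graphics::legend("topright", legend = clusters,
                   col = pal[seq_along(clusters)], lty = 1, bty = "n")
  invisible(list(matrix = M, cluster = cl, legend = clusters))
}

#' Average-distance dendrogram of marker clusters
#'
#' Computes each cluster's mean profile (missing-aware mean per
#' fraction), the pairwise [profile_distance()] between the mean
#' profiles, and an average-linkage hierarchical clustering of the
#' clusters. A quick overview of which sub-cellular niches resemble each
#' other.
#'
#' @param exp a `ProfileExperiment`.
#' @param mk a `MarkerAnnotation`.
#' @param file output figure path or `NULL` for no figure.
#' @return the [stats::hclust] tree, invisibly when a file is written.
#' @export
marker_dendrogram <- function(exp, mk = markers(exp), file = NULL) {
  labs <- cluster_labels(mk)
  if (length(labs) < 2L) stop("need at least two clusters")
  asn <- unclass(mk)
  means <- t(vapply(labs, function(l) {
    ids <- intersect(names(asn)[asn == l], protein_ids(exp))
    colMeans(exp$values[ids, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(exp$values))))
  D <- .pairwise_distances(means)
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  opened <- .open_device(file, width = 7, height = 5)
  if (opened) {
    on.exit(grDevices::dev.off())
    graphics::plot(tree, xlab = "", sub = "",
                   main = "average distance between cluster mean profiles")
  }
  invisible(tree)
}

## shared heatmap painter
.heatmap <- function(m, main, col, zlim) {
  k <- nrow(m)
  graphics::image(seq_len(k), seq_len(k), t(m[rev(seq_len(k)), ]),
                  col = col, zlim = zlim, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(k), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6)
}

#' QSep heatmaps and boxplots
#'
#' Renders the raw and normalised cluster distance matrices as heatmaps
#' (dark blue = small distance, red = large; the normalised panel uses a
#' diverging blue-white-red map) and per-reference-cluster boxplots of
#' the normalised distances, with the within-cluster reference value of 1
#' and the experiment-wide median drawn as vertical lines. Supplying
#' `zlim` fixes the normalised colour scale, allowing several experiments
#' to be rendered on one comparable scale.
#'
#' @param raw a `ClusterDistanceMatrix`.
#' @param q the matching `QSepMatrix`.
#' @param file_prefix path prefix; writes `<prefix>_heatmaps.<ext>` and
#'   `<prefix>_boxplot.<ext>`. `NULL` draws on the current device.
#' @param format figure format when `file_prefix` is used.
#' @param zlim optional shared colour range for the normalised heatmap.
#' @return invisibly, a list with the boxplot data (`per_cluster`),
#'   `median_between`, and the written `files`.
#' @export
plot_qsep <- function(raw, q, file_prefix = NULL, format = "png",
                      zlim = NULL) {
  stopifnot(inherits(raw, "ClusterDistanceMatrix"),
            inherits(q, "QSepMatrix"))
  if (!identical(raw$labels, q$labels))
    stop("cluster labels of raw and normalised matrices differ")
  s <- qsep_summary(q)
  files <- character(0)
  f1 <- if (is.null(file_prefix)) NULL else
    paste0(file_prefix, "_heatmaps.", format)
  opened <- .open_device(f1, width = 10, height = 5)
  if (opened) files <- c(files, f1)
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 6, 3, 1))
  blues <- grDevices::colorRampPalette(c("darkblue", "white"))(64)
  divg <- grDevices::colorRampPalette(c("darkblue", "white", "red"))(64)
  .heatmap(raw$values, "raw distances", rev(blues),
           range(raw$values))
  zl <- if (is.null(zlim)) range(q$values) else zlim
  .heatmap(q$values, "normalised distances", divg, zl)
  graphics::par(op)
  if (opened) grDevices::dev.off()
  f2 <- if (is.null(file_prefix)) NULL else
    paste0(file_prefix, "_boxplot.", format)
  opened <- .open_device(f2, width = 6, height = 5)
  if (opened) {
    files <- c(files, f2)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(rev(s$per_cluster), horizontal = TRUE, las = 1,
                    cex.axis = 0.6, xlab = "normalised distance")
  graphics::abline(v = 1, col = "red", lty = 1)
  graphics::abline(v = s$median_between, col = "grey40", lty = 2)
  invisible(list(per_cluster = s$per_cluster,
                 median_between = s$median_between, files = files))
}
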