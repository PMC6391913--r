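test_that("pca_project conserves variance and matches the eigen oracle", {
  exp <- make_random_exp(n = 6, p = 4, k = 2, seed = 14)
  res <- pca_project(exp)
  X <- exp$values
  # independent oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(res$variance_fraction), ev / sum(ev),
               tolerance = 1e-12)
  # total variance conserved to machine precision
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(res$total_variance, sum(apply(X, 2, var)),
               tolerance = 1e-12)
  # variance fractions non-increasing
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  # retained components store a partial sum <= 1
  res2 <- pca_project(exp, n_components = 2)
  expect_lte(sum(res2$variance_fraction), 1)
  expect_equal(res2$variance_fraction, res$variance_fraction[1:2])
})

test_that("rank-2 data concentrates all variance in two components", {
  set.seed(15)
  basis <- matrix(rnorm(10), 5, 2)
  coords <- matrix(rnorm(40), 20, 2)
  X <- coords %*% t(basis) + matrix(rnorm(5), 20, 5, byrow = TRUE)
  dimnames(X) <- list(sprintf("p%02d", 1:20), paste0("F", 1:5))
  res <- pca_project(profile_experiment(X))
  expect_equal(sum(res$variance_fraction[1:2]), 1, tolerance = 1e-12)
})

test_that("projection is deterministic and row-order invariant", {
  exp <- make_random_exp(n = 15, p = 5, k = 3, seed = 16)
  res <- pca_project(exp)
  # sign convention: the largest-|loading| of each component is positive
  for (j in seq_len(ncol(res$loadings))) {
    l <- res$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  perm <- sample(nrow(exp$values))
  res_p <- pca_project(exp[perm, ])
  expect_equal(res_p$scores[protein_ids(exp), ], res$scores,
               tolerance = 1e-9)
  # constant matrix rejected
  cm <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("F", 1:3)))
  expect_error(pca_project(profile_experiment(cm)), "constant")
  # PCA runs on the zero-imputed view: NAs do not propagate
  exp_na <- make_random_exp(n = 15, p = 5, k = 3, na_rate = 0.2, seed = 16)
  expect_false(anyNA(pca_project(exp_na)$scores))
})

test_that("plot_pca styles share coordinates and render files", {
  tr <- synthetic_truth(k = 2, p = 5, n_per_cluster = 30, n_unknown = 40,
                        delta = 2, sigma = 0.2, seed = 33)
  exp <- generate_experiment(tr)
  res <- pca_project(exp)
  mk <- markers(exp)
  f <- lapply(c(plain = "plain", alpha = "alpha", hexbin = "hexbin",
                annotated = "annotated"), function(s) {
    path <- tempfile(fileext = ".png")
    layer <- plot_pca(res, mk, style = s, file = path)
    expect_true(file.exists(path))
    expect_gt(file.info(path)$size, 0)
    layer
  })
  # plain vs alpha: identical point coordinates, style-only difference
  expect_identical(f$plain$x, f$alpha$x)
  expect_identical(f$plain$y, f$alpha$y)
  # hexbin bin counts account for every protein
  expect_equal(sum(f$hexbin$bins$count), nrow(res$scores))
  # annotated legend lists exactly the cluster labels + unknown
  expect_identical(f$annotated$legend, c("C01", "C02", "unknown"))
  expect_error(plot_pca(res, style = "annotated"), "marker")
  expect_error(plot_pca(res, mk, style = "plain", components = c(1, 99)),
               "components")
  expect_error(plot_pca(res, file = tempfile(fileext = ".bmp")),
               "format")
})

test_that("plot_profiles draws one line per requested marker", {
  tr <- synthetic_truth(k = 3, p = 6, n_per_cluster = 8, n_unknown = 5,
                        delta = 1, sigma = 0.1, seed = 34)
  exp <- generate_experiment(tr)
  mk <- markers(exp)
  path <- tempfile(fileext = ".png")
  layer <- plot_profiles(exp, mk, clusters = c("C01", "C03"), file = path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  expect_equal(nrow(layer$matrix), 16)          # 8 markers x 2 clusters
  expect_setequal(unique(layer$cluster), c("C01", "C03"))
  expect_error(plot_profiles(exp, mk, clusters = character(0)), "at least")
  expect_error(plot_profiles(exp, mk, clusters = "nope"), "nope")
})

test_that("marker_dendrogram clusters mean profiles by average linkage", {
  # k = 2: single merge at the mean-profile distance
  exp <- make_line_exp()
  tree <- marker_dendrogram(exp)
  expect_equal(length(tree$height), 1)
  expect_equal(tree$height, profile_distance(c(1, 0), c(11, 0)))
  # 3 clusters with one far away: the distant cluster merges last
  v <- rbind(a1 = c(0, 0), a2 = c(0.2, 0),
             b1 = c(1, 0), b2 = c(1.2, 0),
             c1 = c(50, 0), c2 = c(50.2, 0))
  colnames(v) <- c("F1", "F2")
  exp3 <- profile_experiment(v, fdata = data.frame(
    markers = rep(c("A", "B", "C"), each = 2), row.names = rownames(v)),
    marker_column = "markers")
  tree3 <- marker_dendrogram(exp3)
  # the distant cluster joins in the final merge, as a singleton
  expect_true(-match("C", tree3$labels) %in% tree3$merge[2, ])
  expect_lt(tree3$height[1], tree3$height[2])
  # permuting protein order leaves the tree topology unchanged
  tree3b <- marker_dendrogram(exp3[sample(6), ])
  expect_equal(tree3$merge, tree3b$merge)
  expect_equal(tree3$height, tree3b$height)
  expect_error(marker_dendrogram(exp3[1:2, ]), "two clusters")
  path <- tempfile(fileext = ".pdf")
  marker_dendrogram(exp3, file = path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
})

test_that("plot_qsep renders heatmaps and boxplots from the summary", {
  exp <- make_random_exp(n = 24, p = 4, k = 4, seed = 18)
  res <- qsep_score(exp, min_markers = 2)
  prefix <- tempfile()
  out <- plot_qsep(res$raw, res$qsep, file_prefix = prefix)
  expect_length(out$files, 2)
  expect_true(all(file.exists(out$files)))
  expect_true(all(file.info(out$files)$size > 0))
  # one boxplot per reference cluster; reference line at the median
  expect_length(out$per_cluster, 4)
  expect_equal(out$median_between, res$summary$median_between)
  # label mismatch rejected
  sub <- subset_clusters(res$raw, c("K1", "K2"))
  expect_error(plot_qsep(sub, res$qsep), "labels")
})
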