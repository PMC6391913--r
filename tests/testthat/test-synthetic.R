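test_that("generation is reproducible and honours the stated geometry", {
  tr <- synthetic_truth(k = 4, p = 6, n_per_cluster = 10, n_unknown = 20,
                        delta = 2, sigma = 0.1, missing_rate = 0.1,
                        seed = 99)
  e1 <- generate_experiment(tr)
  e2 <- generate_experiment(tr)
  expect_identical(e1$values, e2$values)           # bitwise reproducible
  expect_identical(e1$fdata, e2$fdata)
  expect_equal(dim(e1), c(4 * 10 + 20, 6))
  # simplex centres: all pairwise distances exactly delta
  expect_equal(max(abs(dist(tr$centers) - 2)), 0, tolerance = 1e-12)
  tab <- marker_table(markers(e1))
  expect_equal(as.integer(tab), rep(10L, 4))
  # generator restores the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(generate_experiment(tr))
  expect_identical(.Random.seed, before)
})

test_that("missingness matches the nominal rate within binomial noise", {
  tr <- synthetic_truth(k = 3, p = 10, n_per_cluster = 40, n_unknown = 0,
                        delta = 1, sigma = 0.1, missing_rate = 0.2,
                        seed = 5)
  e <- generate_experiment(tr)
  n_cells <- prod(dim(e))
  se <- sqrt(0.2 * 0.8 / n_cells)
  expect_lt(abs(missing_fraction(e) - 0.2), 4 * se)
})

test_that("sigma = 0 collapses clusters to points", {
  tr <- synthetic_truth(k = 3, p = 4, n_per_cluster = 5, n_unknown = 0,
                        delta = 1, sigma = 0, missing_rate = 0, seed = 2)
  e <- generate_experiment(tr)
  raw <- cluster_distance_matrix(e)
  expect_equal(unname(diag(raw$values)), rep(0, 3))
  expect_error(qsep_normalize(raw), "zero within")
})

test_that("within-cluster distances recover the chi closed form", {
  # E d = 2 sigma gamma((p+1)/2) / gamma(p/2); p = 10, sigma = 0.05
  expect_equal(expected_within_distance(10, 0.05),
               2 * 0.05 * gamma(5.5) / gamma(5), tolerance = 1e-12)
  tr <- synthetic_truth(k = 2, p = 10, n_per_cluster = 50, n_unknown = 0,
                        delta = 5, sigma = 0.05, missing_rate = 0,
                        seed = 31)
  e <- generate_experiment(tr)
  raw <- cluster_distance_matrix(e)
  expect_equal(mean(diag(raw$values)), expected_within_distance(10, 0.05),
               tolerance = 0.02)
})

test_that("normalised distances scale as delta / sigma", {
  med_at <- function(sigma, delta = 4, seed = 17) {
    tr <- synthetic_truth(k = 3, p = 10, n_per_cluster = 30, n_unknown = 0,
                          delta = delta, sigma = sigma, seed = seed)
    qsep_score(generate_experiment(tr),
               min_markers = 2)$summary$median_between
  }
  m1 <- med_at(0.05)
  m2 <- med_at(0.10)
  # doubling sigma at fixed large delta halves the normalised distances
  expect_equal(m1 / m2, 2, tolerance = 0.1)
  # and the large-delta asymptote is delta / E[within]
  expect_equal(m1, 4 / expected_within_distance(10, 0.05),
               tolerance = 0.05)
})

test_that("separation_sweep tracks separation monotonically", {
  base <- synthetic_truth(k = 3, p = 10, n_per_cluster = 25,
                          n_unknown = 10, delta = 1, sigma = 0.05,
                          seed = 21)
  sw <- separation_sweep(base, c(0.2, 0.5, 1, 2))
  expect_equal(sw$delta, c(0.2, 0.5, 1, 2))
  expect_true(all(diff(sw$median_between) > 0))     # strictly increasing
  one <- separation_sweep(base, 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$median_between, sw$median_between[3])
})

test_that("coincident clusters give a median near 1", {
  base <- synthetic_truth(k = 3, p = 10, n_per_cluster = 30,
                          n_unknown = 0, delta = 1, sigma = 0.05,
                          seed = 23)
  sw <- separation_sweep(base, 0)
  expect_lt(abs(sw$median_between - 1), 0.1)
})

test_that("truth validation rejects impossible parameters", {
  expect_error(synthetic_truth(k = 1), "at least 2")
  expect_error(synthetic_truth(n_per_cluster = 1), "pairs")
  expect_error(synthetic_truth(missing_rate = 1), "missing_rate")
  expect_error(synthetic_truth(sigma = -1), "non-negative")
  expect_error(synthetic_truth(k = 12, p = 10), "k <= p")
  # random placement honours the minimum separation
  tr <- synthetic_truth(k = 4, p = 6, delta = 1.5, centers = "random",
                        seed = 3)
  expect_gte(min(dist(tr$centers)), 1.5 - 1e-8)
})

test_that("row normalisation emulates relative occupancy data", {
  tr <- synthetic_truth(k = 3, p = 5, n_per_cluster = 8, n_unknown = 0,
                        delta = 1, sigma = 0.05, seed = 4,
                        normalise_rows = TRUE)
  e <- generate_experiment(tr)
  expect_equal(unname(rowSums(abs(e$values))), rep(1, nrow(e$values)),
               tolerance = 1e-12)
})
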