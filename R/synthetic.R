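#' Ground truth for a synthetic marker-structured dataset
#'
#' Describes a simulated fractionation experiment: `k` isotropic Gaussian
#' marker clusters in `p`-dimensional fraction space with a controlled
#' minimum centre separation `delta`, within-cluster standard deviation
#' `sigma`, a pool of unannotated background proteins, and
#' missing-at-random entries. By default the centres sit on a scaled
#' simplex (all pairwise centre distances exactly `delta`, requires
#' `k <= p`), so "separation" is the single scalar `delta`; the
#' `"random"` placement mode gives irregular geometries with pairwise
#' distances >= `delta`.
#'
#' @param k number of clusters (>= 2).
#' @param p number of fractions (>= 2).
#' @param n_per_cluster markers per cluster (>= 2).
#' @param n_unknown unannotated background proteins.
#' @param delta minimum pairwise centre separation.
#' @param sigma isotropic within-cluster standard deviation (>= 0).
#' @param missing_rate per-entry probability of missingness, in `[0, 1)`.
#' @param seed integer RNG seed; generation is bitwise reproducible.
#' @param centers `"simplex"` (default) or `"random"` placement; or a
#'   precomputed `k x p` matrix.
#' @param normalise_rows scale each profile to sum 1 (emulates relative
#'   occupancy data); off by default, QSep is geometry-agnostic.
#' @return a `SyntheticTruth` list.
#' @seealso [generate_experiment()], [separation_sweep()]
#' @export
synthetic_truth <- function(k = 5L, p = 10L, n_per_cluster = 30L,
                            n_unknown = 100L, delta = 1, sigma = 0.1,
                            missing_rate = 0, seed = 1L,
                            centers = c("simplex", "random"),
                            normalise_rows = FALSE) {
  if (k < 2L) stop("'k' must be at least 2")
  if (p < 2L) stop("'p' must be at least 2")
  if (n_per_cluster < 2L)
    stop("'n_per_cluster' must be at least 2 (distances need pairs)")
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  if (is.matrix(centers)) {
    if (!all(dim(centers) == c(k, p)))
      stop("'centers' matrix must be k x p")
    C <- centers
  } else {
    mode <- match.arg(centers)
    C <- switch(mode,
      simplex = {
        if (k > p) stop("simplex placement needs k <= p")
        ## delta / sqrt(2) * e_i: all pairwise distances exactly delta
        diag(rep(delta / sqrt(2), k), nrow = k, ncol = p)
      },
      random = {
        set.seed(seed %% .Machine$integer.max)
        for (try in 1:100) {
          Cc <- matrix(stats::rnorm(k * p, sd = delta), k, p)
          if (k < 2L || min(stats::dist(Cc)) >= delta) break
          ## rescale to enforce the minimum separation
          Cc <- Cc * (delta / min(stats::dist(Cc)))
          break
        }
        Cc
      })
  }
  if (k >= 2L && delta > 0 && min(stats::dist(C)) < delta - 1e-8)
    stop("centre placement violates the minimum separation")
  structure(list(k = k, p = p, n_per_cluster = n_per_cluster,
                 n_unknown = n_unknown, delta = delta, sigma = sigma,
                 missing_rate = missing_rate, seed = seed, centers = C,
                 normalise_rows = normalise_rows),
            class = "SyntheticTruth")
}

#' Generate a synthetic profile experiment from a ground truth
#'
#' Marker proteins are drawn from isotropic Gaussians
#' `N(centre_c, sigma^2 I)`; background ("unknown") proteins are drawn
#' from a mixture: with probability 0.3 from a diffuse Gaussian centred
#' on the centroid of the cluster centres with standard deviation
#' `delta`, otherwise from a randomly chosen cluster with twice the
#' marker dispersion (emulating residents not in the curated marker
#' list). Entries are then masked missing independently with probability
#' `missing_rate`. The generator consumes a single RNG stream seeded from
#' `truth$seed` and restores the caller's RNG state on exit.
#'
#' @param truth a `SyntheticTruth`.
#' @return an annotated `ProfileExperiment` (marker column `"markers"`,
#'   cluster labels `"C01"`, `"C02"`, ...); the truth is attached as
#'   attribute `"truth"`.
#' @export
generate_experiment <- function(truth) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(truth$seed %% .Machine$integer.max)
  k <- truth$k; p <- truth$p; n <- truth$n_per_cluster
  labs <- sprintf("C%02d", seq_len(k))
  Xm <- truth$centers[rep(seq_len(k), each = n), , drop = FALSE] +
    matrix(stats::rnorm(k * n * p, sd = truth$sigma), k * n, p)
  lab <- rep(labs, each = n)
  if (truth$n_unknown > 0L) {
    nu <- truth$n_unknown
    centroid <- colMeans(truth$centers)
    diffuse <- stats::runif(nu) < 0.3
    src <- sample.int(k, nu, replace = TRUE)
    mu <- truth$centers[src, , drop = FALSE]
    mu[diffuse, ] <- matrix(centroid, sum(diffuse), p, byrow = TRUE)
    sd_u <- ifelse(diffuse, max(truth$delta, truth$sigma), 2 * truth$sigma)
    Xu <- mu + matrix(stats::rnorm(nu * p), nu, p) * sd_u
    X <- rbind(Xm, Xu)
    lab <- c(lab, rep(NA_character_, nu))
  } else {
    X <- Xm
  }
  if (truth$normalise_rows) {
    rs <- rowSums(abs(X))
    rs[rs == 0] <- 1
    X <- X / rs
  }
  if (truth$missing_rate > 0) {
    mask <- matrix(stats::runif(length(X)) < truth$missing_rate,
                   nrow(X), ncol(X))
    X[mask] <- NA_real_
  }
  dimnames(X) <- list(sprintf("prot%04d", seq_len(nrow(X))),
                      sprintf("F%02d", seq_len(p)))
  names(lab) <- rownames(X)
  exp <- profile_experiment(X,
                            fdata = data.frame(markers = ifelse(is.na(lab),
                                                                "unknown", lab),
                                               row.names = rownames(X)),
                            marker_column = "markers")
  attr(exp, "truth") <- truth
  exp
}

#' QSep median across a grid of cluster separations
#'
#' Regenerates the synthetic experiment at each separation `delta`
#' (same seed, same other parameters) and records the experiment-wide
#' median normalised between-cluster distance. At fixed dispersion the
#' median should increase with separation; this sweep operationalises
#' "tight, distant clusters score high".
#'
#' @param base a `SyntheticTruth` used as template.
#' @param deltas numeric vector of separations.
#' @param min_markers minimum markers per cluster when scoring (default 2,
#'   i.e. no extra filtering of the simulated clusters).
#' @return data.frame with columns `delta`, `median_between`.
#' @export
separation_sweep <- function(base, deltas, min_markers = 2L) {
  stopifnot(inherits(base, "SyntheticTruth"))
  med <- vapply(deltas, function(d) {
    tr <- synthetic_truth(k = base$k, p = base$p,
                          n_per_cluster = base$n_per_cluster,
                          n_unknown = base$n_unknown, delta = d,
                          sigma = base$sigma,
                          missing_rate = base$missing_rate,
                          seed = base$seed,
                          normalise_rows = base$normalise_rows)
    exp <- generate_experiment(tr)
    qsep_score(exp, min_markers = min_markers)$summary$median_between
  }, numeric(1))
  data.frame(delta = deltas, median_between = med)
}

#' Expected within-cluster pairwise distance of a Gaussian cluster
#'
#' For an isotropic Gaussian cluster in `p` dimensions with standard
#' deviation `sigma`, the difference of two members is
#' `N(0, 2 sigma^2 I)`, so the pairwise distance is `sigma * sqrt(2)`
#' times a chi distribution with `p` degrees of freedom, with mean
#' `2 * sigma * gamma((p + 1) / 2) / gamma(p / 2)`. Used as the
#' closed-form oracle for parameter-recovery checks.
#'
#' @param p dimensionality.
#' @param sigma within-cluster standard deviation.
#' @return the expected pairwise distance.
#' @export
expected_within_distance <- function(p, sigma) {
  2 * sigma * exp(lgamma((p + 1) / 2) - lgamma(p / 2))
}
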