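# Shared fixtures and independent oracles. The oracles deliberately use
# naive scalar loops so they stay independent of the vectorised
# implementation they check.

# scaled pairwise-complete Euclidean distance, written out longhand
oracle_dist <- function(x, y) {
  p <- length(x)
  s <- 0
  m <- 0
  for (f in seq_len(p)) {
    if (!is.na(x[f]) && !is.na(y[f])) {
      s <- s + (x[f] - y[f])^2
      m <- m + 1
    }
  }
  if (m == 0) return(NA_real_)
  sqrt(p / m * s)
}

# brute-force double loop over all marker pairs
oracle_cdm <- function(exp, mk) {
  labs <- cluster_labels(mk)
  asn <- unclass(mk)
  out <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      a <- intersect(names(asn)[asn == labs[i]], protein_ids(exp))
      b <- intersect(names(asn)[asn == labs[j]], protein_ids(exp))
      ds <- c()
      for (pa in a) {
        for (pb in b) {
          if (i == j && pa >= pb) next   # unordered, no self pairs
          ds <- c(ds, oracle_dist(exp$values[pa, ], exp$values[pb, ]))
        }
      }
      out[i, j] <- mean(ds, na.rm = TRUE)
    }
  }
  out
}

# tiny annotated experiment: 2 clusters on a line (second fraction 0),
# reproducing within A = 2, between = 10 by construction
make_line_exp <- function() {
  v <- matrix(c(0, 2, 10, 12,
                0, 0, 0, 0), ncol = 2,
              dimnames = list(c("a1", "a2", "b1", "b2"), c("F1", "F2")))
  fd <- data.frame(markers = c("A", "A", "B", "B"),
                   row.names = rownames(v))
  profile_experiment(v, fdata = fd, marker_column = "markers")
}

# random annotated experiment with optional missingness
make_random_exp <- function(n = 18, p = 5, k = 3, na_rate = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("pr%02d", 1:n), paste0("F", 1:p)))
  if (na_rate > 0)
    v[matrix(runif(n * p) < na_rate, n, p)] <- NA
  lab <- rep(paste0("K", seq_len(k)), length.out = n)
  profile_experiment(v, fdata = data.frame(markers = lab,
                                           row.names = rownames(v)),
                     marker_column = "markers")
}

# fully symmetric 3-cluster toy: point-pair clusters displaced radially
# on an equilateral triangle, so the whole configuration is invariant
# under 120-degree rotation -- all within distances equal, all pairwise
# between-cluster mean distances equal
make_symmetric_raw <- function() {
  ang <- c(90, 210, 330) * pi / 180
  C <- 10 * cbind(cos(ang), sin(ang))
  v <- rbind(C * 1.05, C * 0.95)
  rownames(v) <- sprintf("p%d", 1:6)
  colnames(v) <- c("F1", "F2")
  lab <- rep(c("A", "B", "C"), 2)
  exp <- profile_experiment(v, fdata = data.frame(markers = lab,
                                                  row.names = rownames(v)),
                            marker_column = "markers")
  cluster_distance_matrix(exp)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
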