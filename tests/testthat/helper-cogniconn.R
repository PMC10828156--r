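# Shared fixtures and independent oracles for the test suite.

# Triple-loop brute-force nodal metrics: the independent oracle for the
# vectorized implementation. Denominator: nonzero within-network unordered
# pairs of the node's own network (subject-specific), 0 -> metric 0.
brute_force_metrics <- function(m, network_of) {
  n <- nrow(m)
  within <- numeric(n); inter <- numeric(n)
  for (i in seq_len(n)) {
    g <- network_of[i]
    eg <- 0L
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && network_of[a] == g && network_of[b] == g && m[a, b] != 0)
        eg <- eg + 1L
    }
    wsum <- 0; bsum <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (network_of[j] == g) wsum <- wsum + m[i, j]
      else bsum <- bsum + m[i, j]
    }
    within[i] <- if (eg == 0) 0 else wsum / eg
    inter[i] <- if (eg == 0) 0 else bsum / eg
  }
  ratio <- ifelse(inter == 0, 0, within / inter)
  list(within = within, inter = inter, ratio = ratio)
}

# Random symmetric non-negative weighted graph with zero diagonal.
random_toy_graph <- function(n, density = 0.5) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- ifelse(runif(sum(ut)) < density, round(runif(sum(ut), 0.1, 3), 3), 0)
  m + t(m)
}

# Small labelled feature matrix for ML tests.
toy_features <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%04d", seq_len(n)),
                                paste0("f", seq_len(p))))
  })
  X
}

# Quick small cohort used by several files.
tiny_cohort <- function(n_subjects = 40, n_nodes = 20, seed = 11, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, n_nodes = n_nodes,
                                n_timepoints = 60, seed = seed, ...))
}
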