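test_that("correlation_matrix matches a closed-form Pearson oracle", {
  panel <- rbind(c(1, 2, 3, 4, 5),
                 c(2, 1, 4, 3, 6),
                 c(5, 4, 3, 2, 1))
  fc <- correlation_matrix(panel)
  oracle <- function(a, b) {
    ca <- a - mean(a); cb <- b - mean(b)
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(fc$matrix[i, j], oracle(panel[i, ], panel[j, ]),
                 tolerance = 1e-12)
  # identical rows correlate at 1 (read off before diagonal zeroing)
  fc2 <- correlation_matrix(rbind(panel[1, ], panel[1, ], panel[2, ]))
  expect_equal(fc2$matrix[1, 2], 1)
  # zero-variance node flagged, correlations zeroed
  expect_warning(fcz <- correlation_matrix(rbind(panel, 7)), "zero-variance")
  expect_equal(fcz$matrix[4, ], rep(0, 4))
})

test_that("fisher_z is atanh with zero fixed point and clipping", {
  expect_equal(fisher_z(matrix(0, 2, 2)), matrix(0, 2, 2))
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(fisher_z(m)[1, 2], atanh(0.5), tolerance = 1e-12)
  # monotone on random grids: r1 < r2 => z1 < z2
  withr::with_seed(8, r <- sort(runif(50, -0.99, 0.99)))
  grid <- matrix(0, 51, 51)
  grid[1, -1] <- r; grid[-1, 1] <- r
  zg <- fisher_z(grid)
  expect_true(all(diff(zg[1, -1]) > 0))
  mm <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_warning(zc <- fisher_z(mm), "clipped")
  expect_true(is.finite(zc[1, 2]))
})

test_that("positive/negative parts decompose any matrix", {
  withr::with_seed(3, m <- matrix(rnorm(9), 3, 3))
  m <- m + t(m); diag(m) <- 0
  p <- positive_part(m); n <- negative_part(m)
  expect_true(all(p >= 0) && all(n >= 0))
  expect_equal(p - n, m, tolerance = 1e-15)
  expect_equal(positive_part(-abs(m)), matrix(0, 3, 3))
  # elementwise 3x3 example
  x <- matrix(c(0, 1.5, -2, 1.5, 0, 0.2, -2, 0.2, 0), 3, 3)
  expect_equal(positive_part(x)[1, 3], 0)
  expect_equal(negative_part(x)[1, 3], 2)
})

test_that("log10_sc preserves zeros, order, and rejects negatives", {
  m <- matrix(c(0, 9, 9, 0), 2, 2)
  expect_equal(log10_sc(m)[1, 2], 1)      # log10(1 + 9)
  expect_equal(log10_sc(m)[1, 1], 0)
  w <- sort(runif(20, 0, 100))
  expect_true(all(diff(log10_sc(matrix(w, 1))) > 0))
  expect_equal(log10_sc(matrix(c(0, 10, 10, 0), 2, 2),
                        zero_safe = FALSE)[1, 2], 1)
  expect_error(log10_sc(matrix(-1, 1, 1)), "negative")
})

test_that("nodal metrics equal the brute-force oracle on toy graphs", {
  # 6-node graph, 2 networks of 3, hand-set weights
  m <- matrix(0, 6, 6)
  m[1, 2] <- 2; m[2, 3] <- 1; m[4, 5] <- 3; m[1, 4] <- 0.5; m[3, 6] <- 1.5
  m <- m + t(m)
  net <- c(1, 1, 1, 2, 2, 2)
  parc <- structure(list(n_nodes = 6L, n_networks = 2L, network_of = net,
                         network_names = c("a", "b"), centroids = NULL),
                    class = "parcellation")
  bf <- brute_force_metrics(m, net)
  expect_equal(as.numeric(within_network_connectivity(m, parc)), bf$within,
               tolerance = 1e-14)
  expect_equal(as.numeric(inter_network_connectivity(m, parc)), bf$inter,
               tolerance = 1e-14)
  nm <- nodal_metrics(m, parc)
  expect_equal(as.numeric(nm$ratio), bf$ratio, tolerance = 1e-14)

  # single-network parcellation: inter is all-zero
  parc1 <- generate_parcellation(6, 1, 1)
  expect_equal(as.numeric(inter_network_connectivity(m, parc1)), rep(0, 6))
  # all-zero matrix: all-zero metrics (E_g = 0 rule)
  expect_equal(as.numeric(within_network_connectivity(matrix(0, 6, 6), parc)),
               rep(0, 6))
  expect_error(within_network_connectivity(m[1:5, 1:5], parc), "mismatch")
})

test_that("metric invariants hold on random graphs", {
  withr::with_seed(99, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      k <- sample(1:3, 1)
      parc <- generate_parcellation(n, k, seed = rep)
      m <- random_toy_graph(n)
      nm <- nodal_numerators <- cogniconn:::nodal_numerators(m, parc)
      # strength decomposition: within + inter numerators = nodal strength
      expect_equal(nodal_numerators$within_num + nodal_numerators$inter_num,
                   rowSums(m), tolerance = 1e-12)
      bf <- brute_force_metrics(m, parc$network_of)
      expect_equal(as.numeric(within_network_connectivity(m, parc)),
                   bf$within, tolerance = 1e-12)
    }
  })
})

test_that("denominator switches change only the normalization", {
  parc <- generate_parcellation(8, 2, seed = 1)
  withr::with_seed(5, m <- random_toy_graph(8, density = 0.6))
  w_subj <- within_network_connectivity(m, parc)
  w_all <- within_network_connectivity(m, parc, denominator = "all_pairs")
  w_dbl <- within_network_connectivity(m, parc, double_count = TRUE)
  expect_equal(as.numeric(w_dbl) * 2, as.numeric(w_subj), tolerance = 1e-12)
  # all-pairs denominator >= subject-edge count => values <=
  expect_true(all(as.numeric(w_all) <= as.numeric(w_subj) + 1e-12))
})

test_that("ratio_score divides elementwise with the zero rule", {
  r <- ratio_score(c(2, 0), c(4, 0))
  expect_equal(as.numeric(r), c(0.5, 0))
  expect_equal(attr(r, "zero_inter"), 2L)
  w <- c(1.2, 3, 0.5)
  expect_equal(as.numeric(ratio_score(w, w)), rep(1, 3))
  expect_error(ratio_score(1:3, 1:2), "equal length")
})

test_that("assemble_feature_set reproduces the printed column arithmetic", {
  n_sub <- 3; n_nodes <- 10
  parc <- generate_parcellation(n_nodes, 2, seed = 1)
  mk <- function(seed) {
    withr::with_seed(seed, {
      lapply(c(within = 1, inter = 2, ratio = 3), function(i) {
        m <- matrix(runif(n_sub * n_nodes), n_sub, n_nodes)
        rownames(m) <- sprintf("s%d", 1:n_sub)
        m
      })
    })
  }
  fc <- mk(1); sc <- mk(2); neg <- mk(3)
  gmv <- fc$within * 100
  expect_equal(ncol(assemble_feature_set("A", fc, sc, gmv, parc)$values),
               5 * n_nodes)
  expect_equal(ncol(assemble_feature_set("B", fc, sc, gmv, parc)$values),
               3 * n_nodes)
  expect_equal(ncol(assemble_feature_set("C", fc, sc, gmv, parc,
                                         fc_neg_metrics = neg)$values),
               7 * n_nodes)
  expect_equal(ncol(assemble_feature_set("full", fc, sc, gmv, parc)$values),
               7 * n_nodes)
  extra <- matrix(rnorm(n_sub * 3), n_sub, 3,
                  dimnames = list(sprintf("s%d", 1:n_sub), NULL))
  fmx <- assemble_feature_set("A", fc, sc, gmv, parc,
                              extra_demographics = extra)
  expect_equal(ncol(fmx$values), 5 * n_nodes + 3)
  expect_equal(nrow(fmx$feature_meta), ncol(fmx$values))
  expect_error(assemble_feature_set("C", fc, sc, gmv, parc), "negative-FC")
  bad <- fc; rownames(bad$within) <- c("x", "y", "z")
  expect_error(assemble_feature_set("A", bad, sc, gmv, parc), "mismatch")
})
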