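test_that("multimodal bonus follows its defining arithmetic", {
  b <- multimodal_bonus(0.14, c(0.11, 0.05, 0.08))
  expect_equal(b$b_best, 0.03)
  expect_equal(b$b_all, 0.06)
  # all singles equal -> b_all == b_best
  be <- multimodal_bonus(0.2, rep(0.1, 4))
  expect_equal(be$b_all, be$b_best)
  # MAE basis: signs flipped so positive = multimodal better
  bm <- multimodal_bonus(0.7, c(0.8, 0.9), basis = "mae")
  expect_equal(bm$b_best, 0.1, tolerance = 1e-12)
  expect_equal(bm$b_all, 0.15, tolerance = 1e-12)
  expect_error(multimodal_bonus(0.1, numeric(0)), "at least one")
})

test_that("b_best <= b_all universally on random tuples", {
  withr::with_seed(14, {
    for (i in 1:1000) {
      multi <- rnorm(1)
      singles <- rnorm(sample(1:6, 1))
      b <- multimodal_bonus(multi, singles)
      expect_lte(b$b_best, b$b_all + 1e-15)
      bm <- multimodal_bonus(multi, singles, basis = "mae")
      expect_lte(bm$b_best, bm$b_all + 1e-15)
    }
  })
})

fake_run <- function(weights, names) {
  structure(list(weights = weights, feature_names = names,
                 algorithm = "fake"), class = "fold_results")
}

test_that("feature importance intersection equals the set oracle", {
  nm <- paste0("f", 1:10)
  w1 <- matrix(rep(c(10, 9, 8, 1, 1, 1, 1, 1, 1, 1), each = 3), 3, 10,
               byrow = FALSE)
  w2 <- matrix(rep(c(10, 1, 8, 9, 1, 1, 1, 1, 1, 1), each = 3), 3, 10)
  runs <- list(a = fake_run(w1, nm), b = fake_run(w2, nm))
  it <- feature_importance_concat(runs, top_k = 3)
  expect_setequal(it$surviving, c("f1", "f3"))   # oracle: {f1,f2,f3} ∩ {f1,f4,f3}
  # intersection is a subset of every per-config top list
  for (pc in it$per_config)
    expect_true(all(it$surviving %in% pc$feature))
  # adding a configuration can only shrink or preserve the intersection
  w3 <- matrix(rep(c(10, 1, 1, 1, 8, 9, 1, 1, 1, 1), each = 3), 3, 10)
  it3 <- feature_importance_concat(c(runs, list(c = fake_run(w3, nm))),
                                   top_k = 3)
  expect_true(all(it3$surviving %in% it$surviving))
})

test_that("dominant planted features survive a real importance intersection", {
  X <- toy_features(90, 12, seed = 15)
  withr::with_seed(16, y <- 3 * X[, 4] + rnorm(90, 0, 0.3))
  plan <- make_cv_plan(rownames(X), outer_k = 3, repeats = 1, inner_k = 3,
                       seed = 17)
  runs <- list(
    ridge = fit_predict_concat(X, y, model_config("ridge"), plan,
                               keep_weights = TRUE),
    lasso = fit_predict_concat(X, y, model_config("lasso"), plan,
                               keep_weights = TRUE))
  it <- feature_importance_concat(runs, top_k = 3)
  expect_true("f4" %in% it$surviving)
})

test_that("stacking modality importance ranks the informative modality first", {
  withr::with_seed(18, {
    X <- toy_features(120, 30, seed = 19)
    y <- drop(X[, 1:5] %*% rep(1, 5)) + rnorm(120, 0, 0.5)
  })
  plan <- make_cv_plan(rownames(X), outer_k = 4, repeats = 1, inner_k = 3,
                       seed = 20)
  mods <- list(info = X[, 1:10], noise1 = X[, 11:20], noise2 = X[, 21:30])
  run <- fit_predict_stacking(mods, y, model_config("ridge"), plan,
                              meta_grid = build_grid("rf")[c(1, 5), ])
  mi <- modality_importance_stacking(list(run))
  expect_match(mi$modal_ranking[1], "^info")
  expect_equal(colnames(mi$mean_importance), c("info", "noise1", "noise2"))
})

test_that("extreme groups pick exact quantile blocks with rank tie-breaks", {
  g <- extreme_groups(seq_len(100))
  expect_equal(sum(g == 1, na.rm = TRUE), 25)
  expect_equal(sum(g == 0, na.rm = TRUE), 25)
  expect_equal(sum(is.na(g)), 50)
  g8 <- extreme_groups(1:8)
  expect_equal(which(g8 == 1), c(7, 8))
  expect_equal(which(g8 == 0), c(1, 2))
  # ties at the cutoff: lower index wins membership
  gt <- extreme_groups(c(1, 1, 1, 1, 5, 5, 9, 9, 9, 9, 2, 8), quantile = 0.25)
  expect_equal(sum(gt == 0, na.rm = TRUE), 3)
  expect_true(gt[1] == 0 && gt[2] == 0)
  expect_error(extreme_groups(1:5), "at least 8")
})

test_that("propensity matching pairs across groups and balances covariates", {
  # identical covariate rows across groups: perfect pairing, all SMD 0
  cov <- data.frame(age = rep(c(60, 70, 80), 2), edu = rep(c(2, 5, 7), 2),
                    sex = rep(c(0, 1, 0), 2), etiv = rep(c(1400, 1500, 1600), 2))
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- propensity_match(labels, cov)
  expect_equal(nrow(m$pairs), 3)
  expect_equal(m$balance$smd_after, rep(0, 4))
  # pairs never share a group
  expect_true(all(labels[m$pairs$high] == 1) && all(labels[m$pairs$low] == 0))

  # 6-row toy with distinct ages: greedy matching equals the brute-force
  # minimal-distance assignment for this configuration
  cov2 <- data.frame(age = c(60, 70, 80, 61, 71, 81))
  lab2 <- c(1, 1, 1, 0, 0, 0)
  m2 <- propensity_match(lab2, cov2, caliper = 5)
  expect_equal(m2$pairs[order(m2$pairs$high), "low"], c(4, 5, 6))

  # larger random problem: balance improves and SMDs stay finite
  withr::with_seed(21, {
    n <- 200
    age <- runif(n, 55, 85)
    score <- -0.08 * age + rnorm(n)
    lab <- extreme_groups(score)
    cv <- data.frame(age = age, etiv = rnorm(n, 1500, 100))
  })
  m3 <- propensity_match(lab, cv)
  expect_gt(nrow(m3$pairs), 5)
  expect_true(all(is.finite(m3$balance$smd_after)))
  expect_lt(abs(m3$balance$smd_after[1]), abs(m3$balance$smd_before[1]))
  expect_error(propensity_match(rep(1, 4), data.frame(x = 1:4)), "non-empty")
})

test_that("partial correlation equals the residual-correlation oracle", {
  withr::with_seed(22, {
    z <- matrix(rnorm(10 * 2), 10, 2)
    x <- z[, 1] + rnorm(10)
    y <- z[, 1] - z[, 2] + rnorm(10)
  })
  pc <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, 10 - 2 - 2)
  # no controls reduces to Pearson
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y)$p, cor.test(x, y)$p.value,
               tolerance = 1e-10)
  # y equal to a control: partial r ~ 0
  expect_lt(abs(partial_correlation(x, z[, 1], z)$r), 1e-8)
})
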