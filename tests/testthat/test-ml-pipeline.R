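small_plan <- function(ids, seed = 3)
  make_cv_plan(ids, outer_k = 5, repeats = 2, inner_k = 5, seed = seed)

test_that("concatenation pipeline recovers a realizable linear signal", {
  X <- toy_features(120, 30, seed = 1)
  withr::with_seed(2, y <- drop(X[, 1:5] %*% c(1, 2, -1, 0.5, 1)))
  plan <- small_plan(rownames(X))
  res <- fit_predict_concat(X, y, model_config("ridge"), plan,
                            keep_weights = TRUE)
  s <- summarize_performance(res)
  expect_gt(s$mean_r2, 0.99)
  # dummy reference recorded per fold, strictly worse here
  expect_true(all(is.finite(res$folds$dummy_r2)))
  expect_equal(s$pct_beats_dummy, 100)
  # weights concentrate on the causal columns
  expect_true(all(order(colMeans(res$weights),
                        decreasing = TRUE)[1:5] %in% 1:5))
  # per-fold metrics are recomputable from stored predictions
  f1 <- res$folds[1, ]
  p1 <- res$predictions[[1]]
  expect_equal(f1$mae, mean(abs(p1$observed - p1$predicted)))
  expect_equal(f1$n_test, length(p1$ids))
})

test_that("deconfounding inside the pipeline removes demographic signal", {
  withr::with_seed(4, {
    n <- 150
    conf <- data.frame(etiv = rnorm(n, 1500, 100), age = runif(n, 55, 85),
                       sex = rbinom(n, 1, 0.5),
                       education = sample(1:8, n, TRUE))
    y <- -0.1 * conf$age + 0.5 * conf$sex + 0.3 * conf$education + rnorm(n, 0, 0.3)
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(sprintf("s%03d", 1:n), NULL))
    extra <- as.matrix(conf[, c("age", "sex", "education")])
    rownames(extra) <- rownames(X)
  })
  plan <- small_plan(rownames(X))
  no_dc <- fit_predict_concat(X, y, model_config("ridge"), plan,
                              deconf = deconfound_spec("no_deconf", conf),
                              extra_features = extra)
  full_dc <- fit_predict_concat(X, y, model_config("ridge"), plan,
                                deconf = deconfound_spec("deconf", conf),
                                extra_features = extra)
  expect_gt(summarize_performance(no_dc)$mean_r2, 0.5)
  expect_lt(summarize_performance(full_dc)$mean_r2, 0.05)
})

test_that("stacking preserves fold identities and feeds one column per modality", {
  X <- toy_features(100, 24, seed = 5)
  withr::with_seed(6, y <- drop(X[, 1:4] %*% rep(1, 4)) + rnorm(100, 0, 0.2))
  plan <- small_plan(rownames(X), seed = 7)
  mods <- list(fc = X[, 1:8], sc = X[, 9:16], gmv = X[, 17:24])
  res <- fit_predict_stacking(mods, y, model_config("ridge"), plan,
                              meta_grid = build_grid("rf")[c(1, 5), ])
  expect_true(check_stacking_exclusivity(res))
  expect_equal(colnames(res$weights), c("fc", "sc", "gmv"))  # 3 layer-2 inputs
  expect_equal(nrow(res$folds), 10)
  expect_gt(summarize_performance(res)$mean_r2, 0.5)
  expect_error(fit_predict_stacking(mods[1], y, model_config("ridge"), plan),
               "at least 2")
  bad <- mods; rownames(bad$sc) <- rev(rownames(bad$sc))
  expect_error(fit_predict_stacking(bad, y, model_config("ridge"), plan),
               "mismatch")
})

test_that("classification pipeline scores accuracy against a majority dummy", {
  withr::with_seed(8, {
    X <- toy_features(80, 6, seed = 9)
    labs <- as.integer(X[, 1] + 0.2 * rnorm(80) > 0)
  })
  plan <- small_plan(rownames(X), seed = 10)
  res <- fit_classify(X, labs, model_config("linsvc"), plan)
  s <- summarize_performance(res)
  expect_gt(s$mean_accuracy, 0.85)
  expect_lt(abs(s$mean_dummy_accuracy - 0.5), 0.15)
  # separable toy data: in-sample fit is perfect, CV accuracy near-perfect
  sep <- as.integer(X[, 2] > 0)
  m <- cogniconn:::fit_one("linsvc", scale(X), sep, list(C = 10))
  expect_equal(mean(cogniconn:::predict_one(m, scale(X)) == sep), 1)
  res2 <- fit_classify(X, sep, model_config("linsvc"), plan)
  expect_gte(summarize_performance(res2)$mean_accuracy, 0.9)
  expect_error(fit_classify(X, labs + 1, model_config("linsvc"), plan),
               "binary")
})

test_that("summarize_performance matches a hand-computed oracle", {
  fake <- structure(list(folds = data.frame(
    repeat_ = 1, fold = 1:4, n_test = 10,
    mae = c(0.5, 0.7, 0.6, 0.8), r2 = c(0.1, 0.2, -0.1, 0.3),
    pearson_r = c(0.3, 0.4, 0.1, 0.5),
    dummy_mae = c(0.9, 0.9, 0.5, 0.9), dummy_r2 = c(0, 0, 0, 0)),
    algorithm = "test"), class = "fold_results")
  s <- summarize_performance(fake)
  expect_equal(s$mean_mae, mean(c(0.5, 0.7, 0.6, 0.8)))
  expect_equal(s$mean_r2, 0.125)
  expect_equal(s$pct_beats_dummy, 75)       # strict >: fold 3 fails
  expect_equal(s$pct_beats_dummy_mae, 75)
  # model identical to dummy: percent-better = 0 under strict >
  same <- fake
  same$folds$r2 <- same$folds$dummy_r2
  same$folds$mae <- same$folds$dummy_mae
  s2 <- summarize_performance(same)
  expect_equal(s2$pct_beats_dummy, 0)
})

test_that("scaling and tuning statistics depend on training subjects only", {
  X <- toy_features(60, 10, seed = 11)
  withr::with_seed(12, y <- rnorm(60))
  plan <- make_cv_plan(rownames(X), outer_k = 3, repeats = 1, inner_k = 3,
                       seed = 13)
  res <- fit_predict_concat(X, y, model_config("ridge"), plan)
  # perturb test rows of fold 1: fold-1 training-side results unchanged
  e1 <- plan$outer[[1]]
  X2 <- X
  X2[e1$test_ids, ] <- X2[e1$test_ids, ] * 5 + 7
  res2 <- fit_predict_concat(X2, y, model_config("ridge"), plan)
  expect_identical(res$folds$chosen[[1]], res2$folds$chosen[[1]])
  # and a clean fold (fold 2 shares no test rows with fold 1 test set)
  expect_false(identical(res$folds$r2[1], res2$folds$r2[1]))
})
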