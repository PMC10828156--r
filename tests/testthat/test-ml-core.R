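test_that("cv plans partition subjects per repeat with balanced folds", {
  ids <- sprintf("s%03d", 1:100)
  plan <- make_cv_plan(ids, outer_k = 10, repeats = 10, inner_k = 5, seed = 2)
  expect_length(plan$outer, 100)
  # every subject tested exactly once per repeat; folds of exact size 10
  for (r in 1:10) {
    entries <- Filter(function(e) e$repeat_ == r, plan$outer)
    tested <- unlist(lapply(entries, `[[`, "test_ids"))
    expect_setequal(tested, ids)
    expect_length(tested, 100)
    expect_true(all(vapply(entries, function(e) length(e$test_ids),
                           integer(1)) == 10L))
  }
  for (e in plan$outer)
    expect_length(intersect(e$train_ids, e$test_ids), 0)
  # deterministic
  plan2 <- make_cv_plan(ids, 10, 10, 5, seed = 2)
  expect_identical(plan$outer[[37]], plan2$outer[[37]])
  expect_error(make_cv_plan(ids[1:5], outer_k = 10), "at least")
})

test_that("hyperparameter grids match the printed specification", {
  svr <- build_grid("linsvr")
  expect_equal(nrow(svr), 10)
  expect_equal(range(svr$C), c(1e-4, 1e1))
  expect_equal(diff(log10(svr$C)), rep(5 / 9, 9), tolerance = 1e-12)
  expect_equal(range(build_grid("lasso")$lambda), c(1e-1, 1e2))
  expect_equal(range(build_grid("ridge")$lambda), c(1e-3, 1e5))
  en <- build_grid("en")
  expect_equal(nrow(en), 100)
  expect_setequal(unique(round(en$alpha, 10)), round(seq(0.1, 1, 0.1), 10))
  rf <- build_grid("rf")
  expect_equal(nrow(rf), 14)
  expect_setequal(unique(rf$n_trees), c(100L, 1000L))
  expect_equal(sum(is.na(rf$max_depth)), 2)   # unbounded depth x 2 tree counts
  expect_error(build_grid("xgboost"), "unknown")
})

test_that("deconfound_target fits on train only and recovers exact effects", {
  withr::with_seed(3, {
    n <- 60
    age <- runif(n, 55, 85)
    conf <- cbind(age = age)
    y <- 2 * age
  })
  tr <- 1:40; te <- 41:60
  d <- deconfound_target(y, conf, tr, te)
  expect_lt(max(abs(d$train)), 1e-8)
  expect_lt(max(abs(d$test)), 1e-8)

  # confound uncorrelated with target: residual variance ~ target variance
  withr::with_seed(4, {
    y2 <- rnorm(1000); c2 <- cbind(x = rnorm(1000))
  })
  d2 <- deconfound_target(y2, c2, 1:800, 801:1000)
  expect_lt(abs(var(d2$train) / var(y2[1:800]) - 1), 0.05)

  # rank-deficient confounds dropped with warning
  expect_warning(deconfound_target(y, cbind(age, age), tr, te), "collinear")

  # train-only fitting: test rows never influence coefficients
  y3 <- y; y3[te] <- y3[te] + 1000
  d3 <- deconfound_target(y3, conf, tr, te)
  expect_equal(d3$coefficients, d$coefficients)

  # eTIV is in both deconfound modes
  confounds <- data.frame(etiv = rnorm(5), age = 1:5, sex = c(0, 1, 0, 1, 0),
                          education = 1:5)
  expect_equal(deconfound_spec("no_deconf", confounds)$columns, "etiv")
  expect_setequal(deconfound_spec("deconf", confounds)$columns,
                  c("etiv", "age", "sex", "education"))
  expect_error(deconfound_spec("deconf", confounds[, 1:2, drop = FALSE]),
               "lacks")
})

test_that("ridge path equals the normal-equation solution in both regimes", {
  oracle <- function(X, y, lam) {
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm); yc <- y - ym
    b <- solve(crossprod(Xc) + diag(lam, ncol(X)), crossprod(Xc, yc))
    c(ym - sum(xm * b), b)
  }
  withr::with_seed(5, {
    Xn <- matrix(rnorm(50 * 8), 50, 8); yn <- rnorm(50)     # n > p
    Xp <- matrix(rnorm(20 * 40), 20, 40); yp <- rnorm(20)   # p > n
  })
  for (lam in c(1e-3, 1, 1e3)) {
    expect_equal(as.numeric(cogniconn:::ridge_path(Xn, yn, lam)),
                 as.numeric(oracle(Xn, yn, lam)), tolerance = 1e-8)
    expect_equal(as.numeric(cogniconn:::ridge_path(Xp, yp, lam)),
                 as.numeric(oracle(Xp, yp, lam)), tolerance = 1e-8)
  }
})

test_that("primal linear SVR/SVC approach known solutions on toy data", {
  withr::with_seed(6, {
    X <- matrix(rnorm(200 * 3), 200, 3)
    y <- drop(X %*% c(1, -2, 0.5)) + 3
  })
  m <- cogniconn:::fit_one("linsvr", X, y, list(C = 10))
  expect_lt(mean(abs(cogniconn:::predict_one(m, X) - y)), 0.05)

  labs <- as.integer(X[, 1] > 0)
  mc <- cogniconn:::fit_one("linsvc", X, labs, list(C = 10))
  expect_gt(mean(cogniconn:::predict_one(mc, X) == labs), 0.97)
  ml <- cogniconn:::fit_one("logistic", X, labs, list(C = 1))
  expect_gt(mean(cogniconn:::predict_one(ml, X) == labs), 0.97)
})

test_that("random forest fits signal, is seed-stable, reports importances", {
  withr::with_seed(7, {
    X <- matrix(runif(300 * 4), 300, 4)
    y <- 2 * X[, 2] + sin(4 * X[, 3]) + rnorm(300, 0, 0.1)
  })
  m1 <- cogniconn:::fit_one("rf", X, y, list(n_trees = 200, max_depth = NA),
                            seed = 3)
  m2 <- cogniconn:::fit_one("rf", X, y, list(n_trees = 200, max_depth = NA),
                            seed = 3)
  p1 <- cogniconn:::predict_one(m1, X)
  expect_identical(p1, cogniconn:::predict_one(m2, X))   # seed-pinned
  expect_gt(cogniconn:::r2_score(y, p1), 0.8)
  imp <- cogniconn:::model_weights(m1)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(order(imp, decreasing = TRUE)[1:2] %in% c(2, 3)))
  # depth limit actually limits fitting
  stump <- cogniconn:::fit_one("rf", X, y, list(n_trees = 50, max_depth = 1),
                               seed = 3)
  expect_lt(cogniconn:::r2_score(y, cogniconn:::predict_one(stump, X)),
            cogniconn:::r2_score(y, p1))
})

test_that("inner tuning minimizes MAE with first-entry tie-breaking", {
  withr::with_seed(8, {
    X <- matrix(rnorm(100 * 5), 100, 5)
    y <- drop(X %*% rep(1, 5)) + rnorm(100, 0, 0.01)
  })
  grid <- data.frame(lambda = c(1e-2, 1e6))
  sel <- cogniconn:::tune_inner("ridge", X, y, grid, 5, seed = 1)
  expect_equal(sel$best, 1L)   # tiny penalty wins on near-noiseless data
  # exact ties break to the first enumeration entry
  tied <- data.frame(lambda = c(1, 1))
  sel2 <- cogniconn:::tune_inner("ridge", X, y, tied, 5, seed = 1)
  expect_equal(sel2$best, 1L)
})
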