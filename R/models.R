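#' Hyperparameter grids
#'
#' The printed search spaces, in enumeration order (ties in inner-fold
#' selection are broken by the first entry):
#' * `linsvr`: regularization C, 10^-4 to 10^1, 10 logarithmic steps;
#' * `lasso`: lambda, 10^-1 to 10^2, 10 logarithmic steps;
#' * `ridge`: lambda, 10^-3 to 10^5, 10 logarithmic steps;
#' * `en`: lambda 10^-1 to 10^2 (10 log steps) crossed with alpha
#'   (L1 ratio) 0.1 to 1 in 10 linear steps;
#' * `rf`: number of trees 100 or 1000 crossed with tree depth
#'   4, 6, 8, 10, 20, 40 or unbounded (`NA`).
#'
#' Classifier grids mirror these: `linsvc` and `logistic` use the linSVR C
#' grid, `ridgeclf` the ridge lambda grid, `rfclf` the RF grid.
#'
#' @param algorithm algorithm name (see above).
#' @return data.frame with one row per hyperparameter combination.
#' @export
build_grid <- function(algorithm) {
  switch(algorithm,
    linsvr = ,
    linsvc = ,
    logistic = data.frame(C = 10^seq(-4, 1, length.out = 10)),
    lasso = data.frame(lambda = 10^seq(-1, 2, length.out = 10)),
    ridge = ,
    ridgeclf = data.frame(lambda = 10^seq(-3, 5, length.out = 10)),
    en = expand.grid(lambda = 10^seq(-1, 2, length.out = 10),
                     alpha = seq(0.1, 1, length.out = 10)),
    rf = ,
    rfclf = expand.grid(n_trees = c(100L, 1000L),
                        max_depth = c(4L, 6L, 8L, 10L, 20L, 40L, NA_integer_)),
    stop(sprintf("unknown algorithm '%s'", algorithm)))
}

REGRESSORS <- c("ridge", "lasso", "en", "linsvr", "rf")
CLASSIFIERS <- c("linsvc", "logistic", "ridgeclf", "rfclf")

#' Model configuration
#'
#' @param algorithm one of the regression algorithms (`ridge`, `lasso`,
#'   `en`, `linsvr`, `rf`) or classifiers (`linsvc`, `logistic`,
#'   `ridgeclf`, `rfclf`).
#' @param hyper_grid hyperparameter grid (defaults to [build_grid()]).
#' @param inner_metric inner-fold selection metric: `"mae"` for
#'   regression, `"accuracy"` for classification.
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm, hyper_grid = build_grid(algorithm),
                         inner_metric = NULL) {
  if (!algorithm %in% c(REGRESSORS, CLASSIFIERS))
    stop(sprintf("unknown algorithm '%s'", algorithm))
  if (is.null(inner_metric))
    inner_metric <- if (algorithm %in% REGRESSORS) "mae" else "accuracy"
  structure(list(algorithm = algorithm, hyper_grid = hyper_grid,
                 inner_metric = inner_metric),
            class = "model_config")
}

## ---- single-model fitting -------------------------------------------

# Exact ridge regression (unpenalized intercept) evaluated on a whole
# lambda path from one eigendecomposition. Returns coefficient matrix
# (p+1) x length(lambdas), intercept first.
ridge_path <- function(X, y, lambdas) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  out <- matrix(0, p + 1L, length(lambdas))
  if (p <= n) {
    eg <- eigen(crossprod(Xc), symmetric = TRUE)
    xty <- crossprod(Xc, yc)
    vt_xty <- crossprod(eg$vectors, xty)
    for (k in seq_along(lambdas)) {
      b <- eg$vectors %*% (vt_xty / (pmax(eg$values, 0) + lambdas[k]))
      out[-1L, k] <- b
      out[1L, k] <- ym - sum(xm * b)
    }
  } else {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ut_y <- crossprod(eg$vectors, yc)
    for (k in seq_along(lambdas)) {
      alpha <- eg$vectors %*% (ut_y / (pmax(eg$values, 0) + lambdas[k]))
      b <- crossprod(Xc, alpha)
      out[-1L, k] <- b
      out[1L, k] <- ym - sum(xm * b)
    }
  }
  out
}

# Primal linear models via smoothed-loss L-BFGS. loss: "svr" (epsilon-
# insensitive with epsilon = 0, i.e. smoothed L1), "sqhinge" (squared
# hinge, labels +-1), "logistic" (labels +-1).
fit_primal_linear <- function(X, y, C, loss, maxit = 300L) {
  n <- nrow(X); p <- ncol(X)
  delta <- 1e-4 * max(stats::sd(y), 1e-8)
  obj <- function(theta) {
    w <- theta[-1L]; b <- theta[1L]
    f <- drop(X %*% w) + b
    pen <- 0.5 * sum(w * w)
    switch(loss,
      svr = pen + C * sum(sqrt((y - f)^2 + delta^2) - delta),
      sqhinge = pen + C * sum(pmax(0, 1 - y * f)^2),
      logistic = pen + C * sum(log1p(exp(-y * f))))
  }
  grad <- function(theta) {
    w <- theta[-1L]; b <- theta[1L]
    f <- drop(X %*% w) + b
    g <- switch(loss,
      svr = {
        r <- y - f
        -C * r / sqrt(r^2 + delta^2)
      },
      sqhinge = {
        m <- 1 - y * f
        -2 * C * y * pmax(0, m)
      },
      logistic = -C * y / (1 + exp(y * f)))
    c(sum(g), drop(crossprod(X, g)) + w)
  }
  fit <- stats::optim(numeric(p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e9))
  list(intercept = fit$par[1L], coef = fit$par[-1L])
}

# Fit one model with fixed hyperparameters. Returns an object usable by
# predict_one() / model_weights().
fit_one <- function(algorithm, X, y, params, seed = 1L) {
  model <- switch(algorithm,
    ridge = {
      cf <- ridge_path(X, y, params$lambda)
      list(intercept = cf[1L, 1L], coef = cf[-1L, 1L])
    },
    ridgeclf = {
      cf <- ridge_path(X, 2 * y - 1, params$lambda)  # labels to +-1
      list(intercept = cf[1L, 1L], coef = cf[-1L, 1L], classify = TRUE)
    },
    lasso = {
      fit <- glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda,
                            standardize = FALSE)
      list(glmnet = fit, s = params$lambda)
    },
    en = {
      fit <- glmnet::glmnet(X, y, alpha = params$alpha,
                            lambda = params$lambda, standardize = FALSE)
      list(glmnet = fit, s = params$lambda)
    },
    linsvr = fit_primal_linear(X, y, params$C, "svr"),
    linsvc = c(fit_primal_linear(X, 2 * y - 1, params$C, "sqhinge"),
               list(classify = TRUE)),
    logistic = c(fit_primal_linear(X, 2 * y - 1, params$C, "logistic"),
                 list(classify = TRUE)),
    rf = {
      md <- params$max_depth
      forest <- rf_fit_cpp(X, y, params$n_trees,
                           if (is.na(md)) -1L else as.integer(md),
                           ncol(X), 2L, as.integer(seed))
      list(forest = forest)
    },
    rfclf = {
      md <- params$max_depth
      forest <- rf_fit_cpp(X, as.numeric(y), params$n_trees,
                           if (is.na(md)) -1L else as.integer(md),
                           max(1L, floor(sqrt(ncol(X)))), 2L,
                           as.integer(seed))
      list(forest = forest, classify = TRUE)
    },
    stop(sprintf("unknown algorithm '%s'", algorithm)))
  model$algorithm <- algorithm
  model
}

predict_one <- function(model, X) {
  raw <- if (!is.null(model$forest)) {
    rf_predict_cpp(model$forest, X)
  } else if (!is.null(model$glmnet)) {
    drop(stats::predict(model$glmnet, X, s = model$s))
  } else {
    drop(X %*% model$coef) + model$intercept
  }
  if (isTRUE(model$classify)) as.numeric(raw >= if (is.null(model$forest)) 0 else 0.5)
  else raw
}

# Per-feature weight used for importance analyses: |coefficient| for
# linear models, impurity importance for forests.
model_weights <- function(model) {
  if (!is.null(model$forest)) model$forest$importance
  else if (!is.null(model$glmnet))
    abs(drop(stats::coef(model$glmnet, s = model$s))[-1L])
  else abs(model$coef)
}

## ---- inner-fold hyperparameter tuning -------------------------------

make_inner_folds <- function(n, k, seed) {
  with_seed(seed, {
    fold <- rep(seq_len(k), length.out = n)
    sample(fold)
  })
}

# Predictions of every grid row on validation data, exploiting path
# algorithms where available. Returns n_val x n_grid matrix.
fit_grid_predict <- function(algorithm, Xtr, ytr, Xval, grid, seed = 1L) {
  nv <- nrow(Xval)
  if (algorithm %in% c("ridge", "ridgeclf")) {
    yy <- if (algorithm == "ridgeclf") 2 * ytr - 1 else ytr
    cf <- ridge_path(Xtr, yy, grid$lambda)
    pred <- sweep(Xval %*% cf[-1L, , drop = FALSE], 2L, cf[1L, ], "+")
    if (algorithm == "ridgeclf") pred <- (pred >= 0) + 0
    return(pred)
  }
  if (algorithm %in% c("lasso", "en")) {
    alphas <- if (algorithm == "lasso") 1 else unique(grid$alpha)
    pred <- matrix(NA_real_, nv, nrow(grid))
    for (a in alphas) {
      rows <- if (algorithm == "lasso") seq_len(nrow(grid))
              else which(grid$alpha == a)
      lam <- grid$lambda[rows]
      fit <- glmnet::glmnet(Xtr, ytr, alpha = a, lambda = lam,
                            standardize = FALSE)
      pred[, rows] <- as.matrix(stats::predict(fit, Xval, s = lam))
    }
    return(pred)
  }
  # no path structure: fit row by row
  pred <- matrix(NA_real_, nv, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    model <- fit_one(algorithm, Xtr, ytr, as.list(grid[i, , drop = FALSE]),
                     seed = seed)
    pred[, i] <- predict_one(model, Xval)
  }
  pred
}

# Inner k-fold CV over the grid; returns the index of the best row
# (ties: first in enumeration order) and the per-row mean scores.
tune_inner <- function(algorithm, X, y, grid, inner_k, seed,
                       metric = c("mae", "accuracy")) {
  metric <- match.arg(metric)
  fold <- make_inner_folds(nrow(X), inner_k, seed)
  scores <- matrix(NA_real_, inner_k, nrow(grid))
  for (f in seq_len(inner_k)) {
    tr <- fold != f
    if (metric == "accuracy" && length(unique(y[tr])) < 2L) next
    pred <- fit_grid_predict(algorithm, X[tr, , drop = FALSE], y[tr],
                             X[!tr, , drop = FALSE], grid,
                             seed = substream_seed(seed, paste0("g", f)))
    scores[f, ] <- if (metric == "mae")
      colMeans(abs(pred - y[!tr]))
    else 1 - colMeans(pred == y[!tr])   # error rate: lower is better
  }
  mean_score <- colMeans(scores, na.rm = TRUE)
  list(best = which.min(mean_score), scores = mean_score)
}

## ---- performance metrics --------------------------------------------

mae_score <- function(y, pred) mean(abs(y - pred))

# R^2 = 1 - SS_res / SS_tot with the *test-set* mean in SS_tot; can be
# negative for models worse than the test mean.
r2_score <- function(y, pred) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  1 - sum((y - pred)^2) / ss_tot
}

pearson_safe <- function(y, pred) {
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(y, pred)
}
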