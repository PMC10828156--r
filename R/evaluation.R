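#' Multimodal bonus scores
#'
#' `B_all` is the difference between a multimodal model's performance and
#' the average of its constituent unimodal models; `B_best` the difference
#' to the best unimodal model. On the R^2 basis (default) larger is
#' better; on the MAE basis differences are sign-flipped
#' (`unimodal - multimodal`) so positive still means a multimodal benefit.
#' `B_best <= B_all` always.
#'
#' @param multi_perf scalar multimodal performance (mean outer-fold R^2 or
#'   MAE).
#' @param unimodal_perfs numeric vector of unimodal performances.
#' @param basis `"r2"` (default) or `"mae"`.
#' @return list of class `bonus_scores` with `b_all`, `b_best`, `basis`.
#' @export
multimodal_bonus <- function(multi_perf, unimodal_perfs, basis = c("r2", "mae")) {
  basis <- match.arg(basis)
  if (!length(unimodal_perfs)) stop("need at least one unimodal performance")
  out <- if (basis == "r2")
    list(b_all = multi_perf - mean(unimodal_perfs),
         b_best = multi_perf - max(unimodal_perfs))
  else
    list(b_all = mean(unimodal_perfs) - multi_perf,
         b_best = min(unimodal_perfs) - multi_perf)
  out$basis <- basis
  class(out) <- "bonus_scores"
  out
}

#' @export
print.bonus_scores <- function(x, ...) {
  cat(sprintf("multimodal bonus (%s basis): B_all = %.4f, B_best = %.4f\n",
              x$basis, x$b_all, x$b_best))
  invisible(x)
}

#' Feature importance intersection across algorithms and feature sets
#'
#' For each configuration (one `fold_results` run with `keep_weights =
#' TRUE`), feature weights are averaged across all CV folds, the `top_k`
#' features with the highest mean absolute weight are selected, and only
#' features present in *every* configuration's top list survive.
#'
#' @param runs named list of `fold_results` (e.g. one per
#'   algorithm x feature set), all on identically named features.
#' @param top_k number of top features per configuration (default 20).
#' @param feature_meta optional metadata data.frame (rows aligned with the
#'   feature columns) merged onto the survivors.
#' @return list of class `importance_table`: `per_config` (ranked top-k
#'   data.frames), `surviving` (character vector), `survivor_table`.
#' @export
feature_importance_concat <- function(runs, top_k = 20L,
                                      feature_meta = NULL) {
  if (!length(runs)) stop("no runs supplied")
  per_config <- lapply(runs, function(r) {
    if (is.null(r$weights)) stop("run lacks weights (keep_weights = TRUE)")
    mw <- colMeans(abs(r$weights))
    ord <- order(mw, decreasing = TRUE)[seq_len(min(top_k, length(mw)))]
    data.frame(feature = r$feature_names[ord], mean_weight = mw[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  tops <- lapply(per_config, `[[`, "feature")
  surviving <- Reduce(intersect, tops)
  survivor_table <- NULL
  if (length(surviving)) {
    survivor_table <- data.frame(feature = surviving,
                                 stringsAsFactors = FALSE)
    if (!is.null(feature_meta)) {
      fm <- feature_meta
      fm$feature <- paste(fm$modality, fm$metric, fm$node, sep = "_")
      survivor_table <- merge(survivor_table, fm, by = "feature",
                              sort = FALSE)
    }
  }
  structure(list(per_config = per_config, surviving = surviving,
                 survivor_table = survivor_table, top_k = top_k),
            class = "importance_table")
}

#' Modality importance from the stacking meta-learner
#'
#' Averages the layer-2 RF importances per modality across folds for each
#' configuration, ranks modalities within each configuration, and reports
#' the most common ranking (all tied rankings if the mode is not unique).
#'
#' @param runs list of stacking `fold_results` (meta-importance weights).
#' @return list with `mean_importance` (configs x modalities),
#'   `rankings` (character, one per config), `modal_ranking`.
#' @export
modality_importance_stacking <- function(runs) {
  if (!length(runs)) stop("no stacking runs supplied")
  imp <- t(vapply(runs, function(r) colMeans(r$weights),
                  numeric(ncol(runs[[1]]$weights))))
  colnames(imp) <- colnames(runs[[1]]$weights)
  rankings <- apply(imp, 1L, function(v)
    paste(names(sort(v, decreasing = TRUE)), collapse = " > "))
  tab <- table(rankings)
  modal <- names(tab)[tab == max(tab)]
  list(mean_importance = imp, rankings = unname(rankings),
       modal_ranking = modal)
}

#' Extreme cognitive groups
#'
#' Labels the top and bottom `quantile` fraction of subjects on a score
#' (default quartiles: high and low cognitive performers); the middle is
#' excluded (`NA`). Ties at the cutoffs are resolved by rank order, lower
#' row index first.
#'
#' @param scores numeric vector (e.g. global cognition component scores).
#' @param quantile group fraction (default 0.25).
#' @return integer vector: 1 = high group, 0 = low group, NA = excluded.
#' @export
extreme_groups <- function(scores, quantile = 0.25) {
  n <- length(scores)
  if (n < 8L) stop("need at least 8 subjects")
  k <- floor(n * quantile)
  if (k < 1L) stop("quantile too small for the sample")
  rk <- rank(scores, ties.method = "first")
  labels <- rep(NA_integer_, n)
  labels[rk <= k] <- 0L
  labels[rk > n - k] <- 1L
  labels
}

#' Propensity score matching of extreme groups
#'
#' Logistic propensity model of group membership on the covariates,
#' greedy 1:1 nearest-neighbour matching on the logit scale without
#' replacement, caliper `caliper * sd(logit)`. Returns matched pairs and
#' standardized mean differences before and after matching.
#'
#' @param group_labels 0/1/NA labels from [extreme_groups()].
#' @param covariates data.frame or matrix (e.g. age, education, sex,
#'   eTIV), rows aligned with the labels.
#' @param caliper caliper width in sd of the logit (default 0.2).
#' @return list of class `matched_sample`: `pairs` (data.frame of row
#'   indices `high`, `low`), `high_ids`, `low_ids`, `balance`
#'   (per-covariate SMD before/after).
#' @export
propensity_match <- function(group_labels, covariates, caliper = 0.2) {
  cov <- as.matrix(covariates)
  keep <- which(!is.na(group_labels))
  g <- group_labels[keep]
  if (!length(g) || all(g == 0) || all(g == 1))
    stop("both groups must be non-empty")
  cv <- cov[keep, , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(g ~ cv, family = stats::binomial()))
  logit <- drop(cbind(1, cv) %*% ifelse(is.na(stats::coef(fit)), 0,
                                        stats::coef(fit)))
  cal <- caliper * stats::sd(logit)
  hi <- which(g == 1); lo <- which(g == 0)
  used <- logical(length(lo))
  pairs <- list()
  for (i in hi[order(logit[hi], decreasing = TRUE)]) {
    d <- abs(logit[lo] - logit[i])
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(high = keep[i], low = keep[lo[j]])
    }
  }
  if (!length(pairs)) {
    warning("no matches within caliper")
    pairs_df <- data.frame(high = integer(), low = integer())
  } else pairs_df <- as.data.frame(do.call(rbind, pairs))

  smd <- function(rows_hi, rows_lo) {
    vapply(seq_len(ncol(cov)), function(j) {
      x1 <- cov[rows_hi, j]; x0 <- cov[rows_lo, j]
      sp <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
      if (!is.finite(sp) || sp == 0) 0 else (mean(x1) - mean(x0)) / sp
    }, numeric(1))
  }
  balance <- data.frame(
    covariate = colnames(cov) %||% paste0("x", seq_len(ncol(cov))),
    smd_before = smd(keep[hi], keep[lo]),
    smd_after = if (nrow(pairs_df)) smd(pairs_df$high, pairs_df$low)
                else rep(NA_real_, ncol(cov)))
  structure(list(pairs = pairs_df, high_ids = pairs_df$high,
                 low_ids = pairs_df$low, balance = balance,
                 n_matched = 2L * nrow(pairs_df)),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  cat(sprintf("matched sample: %d pairs (N = %d)\n",
              nrow(x$pairs), x$n_matched))
  print(x$balance)
  invisible(x)
}

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the control
#' variables, with a two-sided p-value from the t distribution on
#' `n - 2 - k` degrees of freedom. With no controls this reduces to the
#' plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls optional numeric matrix/data.frame of control
#'   variables.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  k <- 0L
  if (!is.null(controls) && NCOL(controls) > 0L) {
    Z <- cbind(1, as.matrix(controls))
    q <- qr(Z)
    if (q$rank < ncol(Z)) {
      warning("dropping collinear control column(s)")
      Z <- Z[, q$pivot[seq_len(q$rank)], drop = FALSE]
      q <- qr(Z)
    }
    x <- qr.resid(q, x)
    y <- qr.resid(q, y)
    k <- ncol(Z) - 1L
  }
  # a variable fully explained by the controls has zero residual variance;
  # its partial correlation with anything is 0 by convention
  r <- if (sd_pop(x) < 1e-12 || sd_pop(y) < 1e-12) 0 else stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, 1e-15))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}
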