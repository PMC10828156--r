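#' Confound specification
#'
#' Confound regression removes nuisance variables from the *target* with
#' coefficients estimated on training subjects only (always inside the CV,
#' never on the full sample). The `no_deconf` condition still regresses
#' out eTIV; the `deconf` condition additionally removes age, sex and
#' educational level.
#'
#' @param mode `"no_deconf"` (eTIV only) or `"deconf"` (eTIV + age + sex +
#'   education).
#' @param confounds data.frame with columns `etiv`, `age`, `sex`,
#'   `education` (rows aligned with the subjects).
#' @return object of class `deconfound_spec`.
#' @export
deconfound_spec <- function(mode = c("no_deconf", "deconf"), confounds) {
  mode <- match.arg(mode)
  cols <- if (mode == "no_deconf") "etiv" else
    c("etiv", "age", "sex", "education")
  missing_cols <- setdiff(cols, names(confounds))
  if (length(missing_cols))
    stop(sprintf("confound table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  cm <- as.matrix(confounds[, cols, drop = FALSE])
  stop_if_na(cm, "confounds")
  structure(list(mode = mode, confounds = cm, columns = cols),
            class = "deconfound_spec")
}

#' Train-only confound regression of the target
#'
#' Ordinary least squares of the target on `[intercept, confounds]`,
#' fitted on the training subjects; residuals are returned for train and
#' test using the training coefficients. Rank-deficient confound columns
#' are dropped with a warning.
#'
#' @param target numeric vector over all subjects.
#' @param confounds numeric matrix over all subjects.
#' @param train_idx,test_idx integer row indices.
#' @return list with `train` and `test` residual vectors and the fitted
#'   `coefficients`.
#' @export
deconfound_target <- function(target, confounds, train_idx, test_idx) {
  confounds <- as.matrix(confounds)
  X <- cbind(intercept = 1, confounds)
  qr_tr <- qr(X[train_idx, , drop = FALSE])
  if (qr_tr$rank < ncol(X)) {
    keep <- qr_tr$pivot[seq_len(qr_tr$rank)]
    warning(sprintf("dropping %d collinear confound column(s)",
                    ncol(X) - qr_tr$rank))
    X <- X[, keep, drop = FALSE]
    qr_tr <- qr(X[train_idx, , drop = FALSE])
  }
  beta <- qr.coef(qr_tr, target[train_idx])
  beta[is.na(beta)] <- 0
  list(train = target[train_idx] - drop(X[train_idx, , drop = FALSE] %*% beta),
       test = target[test_idx] - drop(X[test_idx, , drop = FALSE] %*% beta),
       coefficients = beta)
}

# Apply a deconfound spec (or not) for one outer fold.
apply_deconfound <- function(target, spec, train_idx, test_idx) {
  if (is.null(spec))
    return(list(train = target[train_idx], test = target[test_idx]))
  deconfound_target(target, spec$confounds, train_idx, test_idx)
}
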