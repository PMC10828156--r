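#' Median imputation by sex and age band
#'
#' Missing test scores are replaced by the median of observed values in the
#' subject's sex-by-age-band cell, with age bands 55--64, 65--74 and
#' 75--85 years; empty cells fall back to the whole-sample median.
#' Subjects with more than `max_missing` missing tests are excluded (with
#' a message) and reported in the `"excluded"` attribute.
#'
#' @param battery list with `scores` (subjects x tests, NAs for missing)
#'   and optionally `missing_mask`.
#' @param subjects data.frame with `age` and `sex` for every row of the
#'   battery.
#' @param max_missing exclusion threshold (default 3).
#' @return battery with `scores` imputed (possibly fewer rows); attribute
#'   `"excluded"` holds the dropped row indices.
#' @export
impute_group_median <- function(battery, subjects, max_missing = 3L) {
  scores <- battery$scores
  if (nrow(scores) != nrow(subjects))
    stop("battery and subject table must have the same rows")
  n_missing <- rowSums(is.na(scores))
  excl <- which(n_missing > max_missing)
  if (length(excl)) {
    message(sprintf(
      "excluding %d subject(s) with more than %d missing values",
      length(excl), max_missing))
    scores <- scores[-excl, , drop = FALSE]
    subjects <- subjects[-excl, , drop = FALSE]
  }
  band <- cut(subjects$age, c(55, 65, 75, 85.0001), right = FALSE,
              labels = c("55-64", "65-74", "75-85"), include.lowest = TRUE)
  cell <- interaction(subjects$sex, band, drop = FALSE)
  for (j in seq_len(ncol(scores))) {
    miss <- which(is.na(scores[, j]))
    if (!length(miss)) next
    overall <- stats::median(scores[, j], na.rm = TRUE)
    med <- tapply(scores[, j], cell, stats::median, na.rm = TRUE)
    fill <- unname(med[as.character(cell[miss])])
    fill[!is.finite(fill)] <- overall
    scores[miss, j] <- fill
  }
  out <- battery
  out$scores <- scores
  if (!is.null(out$missing_mask) && length(excl))
    out$missing_mask <- out$missing_mask[-excl, , drop = FALSE]
  attr(out, "excluded") <- excl
  out
}

#' Z-score and invert the cognitive battery
#'
#' Converts each test to z-scores (population-sd denominator by default)
#' and multiplies tests flagged as inverted (higher raw value = worse
#' performance, e.g. completion times or error counts) by -1, so higher
#' always means better afterwards.
#'
#' @param battery imputed battery (list with `scores` and `invert_flags`).
#' @param population_sd use the n (population) denominator (default TRUE).
#' @return numeric subjects x tests matrix of standardized scores.
#' @export
zscore_invert <- function(battery, population_sd = TRUE) {
  scores <- battery$scores
  stop_if_na(scores, "battery scores (impute first)")
  flags <- battery$invert_flags %||% rep(FALSE, ncol(scores))
  z <- scores
  for (j in seq_len(ncol(scores))) {
    s <- if (population_sd) sd_pop(scores[, j]) else stats::sd(scores[, j])
    if (s == 0) stop(sprintf("zero-variance test in column %d", j))
    z[, j] <- (scores[, j] - mean(scores[, j])) / s
  }
  z[, flags] <- -z[, flags]
  z
}

#' PCA-derived cognitive composite targets
#'
#' `mode = "global"` extracts the first principal component of the test
#' correlation matrix (the global cognition composite); `mode =
#' "profiles"` retains all components with eigenvalue > 1, applies Varimax
#' rotation (Kaiser-normalized) and returns rotated component scores.
#' Scores use the regression method on the correlation matrix and are
#' standardized to mean 0, variance 1; loadings are sign-fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param z_matrix standardized subjects x tests matrix.
#' @param mode `"global"` or `"profiles"`.
#' @return object of class `composite_solution`: list with `loadings`,
#'   `scores`, `eigenvalues`, `rotation`, `kmo`.
#' @export
pca_targets <- function(z_matrix, mode = c("global", "profiles")) {
  mode <- match.arg(mode)
  if (nrow(z_matrix) <= ncol(z_matrix))
    stop("need more subjects than tests")
  R <- stats::cor(z_matrix)
  eig <- eigen(R, symmetric = TRUE)
  k <- if (mode == "global") 1L else sum(eig$values > 1)
  if (mode == "profiles" && k < 2L)
    warning(sprintf("eigenvalue > 1 rule retains only %d component(s)", k))
  k <- max(k, 1L)
  load <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rotation <- "none"
  if (k > 1L) {
    vm <- stats::varimax(load)   # Kaiser normalization is the default
    load <- load %*% vm$rotmat
    rotation <- "varimax"
  }
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  # regression-method component scores on the correlation matrix
  W <- solve(R, load)
  scores <- scale(z_matrix, center = TRUE, scale = FALSE) %*% W
  for (j in seq_len(k)) {
    s <- sd_pop(scores[, j])
    if (s > 0) scores[, j] <- scores[, j] / s
  }
  dimnames(load) <- list(colnames(z_matrix), paste0("comp", seq_len(k)))
  colnames(scores) <- paste0("comp", seq_len(k))
  structure(list(loadings = load, scores = scores,
                 eigenvalues = eig$values, rotation = rotation,
                 kmo = kmo_index(z_matrix)),
            class = "composite_solution")
}

#' @export
print.composite_solution <- function(x, ...) {
  cat(sprintf("composite solution: %d component(s), rotation %s, KMO %.3f\n",
              ncol(x$loadings), x$rotation, x$kmo))
  invisible(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy index
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(p^2))` over the off-diagonal observed
#' correlations r and anti-image partial correlations p. A singular
#' correlation matrix is ridge-regularized with a warning.
#'
#' @param z_matrix numeric matrix with >= 3 columns.
#' @return scalar in `[0, 1]`.
#' @export
kmo_index <- function(z_matrix) {
  if (ncol(z_matrix) < 3L) stop("KMO needs at least 3 variables")
  R <- stats::cor(z_matrix)
  Rinv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix: using regularized inverse")
    solve(R + diag(1e-8, nrow(R)))
  })
  d <- 1 / sqrt(diag(Rinv))
  P <- -Rinv * outer(d, d)   # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
}

#' Theoretically defined global composite
#'
#' The per-subject average of the standardized (and inverted) test scores.
#'
#' @param z_matrix standardized subjects x tests matrix.
#' @return numeric vector of length `nrow(z_matrix)`.
#' @export
theoretical_composite <- function(z_matrix) {
  rowMeans(z_matrix)
}
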