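#' Phase-randomized surrogate of a time series
#'
#' Fourier-transform surrogate: the amplitude spectrum of the input is
#' preserved exactly while phases of the free frequencies are drawn
#' uniformly with conjugate symmetry, so the output is real. The DC
#' component and (for even length) the Nyquist component are kept, hence
#' mean and variance are preserved.
#'
#' @param series real-valued numeric vector, length >= 4.
#' @param seed integer seed.
#' @return numeric vector of the same length.
#' @export
phase_randomized_surrogate <- function(series, seed = 1L) {
  n <- length(series)
  if (n < 4L) stop("series must have length >= 4")
  stop_if_na(series, "series")
  if (stats::sd(series) == 0) {
    warning("constant series: returned unchanged")
    return(series)
  }
  f <- stats::fft(series)
  nfree <- (n - 1L) %/% 2L
  with_seed(seed, {
    phases <- stats::runif(nfree, 0, 2 * pi)
  })
  idx <- seq_len(nfree) + 1L
  f[idx] <- Mod(f[idx]) * exp(1i * phases)
  f[n + 2L - idx] <- Conj(f[idx])
  Re(stats::fft(f, inverse = TRUE)) / n
}

# Phase-randomize every row of a node x time panel with independent phases
# per node (single RNG draw block; used by the edge filter).
phase_randomize_panel <- function(panel) {
  n <- nrow(panel); tt <- ncol(panel)
  f <- stats::mvfft(t(panel))                 # tt x n, per-column FFT
  nfree <- (tt - 1L) %/% 2L
  idx <- seq_len(nfree) + 1L
  phases <- matrix(stats::runif(nfree * n, 0, 2 * pi), nfree, n)
  f[idx, ] <- Mod(f[idx, , drop = FALSE]) * exp(1i * phases)
  f[tt + 2L - idx, ] <- Conj(f[idx, , drop = FALSE])
  t(Re(stats::mvfft(f, inverse = TRUE)) / tt)
}

#' Surrogate-based edge significance filter
#'
#' For every node pair, the observed Pearson correlation is tested against
#' a null distribution of correlations from phase-randomized surrogates of
#' the node time series (1000 repeats by default). The permutation p-value
#' uses the add-one rule `(k + 1) / (n_perm + 1)` on a two-sided test of
#' `|r|`; edges with `p >= alpha` are set to zero.
#'
#' @param panel `n_nodes x n_timepoints` matrix of node time series.
#' @param n_perm number of surrogate repeats (>= 20).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @return an FC `connectome` with non-significant edges zeroed; the
#'   p-value matrix is attached as attribute `"p_values"`.
#' @export
edge_significance_filter <- function(panel, n_perm = 1000L, alpha = 0.05,
                                     seed = 1L, subject_id = "sub") {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  fc <- correlation_matrix(panel, subject_id = subject_id)
  robs <- abs(fc$matrix)
  n <- nrow(robs)
  exceed <- matrix(0L, n, n)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      surr <- phase_randomize_panel(panel)
      rnull <- abs(suppressWarnings(stats::cor(t(surr))))
      rnull[!is.finite(rnull)] <- 0
      exceed <- exceed + (rnull >= robs)
    }
  })
  p <- (exceed + 1L) / (n_perm + 1L)
  diag(p) <- 0
  filtered <- fc$matrix
  filtered[p >= alpha] <- 0
  fc$matrix <- filtered
  attr(fc, "p_values") <- p
  fc
}

#' Full functional-connectivity preprocessing pipeline
#'
#' Pearson correlation of node time series, optional surrogate-based edge
#' significance filtering, Fisher r-to-z transform (after thresholding, as
#' in the pipeline order), and restriction to the requested sign branch
#' (positive correlations by default).
#'
#' @inheritParams edge_significance_filter
#' @param filter apply the surrogate edge filter (set `FALSE` to skip, e.g.
#'   for quick synthetic runs).
#' @param branch `"positive"` (default), `"negative"` (absolute values of
#'   negative z) or `"signed"` (no restriction).
#' @return an FC `connectome` of non-negative (unless `"signed"`) z values.
#' @export
fc_pipeline <- function(panel, filter = TRUE, n_perm = 1000L, alpha = 0.05,
                        seed = 1L, branch = c("positive", "negative", "signed"),
                        subject_id = "sub") {
  branch <- match.arg(branch)
  fc <- if (filter)
    edge_significance_filter(panel, n_perm = n_perm, alpha = alpha,
                             seed = seed, subject_id = subject_id)
  else correlation_matrix(panel, subject_id = subject_id)
  fc <- fisher_z(fc)
  switch(branch,
         positive = positive_part(fc),
         negative = negative_part(fc),
         signed = fc)
}
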