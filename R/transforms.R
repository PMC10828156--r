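#' Fisher r-to-z transform
#'
#' Applies `z = atanh(r)` elementwise. Zeros map to zeros, so the transform
#' commutes with prior edge thresholding (the pipeline order is: threshold,
#' then transform). Off-diagonal entries with `|r| >= 1` are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param matrix numeric matrix of correlations (connectome or plain matrix).
#' @return matrix (or connectome) of z values.
#' @export
fisher_z <- function(matrix) {
  conn <- inherits(matrix, "connectome")
  m <- as_connectome_matrix(matrix)
  off <- row(m) != col(m)
  bad <- off & abs(m) >= 1
  if (any(bad)) {
    warning(sprintf("%d off-diagonal |r| >= 1 clipped", sum(bad)))
    m[bad] <- sign(m[bad]) * (1 - 1e-7)
  }
  z <- m
  z[off] <- atanh(m[off])
  diag(z) <- 0
  if (conn) { matrix$matrix <- z; matrix } else z
}

#' Positive / negative parts of a weighted matrix
#'
#' `positive_part` keeps entries greater than zero and zeroes the rest;
#' `negative_part` keeps the absolute values of entries below zero. The
#' identity `positive_part(m) - negative_part(m) == m` holds entrywise.
#'
#' @param matrix numeric matrix or connectome.
#' @return matrix (or connectome) of the same shape.
#' @export
positive_part <- function(matrix) {
  conn <- inherits(matrix, "connectome")
  m <- as_connectome_matrix(matrix)
  p <- pmax(m, 0)
  if (conn) { matrix$matrix <- p; matrix } else p
}

#' @rdname positive_part
#' @export
negative_part <- function(matrix) {
  conn <- inherits(matrix, "connectome")
  m <- as_connectome_matrix(matrix)
  p <- pmax(-m, 0)
  if (conn) { matrix$matrix <- p; matrix } else p
}

#' Log-transform of structural streamline weights
#'
#' Default transform is `log10(1 + w)`, which preserves zeros (absent
#' edges) and is monotone on the non-negative weights; `zero_safe = FALSE`
#' applies plain `log10(w)` on the nonzero support instead.
#'
#' @param matrix non-negative numeric matrix or SC connectome.
#' @param zero_safe use `log10(1 + w)` (default) rather than `log10(w)` on
#'   nonzero entries.
#' @return matrix (or connectome) of transformed weights.
#' @export
log10_sc <- function(matrix, zero_safe = TRUE) {
  conn <- inherits(matrix, "connectome")
  m <- as_connectome_matrix(matrix)
  if (any(m < 0)) stop("log10_sc: negative weights are invalid")
  out <- m
  nz <- m > 0
  out[nz] <- if (zero_safe) log10(1 + m[nz]) else log10(m[nz])
  if (conn) { matrix$matrix <- out; matrix } else out
}
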