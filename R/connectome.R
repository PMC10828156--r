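#' Connectome objects
#'
#' A connectome is one subject's weighted adjacency matrix over the
#' parcellation nodes, tagged with its modality. Matrices are validated to
#' be square and symmetric (to `tol`), symmetrized by averaging, and have
#' their diagonal zeroed on construction.
#'
#' @param matrix square numeric matrix of edge weights.
#' @param modality `"FC"` or `"SC"`.
#' @param subject_id subject identifier.
#' @param tol symmetry tolerance.
#' @return an object of class `connectome`.
#' @export
connectome <- function(matrix, modality = c("FC", "SC"), subject_id = "sub",
                       tol = 1e-10) {
  modality <- match.arg(modality)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("connectome matrix must be square")
  stop_if_na(matrix, "connectome matrix")
  asym <- max(abs(matrix - t(matrix)))
  if (asym > tol && asym > 1e-6 * max(abs(matrix), 1))
    stop(sprintf("connectome matrix asymmetric beyond tolerance (max |A - t(A)| = %g)",
                 asym))
  m <- (matrix + t(matrix)) / 2
  diag(m) <- 0
  structure(list(subject_id = subject_id, modality = modality, matrix = m),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$matrix[upper.tri(x$matrix)] != 0)
  np <- sum(upper.tri(x$matrix))
  cat(sprintf("connectome [%s] subject %s: %d nodes, density %.3f\n",
              x$modality, x$subject_id, nrow(x$matrix), nz / np))
  invisible(x)
}

as_connectome_matrix <- function(x) {
  if (inherits(x, "connectome")) x$matrix else x
}

#' Pearson correlation matrix of a node-by-time panel
#'
#' Entry (i, j) is the Pearson correlation of the time series of nodes i
#' and j. Zero-variance nodes are flagged with a warning and their
#' correlations set to 0. The diagonal is zeroed by the `connectome`
#' constructor (unit before zeroing).
#'
#' @param panel `n_nodes x n_timepoints` numeric matrix.
#' @param subject_id subject identifier.
#' @return an FC `connectome`.
#' @export
correlation_matrix <- function(panel, subject_id = "sub") {
  if (!is.matrix(panel) || ncol(panel) < 3L)
    stop("panel must be a matrix with at least 3 timepoints")
  stop_if_na(panel, "panel")
  sds <- apply(panel, 1L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(t(panel)))
  if (any(flat)) {
    warning(sprintf("%d zero-variance node(s); correlations set to 0",
                    sum(flat)))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[!is.finite(r)] <- 0
  connectome(r, modality = "FC", subject_id = subject_id)
}
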