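#' Feature matrices
#'
#' A feature matrix holds subjects x features values plus per-column
#' metadata (modality, metric, node index, network label, or extra flag).
#'
#' @param values numeric subjects x features matrix.
#' @param feature_meta data.frame with one row per column of `values`
#'   (columns `modality`, `metric`, `node`, `network`).
#' @param subject_ids character vector of row identities.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_meta, subject_ids) {
  if (nrow(feature_meta) != ncol(values))
    stop("feature_meta rows must match feature columns")
  if (length(subject_ids) != nrow(values))
    stop("subject_ids must match rows")
  stop_if_na(values, "feature matrix")
  rownames(values) <- subject_ids
  colnames(values) <- paste(feature_meta$modality, feature_meta$metric,
                            feature_meta$node, sep = "_")
  structure(list(values = values, feature_meta = feature_meta,
                 subject_ids = subject_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$feature_meta$modality), collapse = ", ")))
  invisible(x)
}

#' Per-subject nodal metric matrices for a set of connectomes
#'
#' Computes within/inter/ratio vectors for every subject's connectome and
#' stacks them into subjects x nodes matrices.
#'
#' @param connectomes list of `connectome` objects (one per subject).
#' @param parcellation the shared `parcellation`.
#' @param ... passed to [nodal_metrics()].
#' @return list of three subjects x nodes matrices: `within`, `inter`,
#'   `ratio`.
#' @export
connectome_metric_matrices <- function(connectomes, parcellation, ...) {
  per <- lapply(connectomes, nodal_metrics, parcellation = parcellation, ...)
  ids <- unname(vapply(connectomes, function(cc) cc$subject_id, character(1)))
  out <- lapply(c("within", "inter", "ratio"), function(metric) {
    m <- do.call(rbind, lapply(per, function(p) as.numeric(p[[metric]])))
    rownames(m) <- ids
    colnames(m) <- paste0("node", seq_len(parcellation$n_nodes))
    m
  })
  names(out) <- c("within", "inter", "ratio")
  out
}

#' Assemble a named feature set
#'
#' Feature sets follow the printed arithmetic on an n-node parcellation
#' (n = 400 in the reference configuration):
#' * `A`: FC within + inter, SC within + inter, GMV — `5n` (2000) columns;
#' * `B`: FC ratio, SC ratio, GMV — `3n` (1200) columns;
#' * `C`: positive-FC within + inter, negative-FC within + inter,
#'   SC within + inter, GMV — `7n` (2800) columns;
#' * `full`: FC within + inter + ratio, SC within + inter + ratio, GMV —
#'   `7n` (2800) columns.
#'
#' When `extra_demographics` is supplied (a subjects x 3 matrix or
#' data.frame of age, sex, education), three extra-feature columns are
#' appended.
#'
#' @param fset `"A"`, `"B"`, `"C"` or `"full"`.
#' @param fc_metrics,sc_metrics metric-matrix lists from
#'   [connectome_metric_matrices()] (positive-branch FC for all sets).
#' @param gmv subjects x nodes GMV matrix.
#' @param parcellation the shared `parcellation` (for network labels).
#' @param fc_neg_metrics negative-branch FC metrics, required for set `C`.
#' @param extra_demographics optional subjects x 3 demographics block.
#' @return a `feature_matrix`.
#' @export
assemble_feature_set <- function(fset = c("A", "B", "C", "full"),
                                 fc_metrics, sc_metrics, gmv, parcellation,
                                 fc_neg_metrics = NULL,
                                 extra_demographics = NULL) {
  fset <- match.arg(fset)
  validate_parcellation(parcellation)
  nets <- parcellation$network_names[parcellation$network_of]
  nodes <- seq_len(parcellation$n_nodes)

  block <- function(mat, modality, metric) {
    if (is.null(mat)) stop(sprintf("missing component: %s %s", modality, metric))
    if (ncol(mat) != parcellation$n_nodes)
      stop(sprintf("component %s %s has %d columns, expected %d",
                   modality, metric, ncol(mat), parcellation$n_nodes))
    list(values = mat,
         meta = data.frame(modality = modality, metric = metric,
                           node = nodes, network = nets,
                           stringsAsFactors = FALSE))
  }
  blocks <- switch(fset,
    A = list(block(fc_metrics$within, "FC", "within"),
             block(fc_metrics$inter, "FC", "inter"),
             block(sc_metrics$within, "SC", "within"),
             block(sc_metrics$inter, "SC", "inter"),
             block(gmv, "GMV", "gmv")),
    B = list(block(fc_metrics$ratio, "FC", "ratio"),
             block(sc_metrics$ratio, "SC", "ratio"),
             block(gmv, "GMV", "gmv")),
    C = {
      if (is.null(fc_neg_metrics))
        stop("missing component: negative-FC metrics are required for FSet C")
      list(block(fc_metrics$within, "FC", "within"),
           block(fc_metrics$inter, "FC", "inter"),
           block(fc_neg_metrics$within, "FCneg", "within"),
           block(fc_neg_metrics$inter, "FCneg", "inter"),
           block(sc_metrics$within, "SC", "within"),
           block(sc_metrics$inter, "SC", "inter"),
           block(gmv, "GMV", "gmv"))
    },
    full = list(block(fc_metrics$within, "FC", "within"),
                block(fc_metrics$inter, "FC", "inter"),
                block(fc_metrics$ratio, "FC", "ratio"),
                block(sc_metrics$within, "SC", "within"),
                block(sc_metrics$inter, "SC", "inter"),
                block(sc_metrics$ratio, "SC", "ratio"),
                block(gmv, "GMV", "gmv")))

  ids <- rownames(blocks[[1]]$values)
  for (b in blocks) {
    if (!is.null(rownames(b$values)) && !is.null(ids) &&
        !identical(rownames(b$values), ids))
      stop("subject order mismatch between feature components")
  }
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  meta <- do.call(rbind, lapply(blocks, `[[`, "meta"))
  if (!is.null(extra_demographics)) {
    ed <- as.matrix(extra_demographics)
    if (nrow(ed) != nrow(values))
      stop("subject order mismatch: extra_demographics rows differ")
    if (ncol(ed) != 3L) stop("extra_demographics must have 3 columns")
    colnames(ed) <- c("age", "sex", "education")
    values <- cbind(values, ed)
    meta <- rbind(meta, data.frame(modality = "extra",
                                   metric = c("age", "sex", "education"),
                                   node = NA_integer_, network = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(ids)) ids <- sprintf("sub%04d", seq_len(nrow(values)))
  feature_matrix(values, meta, ids)
}
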