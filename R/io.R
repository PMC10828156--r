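#' Read and write connectome matrix files
#'
#' Connectomes are stored as one tab-delimited square numeric matrix per
#' subject and modality, filename `<subject>_<FC|SC>.tsv`. On reading,
#' matrices are validated (square, symmetric to tolerance, dimension
#' matching the parcellation) and pass through the `connectome`
#' constructor (diagonal zeroed).
#'
#' @param conn a `connectome`.
#' @param path file path.
#' @return `write_connectome` returns the path invisibly.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  data.table::fwrite(data.table::as.data.table(conn$matrix), path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @param parcellation optional `parcellation` to validate dimensions.
#' @param modality,subject_id overrides; by default parsed from the
#'   filename.
#' @export
read_connectome <- function(path, parcellation = NULL, modality = NULL,
                            subject_id = NULL) {
  m <- as.matrix(data.table::fread(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (!is.numeric(m))
    stop(sprintf("%s: non-numeric matrix", basename(path)))
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: matrix is %d x %d, not square",
                 basename(path), nrow(m), ncol(m)))
  if (!is.null(parcellation) && nrow(m) != parcellation$n_nodes)
    stop(sprintf("%s: dimension %d does not match parcellation (%d nodes)",
                 basename(path), nrow(m), parcellation$n_nodes))
  base <- sub("\\.[^.]+$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(modality)) {
    modality <- toupper(parts[length(parts)])
    if (!modality %in% c("FC", "SC"))
      stop(sprintf("%s: cannot infer modality from filename", basename(path)))
  }
  if (is.null(subject_id))
    subject_id <- paste(parts[-length(parts)], collapse = "_")
  tryCatch(
    connectome(m, modality = modality, subject_id = subject_id, tol = 1e-8),
    error = function(e)
      stop(sprintf("%s: %s", basename(path), conditionMessage(e))))
}

#' Load a directory of connectome files
#'
#' @param path directory containing `<subject>_<FC|SC>.tsv` files.
#' @param parcellation the `parcellation` the matrices must match.
#' @param modality restrict to one modality (`"FC"`, `"SC"`, or `NULL`
#'   for both).
#' @return named list of `connectome` objects (names = `subject_modality`).
#' @export
read_connectome_dir <- function(path, parcellation, modality = NULL) {
  files <- sort(list.files(path, pattern = "_(FC|SC)\\.tsv$",
                           full.names = TRUE))
  if (!is.null(modality))
    files <- files[grepl(paste0("_", modality, "\\.tsv$"), files)]
  if (!length(files)) stop(sprintf("no connectome files found in %s", path))
  out <- lapply(files, read_connectome, parcellation = parcellation)
  names(out) <- vapply(out, function(cc)
    paste(cc$subject_id, cc$modality, sep = "_"), character(1))
  out
}

#' Persist a feature matrix with sidecar metadata
#'
#' Values go to `<path>` as CSV (first column `subject_id`); per-feature
#' metadata to `<path base>_meta.csv`.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path for the values.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject_id = fm$subject_ids, fm$values,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  data.table::fwrite(fm$feature_meta, meta_path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  ids <- df$subject_id
  values <- as.matrix(df[, -1, drop = FALSE])
  meta <- data.table::fread(sub("\\.csv$", "_meta.csv", path),
                            data.table = FALSE)
  meta$node <- as.integer(meta$node)
  meta$network <- as.character(meta$network)
  feature_matrix(values, meta, ids)
}

#' Pipeline configuration files
#'
#' The configuration is a plain named list mirroring every CLI flag,
#' stored as JSON (lossless round-trip).
#'
#' @param config named list.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
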