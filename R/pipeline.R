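#' Default pipeline configuration
#'
#' A named list mirroring every CLI flag. The defaults reproduce the
#' reference analysis shape: 594 subjects, 400 nodes / 7 networks,
#' feature set A, FC + SC + GMV, concatenation, ridge, no-deconf
#' (eTIV-only) condition, 10 x 10-fold outer CV with inner 5-fold.
#'
#' @param ... overrides of any default entry.
#' @return named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, out_dir = "cogniconn_run",
    n_subjects = 594L, n_nodes = 400L, n_networks = 7L,
    n_timepoints = 296L, brain_r2 = 0.2,
    fc_filter = FALSE, n_perm = 1000L, alpha = 0.05,
    fset = "A", modalities = c("fc", "sc", "gmv"),
    approach = "concat", algorithms = "ridge",
    deconf = "no_deconf", extra_features = FALSE,
    target = "global", outer_k = 10L, repeats = 10L, inner_k = 5L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full pipeline
#'
#' Executes simulate -> features -> targets -> predict -> report on a
#' synthetic cohort, writing all products as plain-text files under
#' `config$out_dir` and returning a run manifest (also written as
#' `manifest.json`). A rerun with an unchanged configuration whose output
#' files are intact is resumed from the cached products (use `force =
#' TRUE` to recompute); determinism is guaranteed by deriving every
#' random draw from `config$seed`.
#'
#' @param config a [default_pipeline_config()]-style list.
#' @param force recompute even if cached outputs match.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), force = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  cfg_digest <- digest_config(config)
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(old$config_digest, cfg_digest) &&
        all(file.exists(file.path(config$out_dir, old$files$file))) &&
        identical(unname(tools::md5sum(file.path(config$out_dir,
                                                 old$files$file))),
                  old$files$md5)) {
      message("run_pipeline: cached outputs match configuration; resuming")
      return(invisible(old))
    }
  }
  t0 <- Sys.time()
  stages <- list()
  run_stage <- function(name, fn) {
    st <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages[[name]] <<- list(seconds = as.numeric(Sys.time() - st, "secs"))
    message(sprintf("[%s] done in %.1fs", name, stages[[name]]$seconds))
    res
  }

  ## simulate -----------------------------------------------------------
  cohort <- run_stage("simulate", function() {
    cc <- cohort_config(n_subjects = config$n_subjects,
                        n_nodes = config$n_nodes,
                        n_networks = config$n_networks,
                        n_timepoints = config$n_timepoints,
                        brain_r2 = config$brain_r2,
                        seed = config$seed,
                        keep_panels = isTRUE(config$fc_filter),
                        keep_connectomes = TRUE)
    cohort <- generate_cohort(cc)
    utils::write.csv(cohort$subjects,
                     file.path(config$out_dir, "subjects.csv"),
                     row.names = FALSE)
    cohort
  })

  ## features -----------------------------------------------------------
  feats <- run_stage("features", function() {
    parc <- cohort$parcellation
    ids <- cohort$subjects$subject_id
    fc_conns <- lapply(seq_along(ids), function(s) {
      if (isTRUE(config$fc_filter))
        fc_pipeline(cohort$panels[[s]], filter = TRUE,
                    n_perm = config$n_perm, alpha = config$alpha,
                    seed = substream_seed(config$seed, paste0("filter", s)),
                    subject_id = ids[s])
      else positive_part(fisher_z(cohort$connectomes[[s]]$fc))
    })
    sc_conns <- lapply(seq_along(ids), function(s)
      log10_sc(cohort$connectomes[[s]]$sc))
    fc_metrics <- connectome_metric_matrices(fc_conns, parc)
    sc_metrics <- connectome_metric_matrices(sc_conns, parc)
    fc_neg <- NULL
    if (config$fset == "C") {
      neg_conns <- lapply(seq_along(ids), function(s)
        negative_part(fisher_z(cohort$connectomes[[s]]$fc)))
      fc_neg <- connectome_metric_matrices(neg_conns, parc)
    }
    extra <- if (isTRUE(config$extra_features))
      as.matrix(cohort$subjects[, c("age", "sex", "education")]) else NULL
    fm <- assemble_feature_set(config$fset, fc_metrics, sc_metrics,
                               cohort$gmv, parc, fc_neg_metrics = fc_neg,
                               extra_demographics = extra)
    write_feature_matrix(fm, file.path(config$out_dir, "features.csv"))
    list(fm = fm, fc_metrics = fc_metrics, sc_metrics = sc_metrics,
         parc = parc)
  })

  ## targets ------------------------------------------------------------
  targets <- run_stage("targets", function() {
    bat <- impute_group_median(cohort$battery, cohort$subjects)
    z <- zscore_invert(bat)
    global <- pca_targets(z, "global")
    profiles <- suppressWarnings(pca_targets(z, "profiles"))
    theo <- theoretical_composite(z)
    df <- data.frame(subject_id = cohort$subjects$subject_id,
                     global = global$scores[, 1],
                     profiles$scores, theoretical = theo,
                     check.names = FALSE)
    utils::write.csv(df, file.path(config$out_dir, "targets.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(test = rownames(global$loadings),
                 global = global$loadings[, 1], profiles$loadings),
      file.path(config$out_dir, "loadings.csv"), row.names = FALSE)
    list(table = df, global = global, profiles = profiles)
  })

  ## predict ------------------------------------------------------------
  results <- run_stage("predict", function() {
    y <- switch(config$target,
                global = targets$table$global,
                theoretical = targets$table$theoretical,
                comp1 = targets$table$comp1,
                comp2 = if ("comp2" %in% names(targets$table))
                  targets$table$comp2 else stop("no second component"),
                stop("unknown target"))
    plan <- make_cv_plan(cohort$subjects$subject_id,
                         outer_k = config$outer_k,
                         repeats = config$repeats,
                         inner_k = config$inner_k,
                         seed = substream_seed(config$seed, "cv"))
    dspec <- if (config$deconf %in% c("no_deconf", "deconf"))
      deconfound_spec(config$deconf, cohort$subjects) else NULL
    blocks <- modality_blocks(feats, cohort, config)
    out <- list()
    for (alg in config$algorithms) {
      cfg_m <- model_config(alg)
      res <- if (config$approach == "stack")
        fit_predict_stacking(blocks, y, cfg_m, plan, deconf = dspec)
      else {
        X <- do.call(cbind, blocks)
        fit_predict_concat(X, y, cfg_m, plan, deconf = dspec)
      }
      fold_df <- res$folds
      fold_df$chosen <- vapply(fold_df$chosen, function(p)
        paste(names(p), unlist(p), sep = "=", collapse = ";"), character(1))
      fold_df$algorithm <- alg
      out[[alg]] <- list(result = res, folds = fold_df)
    }
    all_folds <- do.call(rbind, lapply(out, `[[`, "folds"))
    utils::write.csv(all_folds, file.path(config$out_dir, "folds.csv"),
                     row.names = FALSE)
    out
  })

  ## report -------------------------------------------------------------
  run_stage("report", function() {
    summ <- do.call(rbind, lapply(names(results), function(alg) {
      s <- summarize_performance(results[[alg]]$result)
      s$algorithm <- alg
      s
    }))
    utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    summ
  })

  files <- c("subjects.csv", "features.csv", "features_meta.csv",
             "targets.csv", "loadings.csv", "folds.csv", "summary.csv")
  files <- files[file.exists(file.path(config$out_dir, files))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("cogniconn")),
    config = unclass(config), config_digest = cfg_digest,
    seed = config$seed,
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$out_dir, files)))),
    stages = stages,
    wall_seconds = as.numeric(Sys.time() - t0, "secs"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Per-modality feature blocks used by both approaches.
modality_blocks <- function(feats, cohort, config) {
  meta <- feats$fm$feature_meta
  vals <- feats$fm$values
  blocks <- list()
  for (mod in config$modalities) {
    tag <- switch(mod, fc = "FC", sc = "SC", gmv = "GMV", mod)
    cols <- meta$modality == tag
    if (!any(cols)) stop(sprintf("modality '%s' not in feature set", mod))
    blocks[[mod]] <- vals[, cols, drop = FALSE]
  }
  if (isTRUE(config$extra_features))
    blocks$extra <- vals[, meta$modality == "extra", drop = FALSE]
  blocks
}

digest_config <- function(config) {
  # stable digest without extra packages: md5 of the canonical JSON
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
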