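#' Repeated nested cross-validation plan
#'
#' Builds the outer splits of a repeated nested k-fold scheme (default:
#' 10-fold with 10 repeats, inner 5-fold). Within each repeat the test
#' folds partition the subjects exactly once; the same plan is reused
#' across modalities and stacking layers so train/test identities are
#' preserved everywhere.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param outer_k outer folds per repeat (default 10).
#' @param repeats number of repeats (default 10).
#' @param inner_k inner folds for hyperparameter tuning (default 5).
#' @param seed integer seed; fixes all fold assignments.
#' @return object of class `cv_plan`: list with `outer` (list of entries
#'   `repeat_`, `fold`, `train_ids`, `test_ids`), `inner_k`, `outer_k`,
#'   `repeats`, `seed`, `subject_ids`.
#' @export
make_cv_plan <- function(subject_ids, outer_k = 10L, repeats = 10L,
                         inner_k = 5L, seed = 1L) {
  n <- length(subject_ids)
  if (n < outer_k) stop("need at least outer_k subjects")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  outer <- vector("list", outer_k * repeats)
  i <- 0L
  for (r in seq_len(repeats)) {
    fold <- with_seed(substream_seed(seed, paste0("repeat", r)),
                      sample(rep(seq_len(outer_k), length.out = n)))
    for (f in seq_len(outer_k)) {
      i <- i + 1L
      outer[[i]] <- list(repeat_ = r, fold = f,
                         train_ids = subject_ids[fold != f],
                         test_ids = subject_ids[fold == f])
    }
  }
  structure(list(outer = outer, outer_k = as.integer(outer_k),
                 repeats = as.integer(repeats), inner_k = as.integer(inner_k),
                 seed = as.integer(seed), subject_ids = subject_ids),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv plan: %d x %d-fold outer CV (inner %d-fold), %d subjects\n",
              x$repeats, x$outer_k, x$inner_k, length(x$subject_ids)))
  invisible(x)
}

# Deterministic per-(repeat, fold) seed for inner splits and stochastic
# learners; identical across modalities and stacking layers by design.
fold_seed <- function(plan, entry, tag = "") {
  substream_seed(plan$seed,
                 sprintf("r%df%d%s", entry$repeat_, entry$fold, tag))
}
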