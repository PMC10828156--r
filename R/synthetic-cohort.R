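#' Synthetic cohort configuration
#'
#' Describes the stated world the generator emulates: an older-adult
#' population cohort (default n = 594, ages 55--85) with a 400-node /
#' 7-network cortical parcellation, per-subject functional (correlation of
#' node time series, 296 timepoints) and structural (streamline-count-like)
#' connectomes, region-wise grey-matter volume, demographics (sex,
#' ISCED-like education 1--8, eTIV, DemTect screening), and a battery of 14
#' cognitive tests whose shared component depends linearly on demographics
#' and on a latent brain factor planted in a sparse set of nodes.
#'
#' @param n_subjects number of subjects (default 594).
#' @param n_nodes number of cortical nodes (default 400).
#' @param n_networks number of resting-state networks (default 7).
#' @param n_timepoints timepoints per functional run (default 296 = 300
#'   volumes minus 4 discarded).
#' @param n_tests number of cognitive tests (default 14).
#' @param seed master seed; every stochastic draw is a function of it.
#' @param beta_age,beta_sex,beta_edu standardized confound-to-cognition
#'   coefficients (age negative by default, mirroring age-related decline).
#' @param brain_r2 target variance share of the latent brain factor in the
#'   cognition score.
#' @param n_signal_nodes number of nodes carrying the planted brain signal
#'   (default: 20, capped at `n_nodes`).
#' @param gmv_signal,gmv_noise_sd loading of the latent brain factor on
#'   signal-node GMV, and per-node GMV noise sd (mm^3).
#' @param fc_community_strength weight of the shared network signal in node
#'   time series (within-network correlation ~ strength^2).
#' @param sc_density expected edge density of the structural connectome.
#' @param sc_weight_scale median streamline-count-like edge weight.
#' @param missing_rate per-cell missingness rate in the cognitive battery.
#' @param invert_tests indices of tests stored on an inverted scale (higher
#'   raw value = worse performance, e.g. completion times).
#' @param test_loadings length-`n_tests` loadings of each test on the
#'   cognition score, or the string `"two_factor"` for a two-block
#'   (7 + 7) factor structure.
#' @param keep_panels,keep_connectomes whether `generate_cohort` retains
#'   the node-by-time panels / the FC+SC matrices (memory heavy at full
#'   scale).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 594L, n_nodes = 400L, n_networks = 7L,
                          n_timepoints = 296L, n_tests = 14L, seed = 1L,
                          beta_age = -0.45, beta_sex = 0, beta_edu = 0.3,
                          brain_r2 = 0.2, n_signal_nodes = NULL,
                          gmv_signal = 40, gmv_noise_sd = 50,
                          fc_community_strength = 0.4,
                          sc_density = 0.25, sc_weight_scale = 20,
                          missing_rate = 0.01,
                          invert_tests = c(12L, 13L, 14L),
                          test_loadings = "two_factor",
                          keep_panels = FALSE, keep_connectomes = TRUE) {
  # default: 20 sparse signal nodes, capped for small test parcellations
  if (is.null(n_signal_nodes)) n_signal_nodes <- min(20L, as.integer(n_nodes))
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_nodes = as.integer(n_nodes),
              n_networks = as.integer(n_networks),
              n_timepoints = as.integer(n_timepoints),
              n_tests = as.integer(n_tests), seed = as.integer(seed),
              beta_age = beta_age, beta_sex = beta_sex, beta_edu = beta_edu,
              brain_r2 = brain_r2,
              n_signal_nodes = as.integer(n_signal_nodes),
              gmv_signal = gmv_signal, gmv_noise_sd = gmv_noise_sd,
              fc_community_strength = fc_community_strength,
              sc_density = sc_density, sc_weight_scale = sc_weight_scale,
              missing_rate = missing_rate,
              invert_tests = as.integer(invert_tests),
              test_loadings = test_loadings,
              keep_panels = keep_panels, keep_connectomes = keep_connectomes)
  if (cfg$n_subjects < 2L || cfg$n_nodes < cfg$n_networks)
    stop("invalid cohort dimensions")
  if (cfg$brain_r2 < 0 || cfg$brain_r2 >= 1)
    stop("brain_r2 must be in [0, 1)")
  if (cfg$sc_density <= 0 || cfg$sc_density > 1)
    stop("sc_density must be in (0, 1]")
  if (cfg$n_signal_nodes > cfg$n_nodes)
    stop("n_signal_nodes exceeds n_nodes")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate per-subject node time series
#'
#' Nodes in the same network share a latent network signal with weight
#' `community_strength`; the idiosyncratic remainder is scaled so marginal
#' variance is approximately 1. `community_strength = 0` yields independent
#' node series.
#'
#' @param parcellation a [generate_parcellation()] scheme.
#' @param n_timepoints number of timepoints (>= 30).
#' @param community_strength shared-signal weight in `[0, 1)`.
#' @param seed integer seed.
#' @return numeric matrix `n_nodes x n_timepoints`.
#' @export
generate_timeseries_panel <- function(parcellation, n_timepoints = 296L,
                                      community_strength = 0.4, seed = 1L) {
  validate_parcellation(parcellation)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 30L) stop("n_timepoints must be >= 30")
  if (community_strength < 0 || community_strength >= 1)
    stop("community_strength must be in [0, 1)")
  n <- parcellation$n_nodes
  with_seed(seed, {
    latent <- matrix(stats::rnorm(parcellation$n_networks * n_timepoints),
                     parcellation$n_networks, n_timepoints)
    noise <- matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
    panel <- community_strength * latent[parcellation$network_of, , drop = FALSE] +
      sqrt(1 - community_strength^2) * noise
  })
  dimnames(panel) <- list(paste0("node", seq_len(n)), NULL)
  panel
}

#' Generate a structural connectome (streamline-count-like weights)
#'
#' Off-diagonal edges are present independently with probability `density`;
#' present edges carry log-normal positive weights with median
#' `weight_scale`, emulating SIFT2-weighted streamline counts before the
#' log10 transform.
#'
#' @inheritParams generate_timeseries_panel
#' @param density edge density in (0, 1].
#' @param weight_scale median edge weight.
#' @return a `connectome` (modality `"SC"`), symmetric, non-negative,
#'   zero diagonal.
#' @export
generate_sc_matrix <- function(parcellation, density = 0.25,
                               weight_scale = 20, seed = 1L,
                               subject_id = "sub") {
  validate_parcellation(parcellation)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n <- parcellation$n_nodes
  with_seed(seed, {
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    k <- sum(ut)
    present <- stats::rbinom(k, 1L, density) == 1L
    w <- exp(stats::rnorm(k, log(weight_scale), 1))
    m[ut] <- ifelse(present, w, 0)
  })
  m <- m + t(m)
  connectome(m, modality = "SC", subject_id = subject_id)
}

#' Generate a full synthetic cohort
#'
#' Draws demographics, the latent brain factor, GMV/SC/FC data and the
#' cognitive battery from a [cohort_config()]. The cognition score is a
#' linear combination of standardized age, sex, education, the latent brain
#' factor (planted into the GMV of `n_signal_nodes` nodes) and Gaussian
#' noise; the achieved true R-squared values are recorded in
#' `$true_params`.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with elements `subjects` (data.frame),
#'   `parcellation`, `gmv` (subjects x nodes), `battery` (list: `scores`,
#'   `invert_flags`, `missing_mask`), `target` (the generating cognition
#'   score), `connectomes` (per subject, `fc` raw Pearson matrix and `sc`
#'   count matrix; if kept), `panels` (if kept) and `true_params`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  parc <- generate_parcellation(cfg$n_nodes, cfg$n_networks,
                                seed = substream_seed(cfg$seed, "parcellation"))

  ## demographics ------------------------------------------------------
  subjects <- with_seed(substream_seed(cfg$seed, "demographics"), {
    n <- cfg$n_subjects
    age <- stats::runif(n, 55, 85)
    sex <- stats::rbinom(n, 1L, 0.5)           # 0 = female, 1 = male
    edu <- round(6 + 1.0 * sex - 0.05 * (age - 67) + stats::rnorm(n, 0, 1.7))
    edu <- pmin(pmax(edu, 1L), 8L)
    etiv <- 1400 + 150 * sex + stats::rnorm(n, 0, 110)
    demtect <- pmin(pmax(round(15 - 0.06 * (age - 67) + stats::rnorm(n, 0, 2)),
                         0), 18)
    data.frame(subject_id = sprintf("sub%04d", seq_len(n)),
               age = age, sex = sex, education = as.integer(edu),
               etiv = etiv, demtect = as.integer(demtect),
               stringsAsFactors = FALSE)
  })

  ## cognition target --------------------------------------------------
  tp <- with_seed(substream_seed(cfg$seed, "target"), {
    n <- cfg$n_subjects
    age_z <- (subjects$age - mean(subjects$age)) / sd_pop(subjects$age)
    sex_c <- subjects$sex - mean(subjects$sex)
    edu_z <- (subjects$education - mean(subjects$education)) /
      sd_pop(subjects$education)
    b <- stats::rnorm(n)
    expl <- cfg$beta_age^2 + cfg$beta_sex^2 + cfg$beta_edu^2 + cfg$brain_r2
    noise_sd <- sqrt(max(1 - expl, 0.02))
    g <- cfg$beta_age * age_z + cfg$beta_sex * 2 * sex_c +
      cfg$beta_edu * edu_z + sqrt(cfg$brain_r2) * b +
      noise_sd * stats::rnorm(n)
    gen <- cbind(age_z, sex_c, edu_z, b)
    r2_linear <- summary(stats::lm(g ~ gen))$r.squared
    r2_brain <- stats::cor(g, b)^2
    list(b = b, target = g, r2_linear = r2_linear, r2_brain = r2_brain,
         noise_sd = noise_sd)
  })

  ## GMV with age decline and planted brain signal ----------------------
  signal_nodes <- with_seed(substream_seed(cfg$seed, "signal_nodes"),
                            sort(sample.int(cfg$n_nodes, cfg$n_signal_nodes)))
  gmv <- with_seed(substream_seed(cfg$seed, "gmv"), {
    base <- stats::rnorm(cfg$n_nodes, 1000, 100)
    slope <- stats::rnorm(cfg$n_nodes, -30, 10)   # mm^3 per sd of age
    age_z <- (subjects$age - 70) / 8.66           # ~sd of U(55,85)
    g <- outer(rep(1, cfg$n_subjects), base) +
      outer(age_z, slope) +
      matrix(stats::rnorm(cfg$n_subjects * cfg$n_nodes, 0, cfg$gmv_noise_sd),
             cfg$n_subjects, cfg$n_nodes)
    g[, signal_nodes] <- g[, signal_nodes] + cfg$gmv_signal * tp$b
    pmax(g, 1)
  })
  colnames(gmv) <- paste0("node", seq_len(cfg$n_nodes))
  rownames(gmv) <- subjects$subject_id

  ## connectomes --------------------------------------------------------
  connectomes <- NULL
  panels <- NULL
  if (cfg$keep_connectomes || cfg$keep_panels) {
    if (cfg$keep_panels) panels <- vector("list", cfg$n_subjects)
    if (cfg$keep_connectomes) connectomes <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      panel <- generate_timeseries_panel(
        parc, cfg$n_timepoints, cfg$fc_community_strength,
        seed = substream_seed(cfg$seed, paste0("panel", s)))
      sc <- generate_sc_matrix(
        parc, cfg$sc_density, cfg$sc_weight_scale,
        seed = substream_seed(cfg$seed, paste0("sc", s)),
        subject_id = subjects$subject_id[s])
      # mild planting of the brain factor into signal-node SC rows keeps
      # the latent recoverable from SC as well (secondary channel)
      mult <- 1 + 0.1 * tp$b[s]
      if (mult > 0.1) {
        sc$matrix[signal_nodes, ] <- sc$matrix[signal_nodes, ] * mult
        sc$matrix[, signal_nodes] <- t(sc$matrix[signal_nodes, , drop = FALSE])
      }
      if (cfg$keep_panels) panels[[s]] <- panel
      if (cfg$keep_connectomes) {
        fc <- correlation_matrix(panel, subject_id = subjects$subject_id[s])
        connectomes[[s]] <- list(fc = fc, sc = sc)
      }
    }
    if (!is.null(connectomes)) names(connectomes) <- subjects$subject_id
    if (!is.null(panels)) names(panels) <- subjects$subject_id
  }

  ## cognitive battery --------------------------------------------------
  battery <- with_seed(substream_seed(cfg$seed, "battery"), {
    n <- cfg$n_subjects; p <- cfg$n_tests
    if (identical(cfg$test_loadings, "two_factor")) {
      load_g <- rep(0.65, p)
      spec <- stats::rnorm(n)  # second shared factor, orthogonal to g
      block <- rep(c(1, -1), each = ceiling(p / 2))[seq_len(p)]
      load_s <- 0.35 * block
    } else {
      load_g <- rep_len(cfg$test_loadings, p)
      spec <- rep(0, n)
      load_s <- rep(0, p)
    }
    uniq <- sqrt(pmax(1 - load_g^2 - load_s^2, 0.05))
    scores <- outer(tp$target, load_g) + outer(spec, load_s) +
      sweep(matrix(stats::rnorm(n * p), n, p), 2L, uniq, "*")
    invert_flags <- seq_len(p) %in% cfg$invert_tests
    scores[, invert_flags] <- -scores[, invert_flags]
    missing_mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    scores[missing_mask] <- NA_real_
    colnames(scores) <- paste0("test", seq_len(p))
    rownames(scores) <- subjects$subject_id
    list(scores = scores, invert_flags = invert_flags,
         missing_mask = missing_mask)
  })

  structure(
    list(subjects = subjects, parcellation = parc, gmv = gmv,
         battery = battery, target = tp$target,
         connectomes = connectomes, panels = panels,
         config = cfg,
         true_params = list(b = tp$b, signal_nodes = signal_nodes,
                            r2_linear = tp$r2_linear,
                            r2_brain = tp$r2_brain,
                            noise_sd = tp$noise_sd)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d subjects, %d nodes / %d networks, %d tests\n",
    x$config$n_subjects, x$config$n_nodes, x$config$n_networks,
    x$config$n_tests))
  cat(sprintf("  true R2 (linear predictor): %.3f; brain share: %.3f\n",
              x$true_params$r2_linear, x$true_params$r2_brain))
  invisible(x)
}

#' Flag subjects whose mean GMV is an outlier
#'
#' Quality-control rule: mean GMV more than `k` times the inter-quartile
#' range away from the quartiles. Off by default during synthesis; exposed
#' for pipelines applying the exclusion.
#'
#' @param gmv subjects x nodes GMV matrix.
#' @param k IQR multiplier (default 1.5).
#' @return logical vector, `TRUE` = outlier.
#' @export
gmv_outliers <- function(gmv, k = 1.5) {
  m <- rowMeans(gmv)
  q <- stats::quantile(m, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  m < q[1] - k * iqr | m > q[2] + k * iqr
}

#' Write a cohort to plain-text files
#'
#' Emits `subjects.csv`, `battery.csv`, `gmv.csv`, `parcellation.tsv`,
#' one delimited square matrix per subject and modality under
#' `connectomes/`, and a `manifest.json` recording the configuration, the
#' seed and every file path.
#'
#' @param cohort a [generate_cohort()] result (with connectomes kept).
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  bat <- data.frame(subject_id = cohort$subjects$subject_id,
                    cohort$battery$scores, check.names = FALSE)
  utils::write.csv(bat, file.path(dir, "battery.csv"), row.names = FALSE)
  gmv <- data.frame(subject_id = cohort$subjects$subject_id, cohort$gmv,
                    check.names = FALSE)
  utils::write.csv(gmv, file.path(dir, "gmv.csv"), row.names = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  files <- c("subjects.csv", "battery.csv", "gmv.csv", "parcellation.tsv")
  if (!is.null(cohort$connectomes)) {
    cdir <- file.path(dir, "connectomes")
    dir.create(cdir, showWarnings = FALSE)
    for (id in names(cohort$connectomes)) {
      for (mod in c("fc", "sc")) {
        f <- file.path(cdir, sprintf("%s_%s.tsv", id, toupper(mod)))
        write_connectome(cohort$connectomes[[id]][[mod]], f)
        files <- c(files, file.path("connectomes", basename(f)))
      }
    }
  }
  manifest <- list(kind = "cohort", seed = cohort$config$seed,
                   config = unclass(cohort$config), files = files,
                   invert_flags = cohort$battery$invert_flags,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
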