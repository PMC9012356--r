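#' Study run configuration
#'
#' Validated bag of parameters tying the simulation, preprocessing, ratio and
#' evaluation stages together. Unknown keys are rejected; the fully resolved
#' configuration is attached to every run's output.
#'
#' @param seed integer RNG seed for the whole run.
#' @param n_per_group named integer vector of phantom counts per group
#'   (defaults to 2 per group, a demonstration size; the value-level
#'   simulations use the full printed sizes instead).
#' @param mode preprocessing mode, `"oracle"` or `"estimated"`.
#' @param noise_sigma,bias_amplitude phantom parameters (see
#'   [phantom_spec()]).
#' @param grid_shape,voxel_size_mm phantom grid.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param threshold atlas probability threshold.
#' @param vol_rho,extent_rho cohort-simulation correlations (see
#'   [cohort_spec()]).
#' @param ... rejected; guards against misspelled keys.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_group = c(`MSA-C` = 2L, SCA3 = 2L, SCA6 = 2L,
                                       Control = 2L),
                       mode = c("oracle", "estimated"),
                       noise_sigma = 5, bias_amplitude = 0.2,
                       grid_shape = c(64, 64, 64),
                       voxel_size_mm = c(2, 2, 2),
                       fwhm_mm = 8, threshold = 0.90,
                       vol_rho = 0.6, extent_rho = 0.85, ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown configuration keys: %s",
                 paste(names(extra), collapse = ", ")))
  mode <- match.arg(mode)
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 mode = mode, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 fwhm_mm = fwhm_mm, threshold = threshold,
                 vol_rho = vol_rho, extent_rho = extent_rho),
            class = "run_config")
}

#' Write / read a run configuration as a flat key-value file
#' @param config a [run_config()].
#' @param path text file path.
#' @return `path` invisibly / a `run_config`.
#' @export
write_config <- function(config, path) {
  enc <- function(v) paste(format(v, digits = 17), collapse = ",")
  keys <- names(unclass(config))
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    val <- if (!is.null(names(v)) && any(nzchar(names(v))))
      paste(sprintf("%s=%s", names(v), format(v, digits = 17)),
            collapse = ",")
    else enc(v)
    sprintf("%s: %s", k, val)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  out <- list()
  for (p in kv) {
    k <- p[1]; v <- p[2]
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (all(grepl("=", parts))) {
      nm <- sub("=.*", "", parts)
      vv <- as.numeric(sub(".*=", "", parts))
      names(vv) <- nm
      out[[k]] <- vv
    } else {
      num <- suppressWarnings(as.numeric(parts))
      out[[k]] <- if (anyNA(num)) parts else num
    }
  }
  do.call(run_config, out)
}

#' Run an image-level phantom study
#'
#' Draws per-subject MCP target ratios from the printed group moments, builds
#' one phantom per subject, pushes each through the full measurement pipeline
#' ([measure_subject()]), and returns the per-subject results table. Two runs
#' with the same configuration produce identical tables.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the cohort table is written
#'   as `phantom_cohort.csv` (UTF-8, "." decimal, header row) together with
#'   the resolved configuration.
#' @return `data.frame` with one row per subject: `subject_id`, `group`,
#'   `target_ratio`, the [measure_subject()] columns, and `mode`.
#' @export
run_phantom_study <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config()")
  gm <- group_moments()
  gm <- gm[gm$group %in% names(config$n_per_group), , drop = FALSE]
  set.seed(config$seed)
  plan <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
    n <- config$n_per_group[[gm$group[i]]]
    data.frame(group = gm$group[i],
               target = stats::rnorm(n, gm$ratio_mean[i], gm$ratio_sd[i]))
  }))
  plan$target <- pmin(pmax(plan$target, -0.5), 0.5)
  plan$seed <- config$seed + seq_len(nrow(plan))
  atlas <- make_atlas(config$grid_shape, config$voxel_size_mm)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    spec <- phantom_spec(grid_shape = config$grid_shape,
                         voxel_size_mm = config$voxel_size_mm,
                         mcp_target_ratio = plan$target[i],
                         bias_amplitude = config$bias_amplitude,
                         noise_sigma = config$noise_sigma,
                         seed = plan$seed[i])
    ph <- make_phantom(spec)
    res <- tryCatch(
      measure_subject(ph, atlas, mode = config$mode,
                      fwhm_mm = config$fwhm_mm,
                      threshold = config$threshold),
      error = function(e) stop(sprintf(
        "stage measure_subject failed for subject %d (%s): %s",
        i, plan$group[i], conditionMessage(e))))
    cbind(data.frame(subject_id = sprintf("P%03d", i),
                     group = plan$group[i],
                     target_ratio = plan$target[i]),
          res, data.frame(mode = config$mode))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "phantom_cohort.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "run_config.txt"))
  }
  out
}

#' ROC/AUC evaluation of a value-level cohort
#'
#' For each pairwise group comparison and each marker (ratio, normalised
#' volume; lower = diseased) computes the empirical ROC, the AUC with its
#' DeLong 95% CI, and the closest-to-corner cutoff; runs the paired DeLong
#' test between the two markers within each comparison; screens each group's
#' ratio values for outliers with the Grubbs test; and runs the
#' [group_comparisons()] battery.
#'
#' @param cohort a [simulate_value_cohort()]-style table.
#' @param comparisons list of `c(diseased, reference)` group-name pairs;
#'   defaults to the four published comparisons.
#' @return list with `auc_table` (`data.frame`), `delong` (`data.frame`),
#'   `grubbs` (named list), `groups` ([group_comparisons()] output).
#' @export
evaluate_cohort <- function(cohort,
                            comparisons = list(c("MSA-C", "SCA3"),
                                               c("MSA-C", "SCA6"),
                                               c("MSA-C", "Control"),
                                               c("SCA3", "SCA6"))) {
  markers <- c(ratio = "mcp_ratio", volume = "mcp_volume_norm")
  rows <- list(); drows <- list()
  for (cmp in comparisons) {
    sel <- cohort$group %in% cmp
    lab <- cohort$group[sel] == cmp[1]
    nm <- paste(cmp, collapse = " vs ")
    for (mk in names(markers)) {
      sc <- cohort[[markers[[mk]]]][sel]
      r <- roc_auc(sc, lab, direction = "lower")
      cut <- optimal_cutoff(r)
      rows[[paste(nm, mk)]] <- data.frame(
        comparison = nm, marker = mk, auc = r$auc, se = r$auc_se,
        ci_lo = r$ci_95[1], ci_hi = r$ci_95[2],
        cutoff = cut$threshold, sensitivity = cut$sensitivity,
        specificity = cut$specificity)
    }
    dl <- delong_test(cohort$mcp_ratio[sel], cohort$mcp_volume_norm[sel],
                      lab, direction = "lower")
    drows[[nm]] <- data.frame(comparison = nm, auc_ratio = dl$auc_a,
                              auc_volume = dl$auc_b, z = dl$z, p = dl$p)
  }
  gr <- lapply(split(cohort$mcp_ratio, cohort$group), function(x)
    if (length(x) >= 3 && stats::sd(x) > 0) grubbs(x) else NULL)
  list(auc_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       delong = do.call(rbind, c(drows, list(make.row.names = FALSE))),
       grubbs = gr,
       groups = group_comparisons(cohort))
}

#' Mean empirical AUC of two Gaussian biomarker groups over replicates
#'
#' Repeatedly draws a diseased group `Normal(mean1, sd1)` of size `n1` and a
#' reference group `Normal(mean0, sd0)` of size `n0`, computes the empirical
#' (tie-corrected rank) AUC with lower values indicating disease, and
#' averages over replicates. This is the simulation used to check the
#' published group-separation figures against their printed group moments.
#'
#' @param n1,mean1,sd1 diseased group size and moments.
#' @param n0,mean0,sd0 reference group size and moments.
#' @param reps number of replicate cohorts (default 2000).
#' @param seed optional RNG seed.
#' @return list with `mean_auc`, `sd_auc`, `reps`.
#' @export
simulate_mean_auc <- function(n1, mean1, sd1, n0, mean0, sd0,
                              reps = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- rep(c(TRUE, FALSE), c(n1, n0))
  aucs <- vapply(seq_len(reps), function(i) {
    x <- c(stats::rnorm(n1, mean1, sd1), stats::rnorm(n0, mean0, sd0))
    r <- rank(-x)
    (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), reps = reps)
}
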