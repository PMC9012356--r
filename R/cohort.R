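#' Printed study-group moments
#'
#' The four diagnostic groups with their sizes and the reported MCP sT1w/T2w
#' ratio and ICV-normalised MCP volume means/SDs; these are the defaults every
#' value-level simulation draws from.
#'
#' @return `data.frame` with columns `group`, `n`, `ratio_mean`, `ratio_sd`,
#'   `vol_mean`, `vol_sd`, `age_mean`, `age_sd`, `male`, `female`,
#'   `dur_median`, `dur_min`, `dur_max`.
#' @export
group_moments <- function() {
  data.frame(
    group = c("MSA-C", "SCA3", "SCA6", "Control"),
    n = c(32L, 8L, 16L, 17L),
    ratio_mean = c(0.07, 0.17, 0.18, 0.19),
    ratio_sd = c(0.06, 0.03, 0.03, 0.03),
    vol_mean = c(0.20, 0.23, 0.31, 0.34),
    vol_sd = c(0.06, 0.04, 0.05, 0.05),
    age_mean = c(62.8, 51.4, 58.3, 62.4),
    age_sd = c(9.4, 16.7, 13.7, 10.8),
    male = c(19L, 2L, 10L, 9L),
    female = c(13L, 6L, 6L, 8L),
    dur_median = c(2.3, 4.5, 3.5, NA),
    dur_min = c(0.8, 0.8, 0.3, NA),
    dur_max = c(5.9, 5.7, 9.8, NA),
    stringsAsFactors = FALSE)
}

#' Cohort simulation parameters
#'
#' @param groups per-group sizes and moments, as in [group_moments()] (the
#'   default). SDs must be nonnegative, sizes >= 1.
#' @param vol_rho within-subject correlation between the ratio draw and the
#'   normalised-volume draw, in `[-1, 1]` (default 0.6, matching the sign and
#'   rough size of the reported ratio-volume association in MSA-C).
#' @param extent_rho strength of the monotone-noisy link between the ratio
#'   and the ordinal 0-3 hyperintensity-extent score, in `[-1, 1]`
#'   (default 0.85; the link itself is decreasing: lower ratio, higher
#'   extent).
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = group_moments(), vol_rho = 0.6,
                        extent_rho = 0.85, seed = NULL) {
  stopifnot(all(c("group", "n", "ratio_mean", "ratio_sd", "vol_mean",
                  "vol_sd") %in% names(groups)))
  if (any(groups$n < 1)) stop("group sizes must be >= 1")
  if (any(groups$ratio_sd < 0) || any(groups$vol_sd < 0))
    stop("SDs must be >= 0")
  if (abs(vol_rho) > 1 || abs(extent_rho) > 1)
    stop("correlations must lie in [-1, 1]")
  structure(list(groups = groups, vol_rho = vol_rho,
                 extent_rho = extent_rho, seed = seed),
            class = "cohort_spec")
}

#' Simulate a value-level cohort
#'
#' Draws one row per subject: group label, Gaussian MCP ratio value, Gaussian
#' ICV-normalised MCP volume (correlated with the ratio draw at `vol_rho`),
#' an ordinal 0-3 extent score monotone-noisily decreasing in the ratio, and
#' demographics (age, sex, disease duration) matched to the printed
#' group-level summaries. Reproducible under `seed`.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `subject_id`, `group`, `age`, `sex`,
#'   `duration`, `mcp_ratio`, `mcp_volume_norm`, `extent_score`.
#' @export
simulate_value_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec()")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  g <- spec$groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    n <- g$n[i]
    z_r <- stats::rnorm(n)
    z_v <- spec$vol_rho * z_r +
      sqrt(1 - spec$vol_rho^2) * stats::rnorm(n)
    ratio <- g$ratio_mean[i] + g$ratio_sd[i] * z_r
    vol <- g$vol_mean[i] + g$vol_sd[i] * z_v
    # extent latent: standardized severity (low ratio = severe) + noise
    sev <- (0.19 - ratio) / 0.06
    lat <- spec$extent_rho * sev +
      sqrt(1 - spec$extent_rho^2) * stats::rnorm(n)
    extent <- findInterval(lat, c(0.6, 1.2, 1.8))
    age <- if (!is.na(g$age_mean[i]))
      stats::rnorm(n, g$age_mean[i], g$age_sd[i]) else rep(NA_real_, n)
    p_male <- if (!is.null(g$male)) g$male[i] / (g$male[i] + g$female[i])
      else 0.5
    sex <- ifelse(stats::runif(n) < p_male, "M", "F")
    dur <- if (!is.na(g$dur_median[i])) {
      # lognormal matched to the printed median, clamped to the printed range
      d <- stats::rlnorm(n, log(g$dur_median[i]), 0.55)
      pmin(pmax(d, g$dur_min[i]), g$dur_max[i])
    } else rep(NA_real_, n)
    data.frame(group = g$group[i], age = age, sex = sex, duration = dur,
               mcp_ratio = ratio, mcp_volume_norm = vol,
               extent_score = extent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
  out$group <- factor(out$group, levels = g$group)
  out
}

#' Reviewer error model for visual ratings
#'
#' Per-reviewer sensitivity and specificity for binary signs (Bernoulli
#' flips of the truth), plus a symmetric transition noise for ordinal 0/1/2
#' grades (each grade moves one step up or down with probability
#' `ordinal_noise / 2` each, clamped to the valid range).
#'
#' @param sensitivity,specificity numeric vectors in `[0, 1]`, one entry per
#'   reviewer (defaults: the three reviewers' MCP-hyperintensity operating
#'   points for MSA vs SCA3).
#' @param ordinal_noise per-step transition probability in `[0, 1]`.
#' @return object of class `rater_model`.
#' @export
rater_model <- function(sensitivity = c(0.906, 0.969, 0.844),
                        specificity = c(0.750, 0.125, 0.875),
                        ordinal_noise = 0.1) {
  if (length(sensitivity) != length(specificity))
    stop("need one sensitivity and one specificity per reviewer")
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  if (ordinal_noise < 0 || ordinal_noise > 1)
    stop("`ordinal_noise` must lie in [0, 1]")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 ordinal_noise = ordinal_noise,
                 n_reviewers = length(sensitivity)),
            class = "rater_model")
}

#' Simulate reviewer ratings from subject-level truth
#'
#' Binary truths are flipped reviewer-wise with the model's
#' sensitivity/specificity; ordinal truths (grades 0/1/2) receive symmetric
#' one-step transition noise. Reproducible under `seed`.
#'
#' @param truth list with any of: `mcp_hyper` (logical per subject),
#'   `hcb_grade` (integer 0..2 per subject).
#' @param model a [rater_model()].
#' @param seed RNG seed.
#' @return `data.frame` with one row per subject and one column per
#'   sign/reviewer combination (`<sign>_r<j>`).
#' @export
simulate_ratings <- function(truth, model = rater_model(), seed = NULL) {
  if (!inherits(model, "rater_model")) stop("`model` must be a rater_model()")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  if (!is.null(truth$mcp_hyper)) {
    tv <- as.logical(truth$mcp_hyper)
    for (j in seq_len(model$n_reviewers)) {
      p <- ifelse(tv, model$sensitivity[j], 1 - model$specificity[j])
      out[[sprintf("mcp_hyper_r%d", j)]] <-
        as.integer(stats::runif(length(tv)) < p)
    }
  }
  if (!is.null(truth$hcb_grade)) {
    g <- as.integer(truth$hcb_grade)
    if (any(g < 0 | g > 2)) stop("hcb_grade must be 0, 1 or 2")
    for (j in seq_len(model$n_reviewers)) {
      u <- stats::runif(length(g))
      step <- ifelse(u < model$ordinal_noise / 2, -1L,
                     ifelse(u < model$ordinal_noise, 1L, 0L))
      out[[sprintf("hcb_grade_r%d", j)]] <- pmin(pmax(g + step, 0L), 2L)
    }
  }
  if (!length(out)) stop("`truth` holds no recognised signs")
  as.data.frame(out)
}

#' Group-comparison battery for a cohort table
#'
#' The statistical suite applied to a (simulated or measured) cohort:
#' one-way ANCOVA of the biomarker on group with age as covariate; a
#' Kruskal-Wallis test of disease duration across patient groups with
#' pairwise exact Mann-Whitney post-hocs at a Bonferroni-adjusted alpha;
#' a chi-square test of the sex distribution; Spearman correlation between
#' extent score and ratio within MSA-C; Pearson correlation between ratio
#' and normalised volume within MSA-C.
#'
#' @param cohort a [simulate_value_cohort()]-style `data.frame`.
#' @param value name of the biomarker column for the ANCOVA (default
#'   `"mcp_ratio"`).
#' @param alpha familywise level for the post-hoc tests (default 0.05).
#' @return list with elements `ancova`, `kruskal`, `pairwise` (data.frame),
#'   `adjusted_alpha`, `chisq_sex`, `spearman_extent`, `pearson_volume`.
#' @export
group_comparisons <- function(cohort, value = "mcp_ratio", alpha = 0.05) {
  if (!all(c("group", value) %in% names(cohort)))
    stop("cohort must have `group` and the value column")
  if (min(table(cohort$group)) < 2) stop("insufficient group sizes")
  fml <- stats::as.formula(paste(value, "~ age + group"))
  fit <- stats::lm(fml, data = cohort)
  an <- stats::anova(fit)
  ancova <- list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
                 df = unname(an["group", "Df"]))

  pat <- cohort[!is.na(cohort$duration), , drop = FALSE]
  pat$group <- droplevels(pat$group)
  kr <- stats::kruskal.test(duration ~ group, data = pat)
  gl <- levels(pat$group)
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], p = NA_real_)
  for (i in seq_len(m)) {
    xa <- pat$duration[pat$group == pairs[1, i]]
    xb <- pat$duration[pat$group == pairs[2, i]]
    pw$p[i] <- suppressWarnings(
      stats::wilcox.test(xa, xb, exact = TRUE)$p.value)
  }
  adjusted_alpha <- alpha / m
  pw$significant <- pw$p < adjusted_alpha

  chi <- suppressWarnings(
    stats::chisq.test(table(cohort$group, cohort$sex)))

  msa <- cohort[cohort$group == levels(cohort$group)[1], , drop = FALSE]
  sp <- if (all(c("extent_score", "mcp_ratio") %in% names(msa)))
    suppressWarnings(stats::cor.test(msa$extent_score, msa$mcp_ratio,
                                     method = "spearman")) else NULL
  pe <- if (all(c("mcp_volume_norm", "mcp_ratio") %in% names(msa)))
    stats::cor.test(msa$mcp_ratio, msa$mcp_volume_norm,
                    method = "pearson") else NULL

  list(ancova = ancova,
       kruskal = list(H = unname(kr$statistic), p = kr$p.value),
       pairwise = pw, adjusted_alpha = adjusted_alpha,
       chisq_sex = list(statistic = unname(chi$statistic), p = chi$p.value),
       spearman_extent = if (!is.null(sp))
         list(rho = unname(sp$estimate), p = sp$p.value) else NULL,
       pearson_volume = if (!is.null(pe))
         list(r = unname(pe$estimate), p = pe$p.value) else NULL)
}
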