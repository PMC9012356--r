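# mcpratio

Quantifying middle cerebellar peduncle (MCP) degeneration with the
standardized T1w/T2w ratio, and evaluating it as a diagnostic biomarker.

The cerebellar subtype of multiple system atrophy (MSA-C) degenerates the
pontocerebellar fibres of the MCP early — demyelination that lowers the
T1w/T2w contrast — while the spinocerebellar ataxias that mimic it
clinically (SCA3, SCA6) spare the MCP largely or entirely. This package
implements, end to end:

* **The biomarker.** From a co-registered T1w/T2w pair: the grey-matter
  scaling factor `s = median(T1w_GM) / median(T2w_GM)`, the standardized
  ratio map

  `sT1w/T2w = (T1w − s·T2w) / (T1w + s·T2w)`,

  8-mm FWHM mask-normalised Gaussian smoothing, bilateral median extraction
  in a probabilistic MCP atlas thresholded at 90% probability, and the
  ICV-normalised MCP volume (reported ×10³). The map is bounded in (−1, 1)
  and invariant to independent global rescaling of either input image.
* **Desk-scale preprocessing** honouring the contracts of the standard
  tools: polynomial log-domain bias-field correction, rigid registration,
  Otsu + morphology skull-stripping, k-means tissue segmentation — each
  swappable for generator ground truth ("oracle-mask" mode).
* **A synthetic data generator**: multi-contrast brain phantoms whose
  noiseless pipeline output equals the constructed MCP ratio exactly, a
  mirrored probabilistic MCP atlas, value-level cohorts drawn from the
  published group moments (32 MSA-C / 8 SCA3 / 16 SCA6 / 17 controls), and
  a reviewer-error simulator for visual ratings.
* **The diagnostics layer**: empirical ROC/AUC with DeLong variance and the
  paired DeLong test, closest-to-corner cutoffs, Clopper–Pearson exact
  intervals, exact binomial accuracy comparisons, ICC(2,1) inter-rater
  agreement, the Grubbs outlier screen, and the covariate-adjusted group
  comparison battery (ANCOVA, Kruskal–Wallis + exact Mann–Whitney with
  Bonferroni correction, chi-square, Spearman/Pearson).

No patient data are used anywhere: image-level stages run on phantoms, and
the published reviewer-performance table is reconstructed exactly from the
printed group sizes.

## Worked example

Generate one MSA-C-like phantom (target MCP ratio 0.07, default noise and
bias), measure it with fully estimated preprocessing, and evaluate a
simulated cohort:

```r
library(mcpratio)

ph  <- make_phantom(phantom_spec(mcp_target_ratio = 0.07, seed = 42))
res <- measure_subject(ph, mode = "estimated")
res[c("s", "mcp_value", "mcp_volume_norm")]
#>          s mcp_value mcp_volume_norm
#> 1 0.905056 0.0710604        0.341025
```

The estimated scaling factor sits near the construction value (100/110 ≈
0.909), the measured MCP ratio recovers the 0.07 target to ~0.001, and the
normalised MCP volume matches the published control mean (0.34 × 10⁻³).

```r
co <- simulate_value_cohort(cohort_spec(seed = 30))
ev <- evaluate_cohort(co)
subset(ev$auc_table, marker == "ratio" & comparison == "MSA-C vs SCA3")
#>      comparison marker   auc     se ci_lo ci_hi cutoff sensitivity specificity
#> 1 MSA-C vs SCA3  ratio 0.953 0.0307 0.893     1  0.116       0.844           1
```

One simulated cohort at the printed group sizes separates MSA-C from SCA3
with AUC ≈ 0.95 (the published point estimate is 0.934 with CI 0.854–1.000;
single draws at n = 32 vs 8 scatter by several hundredths). Averaging the
empirical AUC over 2000 replicate cohorts reproduces the published value to
~0.001 (see below).

The numbered drivers under `analysis/` run the full workflow and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_phantoms.R    # phantom cohort + NIfTI demo
Rscript analysis/02_ratio_pipeline.R       # oracle vs estimated recovery
Rscript analysis/03_cohort_diagnostics.R   # ROC/AUC, DeLong, ANCOVA, Grubbs
Rscript analysis/04_rater_agreement.R      # reviewer table, binomial, ICC
```

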