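---
title: "Methods: the standardized T1w/T2w ratio for the middle cerebellar peduncle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the standardized T1w/T2w ratio for the middle cerebellar peduncle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpratio)
```

## The biomarker

Degeneration of the middle cerebellar peduncle (MCP) — demyelination and
gliosis of the pontocerebellar fibres — is an early feature of the cerebellar
subtype of multiple system atrophy (MSA-C) and is much milder in the
spinocerebellar ataxias (SCA3, SCA6) that mimic it clinically. The
standardized T1w/T2w ratio converts an ordinary T1-weighted/T2-weighted image
pair into a unit-free, scanner-comparable contrast that falls where myelin is
lost:

1. **Scaling factor.** `s = median(T1w in GM) / median(T2w in GM)`, both
   medians over a grey-matter mask. Scaling the T2w image by `s` (giving
   `sT2`) puts the two contrasts on a common intensity scale.
2. **Ratio map.** `sT1w/T2w = (T1w − sT2) / (T1w + sT2)` voxelwise. The map
   is bounded in (−1, 1) wherever both inputs are positive and is invariant
   to independent global rescaling of either input, because `s` absorbs any
   such factor — the property that makes values comparable across subjects
   and scanners.
3. **Smoothing.** An 8-mm full-width-at-half-maximum Gaussian kernel
   (`sigma = FWHM / (2 sqrt(2 ln 2))`, converted to voxels per axis),
   applied with mask-normalised convolution so that invalid voxels
   (non-positive denominator) are excluded rather than zero-filled.
4. **ROI statistic.** A probabilistic MCP atlas is thresholded at 90%
   probability (inclusive) on each side; the subject's MCP value is the mean
   of the left and right ROI **medians**.
5. **Volumetry.** The thresholded atlas mask volume, averaged over sides and
   divided by the intracranial volume (ICV, the brain-mask volume), reported
   as ratio × 10³.

The per-subject outputs are the MCP sT1w/T2w ratio value and the
ICV-normalised MCP volume; the diagnostics layer evaluates both as
classifiers (lower value = diseased).

## What the phantom generator emulates — and what it does not

No patient images are distributed, so every image-level computation is
exercised on synthetic multi-contrast phantoms:

* a stylised ellipsoidal head (CSF shell, grey-matter ribbon, white-matter
  core) with a brainstem/cerebellum block holding the two MCP regions;
* piecewise-constant tissue intensities with T1w (CSF < GM < WM) and T2w
  (WM < GM < CSF) contrast;
* a smooth multiplicative bias field — the exponential of a random
  order-2 polynomial, normalised to in-brain mean 1, shared by both
  contrasts (a receiver-coil interpretation), with peak fractional deviation
  `bias_amplitude` (default 0.2);
* additive Gaussian noise (default SD 5 on tissue intensities of 60–220,
  i.e. roughly the signal-to-noise of a 1.5-T acquisition), with a Rician
  option; Gaussian is the default for desk-scale simplicity and is a
  documented deviation from magnitude-image physics;
* optionally, a thick-slice (boxcar-averaged) and rigidly offset T2w grid to
  emulate separately acquired 2D T2w images.

**Calibration.** Inside the brainstem/cerebellum block the T2w intensity is
back-solved as `T2w = T1w (1 − r*) / ((1 + r*) s)` from the noiseless
grey-matter scaling factor `s` and the target ratio `r*`, so the noiseless
pipeline output equals `r*` exactly. The block is a box sized so that every
ROI voxel's entire (3-sigma-truncated) smoothing kernel stays inside the
constant-ratio region; this is what makes the noiseless recovery exact to
float precision rather than merely approximate. Default per-group targets
are the published group means (0.07 ± 0.06 MSA-C, 0.17 ± 0.03 SCA3,
0.18 ± 0.03 SCA6, 0.19 ± 0.03 controls, n = 32/8/16/17), and the atlas ROI
is sized so the control phantom's normalised MCP volume is ≈ 0.34 × 10⁻³,
the published control mean.

The phantom is deliberately *not* anatomy: no gyri, no partial-volume
mixing, no k-space artefacts, and tissue classes are exactly Gaussian around
their means. Passing tests therefore demonstrate that the pipeline's
arithmetic, invariances and error propagation are correct, not that the
biomarker separates real patient groups; the distributional form of MCP
values within real groups (we assume Gaussian; the published outlier
handling hints at heavier tails) is likewise an assumption, confined to the
value-level simulator.

## Preprocessing choices

The published pipeline delegates preprocessing to standard neuroimaging
tools; this package re-implements the *contracts* at desk scale:

* **Bias field**: least-squares fit of an order-2 polynomial to
  log-intensity in a mask, exponentiated and normalised to in-mask mean 1.
  When tissue labels are available the fit includes per-tissue intercepts,
  so piecewise-constant anatomy is not absorbed into the field (the idea
  behind segmentation-coupled bias models). Because the generator's true
  log-field is itself an order-2 polynomial, recovery on phantoms is exact
  up to normalisation. **One** field is estimated from the T1w image
  (two segment/fit/correct passes) and divided out of *both* contrasts:
  correcting each contrast with an independently fitted field lets small
  contrast-dependent fit errors break the voxelwise cancellation of the
  common coil field in the ratio and biased the MCP value by ~0.03 in
  development experiments; the shared field restores exact cancellation and
  leaves residual errors around 0.002.
* **Correction**: voxelwise division, followed by an in-mask mean-restoring
  rescale — division by a mean-1 field does not by itself preserve the mean
  of the quotient, so the rescale makes the "intensity scale preserved"
  contract exact.
* **Brain mask**: Otsu threshold on *log-compressed* intensities (plain Otsu
  on a multimodal histogram sometimes prefers the CSF/GM split; compression
  makes the air/tissue gap dominate), then the largest 6-connected
  component and a one-voxel morphological closing. The mask volume defines
  the ICV.
* **Segmentation**: three-class 1-D k-means on in-mask T1w intensities with
  deterministic quantile initialisation, classes relabelled by ascending
  mean so CSF < GM < WM. The output depends only on intensity order, never
  on RNG state.
* **Registration**: 6-parameter rigid, derivative-free Nelder–Mead over a
  mean-squared-difference cost with trilinear resampling; multi-start from
  the identity. MSE presumes same-contrast pairs, so the cross-contrast
  T1w–T2w co-registration uses the `identity` mode (the generator produces
  both contrasts on one grid, the spec's default); the optimiser is
  exercised on same-contrast pairs with known injected transforms, where it
  recovers 5°/3 mm offsets to ~0.03°/0.01 mm. Resampling outside the source
  grid yields zero plus an out-of-field flag.
* **Oracle-mask mode**: every preprocessing output can be replaced by
  generator truth, isolating ratio/statistics testing from segmentation
  error.

Voxel indices are 0-based internally; world coordinates are RAS mm through
the (diagonal) affine; volumes round-trip losslessly through NIfTI-1.

## Numerical and inferential choices

* **Validity of ratio voxels**: a voxel is valid when T1w > 0 *and*
  sT2 > 0. Requiring only a positive denominator would admit noisy voxels
  with ratios outside (−1, 1); the stricter rule guarantees boundedness.
  Invalid voxels are excluded from medians, never clipped or zeroed.
* **Atlas threshold**: probability ≥ 0.90, inclusive (the printed "90%
  probability threshold" does not state inclusivity; we document ≥).
* **Atlas profile**: each channel is `p = max(0, 1 − q⁴)` in the normalised
  ellipsoidal radius `q` — exactly 1 at the centre, smoothly decaying, zero
  outside the support — and the left channel is the mirror image of the
  right.
* **MCP volume**: the thresholded-mask volume in subject space. Whether a
  deformation Jacobian should modulate atlas-derived volumes is left open
  in the source description; this package measures the thresholded mask and
  says so.
* **ROC direction**: lower score = diseased for both markers (configurable).
  Thresholds sit at midpoints between distinct scores; ties contribute
  half-steps, and the AUC is the tie-corrected Mann–Whitney probability
  (identical to the trapezoid under the empirical curve).
* **Cutoff**: the point closest to the upper-left corner,
  `min sqrt((1 − TPR)² + FPR²)`; ties break toward higher specificity, then
  the lower threshold.
* **AUC inference**: DeLong structural components for the single-AUC
  standard error and the paired two-AUC test; degenerate variance with a
  genuine AUC difference raises an error rather than returning a fake z.
* **Proportion CIs**: Clopper–Pearson exact intervals. The published table
  never names its CI method; Clopper–Pearson reproduces the verified
  (75.0–98.0) interval for 29/32. The printed intervals for several 100%
  cells are *not* Clopper–Pearson at the reconstructable counts; those cells
  are noted, not guessed at, and only point estimates are asserted
  table-wide. Cells with 0/0 denominators are reported as undefined, never
  as 0.
* **Binomial accuracy comparisons**: one-sided lower-tail exact binomial by
  default — consistent with the published p = 0.042 for 32/40 against 0.90,
  which exact enumeration reproduces only one-sided — with the
  minimum-likelihood two-sided variant available.
* **ICC**: two-way random-effects, absolute-agreement, single-measure
  ICC(2,1) by default (the source is silent on the form); two-way mixed
  consistency ICC(3,1) optional. Zero between-subject variance is flagged
  undefined.
* **Grubbs outlier screen**: `G = max|x − mean|/sd` against the t-based
  critical value at `alpha/(2n)`; single-outlier by default with an
  iterative remove-and-retest option.
* **Group comparisons**: ANCOVA of the biomarker on group with age as the
  (single) covariate via a linear model with a common slope; Kruskal–Wallis
  across patient groups with pairwise exact Mann–Whitney post-hocs at the
  Bonferroni-adjusted threshold 0.05/3 = 0.0167; chi-square for sex;
  Spearman (extent score vs ratio) and Pearson (ratio vs volume)
  correlations within MSA-C. Exact Mann–Whitney p-values are unavailable
  under ties, in which case the normal approximation is used (standard
  behaviour of `wilcox.test`).

## Problem sizes

Image-level analyses run on 64³ grids at 2-mm isotropic voxels (the demo
study measures 8–16 phantoms); value-level simulations use the printed group
sizes, with 2000 replicate cohorts for the mean-AUC checks, 10⁴ draws for
the bootstrap and coverage suites, and 10⁵ subjects for rating-error
calibration checks. All sizes were chosen as the smallest that leave the
Monte-Carlo error well under the tolerances being asserted.

## Known limitations

* Mean-squared-difference registration is mono-contrast; mutual-information
  registration and nonlinear template normalisation are out of scope (the
  common-space transform is the identity in the phantom world, with a hook
  for a real warp).
* The rater simulator flips binary signs independently per reviewer;
  correlated reviewer errors (shared difficult cases) are not modelled, so
  simulated ICCs need not match the published ones.
* Gaussian group distributions and Gaussian image noise are idealisations;
  the published patient-level point estimates that depend on unpublished raw
  values (exact AUC CIs, ICC magnitudes, correlation coefficients) are
  structural targets only.
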