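make_const_volume <- function(value, dm = c(12, 12, 12)) {
  volume(array(value, dm), c(2, 2, 2))
}

test_that("scaling factor follows its definition and scale law", {
  ph <- noiseless_phantom()
  gm <- ph$truth_labels == TISSUE_LABELS[["gm"]]
  wm <- ph$truth_labels == TISSUE_LABELS[["wm"]]
  s <- scaling_factor(ph$t1w, ph$t2w, gm, wm)
  expect_equal(s$s, 100 / 110, tolerance = 1e-12)
  expect_equal(s$wm_median_t1w, 150, tolerance = 1e-12)

  # equal medians give s = 1; 200/50 gives 4
  a <- make_const_volume(200); b <- make_const_volume(50)
  m <- array(TRUE, dim(a$values))
  expect_identical(scaling_factor(a, a, m)$s, 1)
  expect_identical(scaling_factor(a, b, m)$s, 4)

  # s(T1w, c*T2w) = s(T1w, T2w) / c
  for (cc in c(0.5, 7)) {
    t2c <- volume(ph$t2w$values * cc, ph$t2w$voxel_size, ph$t2w$affine)
    expect_equal(scaling_factor(ph$t1w, t2c, gm)$s, s$s / cc,
                 tolerance = 1e-12)
  }
  expect_error(scaling_factor(a, b, array(FALSE, dim(a$values))), "empty")
})

test_that("median scaling factor shrugs off corruption of a minority of non-GM voxels", {
  ph <- noiseless_phantom()
  gm <- ph$truth_labels == TISSUE_LABELS[["gm"]]
  s0 <- scaling_factor(ph$t1w, ph$t2w, gm)$s
  t1c <- ph$t1w; t2c <- ph$t2w
  non_gm <- which(!gm)
  set.seed(99)
  bad <- sample(non_gm, floor(0.4 * length(non_gm)))
  t1c$values[bad] <- 1e6
  t2c$values[bad] <- 1e-3
  # also corrupt 40% of GM itself: the median still stands
  gm_idx <- which(gm)
  badgm <- sample(gm_idx, floor(0.4 * length(gm_idx)) %/% 2)
  t1c$values[badgm] <- 1e6
  expect_equal(scaling_factor(t1c, t2c, gm)$s, s0, tolerance = 1e-12)
})

test_that("ratio map obeys its pointwise definition, validity and boundedness", {
  t1 <- make_const_volume(3)
  t2 <- make_const_volume(1)
  rm1 <- ratio_map(t1, t2, 1)
  expect_true(all(rm1$values == 0.5))       # (3-1)/(3+1)
  rm0 <- ratio_map(t1, volume(t1$values, t1$voxel_size, t1$affine), 1)
  expect_true(all(rm0$values == 0))         # T1w = sT2

  ph <- default_noisy_phantom()
  s <- 0.909
  rm_ <- ratio_map(ph$t1w, ph$t2w, s)
  expect_true(all(abs(rm_$values[rm_$valid]) < 1))
  expect_true(all(is.na(rm_$values[!rm_$valid])))
  expect_gt(sum(!rm_$valid), 0)             # noisy background goes invalid
  expect_error(ratio_map(t1, make_const_volume(1, c(8, 8, 8)), 1),
               "same grid")
})

test_that("the standardized ratio map is invariant to independent global rescaling", {
  ph <- default_noisy_phantom()
  mask <- ph$truth_labels > 0L
  gm <- ph$truth_labels == TISSUE_LABELS[["gm"]]
  s1 <- scaling_factor(ph$t1w, ph$t2w, gm)
  r1 <- ratio_map(ph$t1w, ph$t2w, s1)
  for (ab in list(c(2.5, 1), c(1, 0.3), c(5.5, 0.07))) {
    t1s <- volume(ph$t1w$values * ab[1], ph$t1w$voxel_size, ph$t1w$affine)
    t2s <- volume(ph$t2w$values * ab[2], ph$t2w$voxel_size, ph$t2w$affine)
    s2 <- scaling_factor(t1s, t2s, gm)
    r2 <- ratio_map(t1s, t2s, s2)
    expect_identical(r1$valid, r2$valid)
    expect_lt(max(abs(r1$values[r1$valid] - r2$values[r2$valid])), 1e-10)
  }
})

test_that("smoothing preserves constants, is identity at fwhm 0, and has the closed-form impulse response", {
  dm <- c(21, 21, 21)
  const <- ratio_map(make_const_volume(3, dm), make_const_volume(1, dm), 1)
  sm <- smooth_ratio_map(const, 8)
  expect_lt(max(abs(sm$values - 0.5)), 1e-9)
  expect_identical(smooth_ratio_map(const, 0), const)

  # unit impulse on an otherwise-zero but fully valid map
  imp <- const
  imp$values[] <- 0
  imp$values[11, 11, 11] <- 1
  smi <- smooth_ratio_map(imp, 8)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2      # voxel units at 2 mm
  # 3-sigma kernel truncation renormalises by ~0.3% per axis
  expect_equal(smi$values[11, 11, 11], (2 * pi * sigma^2)^(-3 / 2),
               tolerance = 1e-3)
})

test_that("MCP value is the mean of two brute-force ROI medians", {
  ph <- default_noisy_phantom()
  pp <- preprocess_subject(ph, mode = "oracle")
  s <- scaling_factor(pp$t1w, pp$t2w, pp$labels == 2L)
  sm <- smooth_ratio_map(ratio_map(pp$t1w, pp$t2w, s), 8)
  mv <- mcp_value(sm, ph$atlas, threshold = 0.90)
  lmed <- median_bruteforce(sm$values,
                            atlas_mask(ph$atlas, "left") & sm$valid)
  rmed <- median_bruteforce(sm$values,
                            atlas_mask(ph$atlas, "right") & sm$valid)
  expect_identical(mv$left_median, lmed)
  expect_identical(mv$right_median, rmed)
  expect_identical(mv$mcp_value, (lmed + rmed) / 2)

  const <- ratio_map(make_const_volume(3, dim(ph$t1w$values)),
                     make_const_volume(1, dim(ph$t1w$values)), 1)
  const$affine <- ph$t1w$affine
  expect_identical(mcp_value(const, ph$atlas)$mcp_value, 0.5)
  expect_error(mcp_value(sm, ph$atlas, threshold = 1.1), "empty")
})

test_that("volume measurement is exact arithmetic over brute-force counts", {
  ph <- noiseless_phantom()
  brain <- ph$truth_labels > 0L
  vol <- mcp_volume(ph$atlas, brain, c(2, 2, 2))
  nl <- sum(ph$atlas$left >= 0.9); nr <- sum(ph$atlas$right >= 0.9)
  expect_identical(vol$left_mm3, nl * 8)
  expect_identical(vol$right_mm3, nr * 8)
  expect_identical(vol$mcp_volume_mm3, (nl + nr) / 2 * 8)
  expect_identical(vol$icv_mm3, sum(brain) * 8)
  expect_equal(vol$mcp_volume_norm,
               (nl + nr) / 2 * 8 / (sum(brain) * 8) * 1e3,
               tolerance = 1e-12)

  # 100 voxels of 1 mm^3 per side over a 10^6 mm^3 ICV gives 0.1
  at <- ph$atlas
  at$left[] <- 0; at$right[] <- 0
  at$left[1:100] <- 1; at$right[1:100] <- 1
  fake_brain <- array(TRUE, c(100, 100, 100))
  at2 <- list(left = array(0, c(100, 100, 100)),
              right = array(0, c(100, 100, 100)))
  at2$left[1:100] <- 1; at2$right[1:100] <- 1
  class(at2) <- "prob_atlas"
  v <- mcp_volume(at2, fake_brain, c(1, 1, 1))
  expect_identical(v$mcp_volume_norm, 0.1)
})

test_that("end-to-end MCP value is invariant to independent global input rescaling", {
  ph <- default_noisy_phantom()
  base <- measure_subject(ph, mode = "oracle")$mcp_value
  ph2 <- ph
  ph2$t1w <- volume(ph$t1w$values * 3.1, ph$t1w$voxel_size, ph$t1w$affine)
  ph2$t2w <- volume(ph$t2w$values * 0.41, ph$t2w$voxel_size, ph$t2w$affine)
  rescaled <- measure_subject(ph2, mode = "oracle")$mcp_value
  expect_equal(rescaled, base, tolerance = 1e-9)
})
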