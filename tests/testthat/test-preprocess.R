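test_that("bias estimation returns a unit field for bias-free input and is idempotent", {
  ph <- noiseless_phantom()
  brain <- ph$truth_labels > 0L
  # piecewise-constant anatomy, no bias: with tissue intercepts the
  # polynomial component is exactly zero
  f <- estimate_bias_field(ph$t1w, brain, labels = ph$truth_labels)
  expect_lt(max(abs(f$values[brain] - 1)), 1e-6)

  # constant image, no labels needed
  cv <- volume(array(7, c(16, 16, 16)), c(2, 2, 2))
  m <- array(TRUE, c(16, 16, 16))
  fc <- estimate_bias_field(cv, m)
  expect_lt(max(abs(fc$values - 1)), 1e-6)

  expect_error(estimate_bias_field(cv, array(FALSE, c(16, 16, 16))), "empty")
  neg <- volume(array(-1, c(8, 8, 8)), c(1, 1, 1))
  expect_error(estimate_bias_field(neg, array(TRUE, c(8, 8, 8))),
               "positive")
})

test_that("a known smooth multiplicative field is recovered (r > 0.99) and corrected", {
  ph <- cached_phantom("biased_clean",
                       phantom_spec(noise_sigma = 0, bias_amplitude = 0.3,
                                    seed = 19))
  brain <- ph$truth_labels > 0L
  f <- estimate_bias_field(ph$t1w, brain, labels = ph$truth_labels)
  expect_gt(cor(f$values[brain], ph$truth_bias_field$values[brain]), 0.99)

  corrected <- correct_bias(ph$t1w, f, brain)
  # in-mask mean preserved by the mean-restoring rescale
  expect_equal(mean(corrected$values[brain]), mean(ph$t1w$values[brain]),
               tolerance = 1e-6)
  # re-estimation on the corrected image gives a near-unit field
  f2 <- estimate_bias_field(corrected, brain, labels = ph$truth_labels)
  expect_lt(max(abs(f2$values[brain] - 1)), 0.02)
  # within-tissue coefficient of variation strictly drops
  wm <- ph$truth_labels == TISSUE_LABELS[["wm"]]
  cv_before <- sd(ph$t1w$values[wm]) / mean(ph$t1w$values[wm])
  cv_after <- sd(corrected$values[wm]) / mean(corrected$values[wm])
  expect_lt(cv_after, cv_before)
})

test_that("correct_bias with a unit field is the identity", {
  ph <- noiseless_phantom()
  one <- volume(array(1, dim(ph$t1w$values)), ph$t1w$voxel_size,
                ph$t1w$affine)
  out <- correct_bias(ph$t1w, one)
  expect_equal(out$values, ph$t1w$values, tolerance = 1e-12)
})

test_that("brain mask hits Dice >= 0.99 noiseless and > 0.95 at default noise", {
  clean <- noiseless_phantom()
  truth <- clean$truth_labels > 0L
  expect_gte(dice(brain_mask(clean$t1w), truth), 0.99)
  noisy <- default_noisy_phantom()
  expect_gt(dice(brain_mask(noisy$t1w), noisy$truth_labels > 0L), 0.95)
  zero <- volume(array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_error(brain_mask(zero), "all-zero")
})

test_that("segmentation is exact on the noiseless phantom and ordered by intensity", {
  ph <- noiseless_phantom()
  truth <- ph$truth_labels
  labels <- segment_tissues(ph$t1w, truth > 0L)
  expect_identical(labels, truth)
  means <- vapply(1:3, function(l) mean(ph$t1w$values[labels == l]), 0)
  expect_true(all(diff(means) > 0))
})

test_that("low-noise segmentation keeps GM Dice > 0.9 and is rescale-invariant", {
  ph <- cached_phantom("lownoise",
                       phantom_spec(noise_sigma = 3, bias_amplitude = 0,
                                    mcp_target_ratio = 0.07, seed = 31))
  mask <- ph$truth_labels > 0L
  labels <- segment_tissues(ph$t1w, mask)
  gm_truth <- ph$truth_labels == TISSUE_LABELS[["gm"]]
  expect_gt(dice(labels == TISSUE_LABELS[["gm"]], gm_truth), 0.9)
  # global positive rescaling leaves the labels unchanged
  scaled <- volume(ph$t1w$values * 3.7, ph$t1w$voxel_size, ph$t1w$affine)
  expect_identical(segment_tissues(scaled, mask), labels)
  tiny <- volume(array(rep(c(1, 1), 4), c(2, 2, 2)), c(1, 1, 1))
  expect_error(segment_tissues(tiny, array(TRUE, c(2, 2, 2))),
               "distinct intensities")
})

test_that("identity-mode registration returns the exact identity transform", {
  ph <- noiseless_phantom()
  reg <- register_rigid(ph$t2w, ph$t1w, mode = "identity")
  expect_identical(reg$transform$rotation_deg, c(0, 0, 0))
  expect_identical(reg$transform$translation_mm, c(0, 0, 0))
  expect_equal(reg$volume$values, ph$t2w$values, tolerance = 1e-12)
})

test_that("optimization recovers identity for identical volumes and a known offset", {
  ph0 <- cached_phantom("reg_ref",
                        phantom_spec(noise_sigma = 0, bias_amplitude = 0,
                                     seed = 9))
  reg0 <- register_rigid(ph0$t2w, ph0$t2w, mode = "optimize",
                         subsample = 4L)
  expect_lt(max(abs(c(reg0$transform$rotation_deg,
                      reg0$transform$translation_mm))), 1e-3)

  tf <- rigid_transform(c(0, 0, 5), c(3, 0, 0))
  ph <- make_phantom(phantom_spec(noise_sigma = 1, bias_amplitude = 0,
                                  rigid_offset = tf, seed = 9))
  reg <- register_rigid(ph$t2w, ph0$t2w, mode = "optimize", subsample = 3L)
  inv <- invert_rigid(tf)
  expect_lt(max(abs(reg$transform$rotation_deg - inv$rotation_deg)), 0.5)
  # within half a voxel (1 mm at the default 2 mm grid)
  expect_lt(max(abs(reg$transform$translation_mm - inv$translation_mm)), 1)
})

test_that("rigid transforms compose, invert and round-trip through text records", {
  a <- rigid_transform(c(3, -2, 5), c(1, -4, 2))
  b <- rigid_transform(c(-1, 4, -2), c(0.5, 2, -3))
  ab <- compose_rigid(a, b)
  expect_equal(rigid_matrix(ab), rigid_matrix(a) %*% rigid_matrix(b),
               tolerance = 1e-12)
  ia <- invert_rigid(a)
  expect_equal(rigid_matrix(compose_rigid(a, ia)), diag(4),
               tolerance = 1e-12)
  f <- tempfile()
  write_rigid(a, f)
  back <- read_rigid(f)
  expect_equal(back$rotation_deg, a$rotation_deg, tolerance = 1e-12)
  expect_equal(back$translation_mm, a$translation_mm, tolerance = 1e-12)
})
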