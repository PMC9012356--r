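test_that("AUC equals the tie-corrected pairwise probability, the trapezoid, and pROC", {
  # worked toy: diseased {0.05, 0.10}, non-diseased {0.10, 0.20}, lower = diseased
  sc <- c(0.05, 0.10, 0.10, 0.20)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_auc(sc, lab, "lower")
  expect_equal(r$auc, 0.875, tolerance = 1e-12)       # (3 + 0.5)/4

  # perfectly separated groups
  rp <- roc_auc(c(1, 2, 3, 10, 11), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                "lower")
  expect_identical(rp$auc, 1)

  set.seed(202)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    sc <- round(c(rnorm(n1, 0), rnorm(n0, 1)), 1)   # rounding makes ties
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_auc(sc, lab, "lower")
    expect_equal(r$auc, auc_pairwise(sc, lab), tolerance = 1e-12)
    # trapezoid over the empirical curve
    trap <- sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-length(r$tpr)]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # direction flip complements the AUC
    expect_equal(roc_auc(sc, lab, "higher")$auc, 1 - r$auc,
                 tolerance = 1e-12)
    # curve endpoints and monotonicity
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }

  # independent implementation: pROC
  set.seed(7)
  sc <- rnorm(60); lab <- rep(c(TRUE, FALSE), 30)
  r <- roc_auc(sc, lab, "lower")
  pr <- pROC::roc(lab, sc, direction = ">", levels = c(FALSE, TRUE),
                  quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_error(roc_auc(sc, rep(TRUE, 60)), "both classes")
})

test_that("DeLong variance matches a direct hand computation and pROC's test", {
  # frozen 5-subject toy: scores .1...5, diseased at positions 1,2,5
  sc <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  lab <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  r <- roc_auc(sc, lab, "higher")
  expect_equal(r$auc, 1 / 3, tolerance = 1e-12)
  expect_equal(r$auc_se^2, 0.1111111111, tolerance = 1e-9)

  # identical markers: z = 0, p = 1
  d0 <- delong_test(sc, sc, lab, "higher")
  expect_identical(c(d0$z, d0$p), c(0, 1))

  set.seed(31)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  lab <- rep(c(TRUE, FALSE), 25)
  d <- delong_test(a, b, lab, "higher")
  pr <- pROC::roc.test(
    pROC::roc(lab, a, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE),
    pROC::roc(lab, b, direction = "<", levels = c(FALSE, TRUE), quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d$p, pr$p.value, tolerance = 1e-9)
  expect_equal(abs(d$z), abs(as.numeric(pr$statistic)), tolerance = 1e-9)
})

test_that("DeLong variance sits within 15% of a 10^4 stratified bootstrap", {
  set.seed(50)
  n <- 50
  sc <- c(rnorm(25, 0, 1), rnorm(25, 1, 1))
  lab <- rep(c(TRUE, FALSE), c(25, 25))
  r <- roc_auc(sc, lab, "higher")
  pos <- sc[lab]; neg <- sc[!lab]
  B <- 1e4
  boot <- vapply(seq_len(B), function(i) {
    x <- c(sample(pos, 25, TRUE), sample(neg, 25, TRUE))
    rk <- rank(x)
    (sum(rk[1:25]) - 25 * 26 / 2) / (25 * 25)
  }, 0)
  expect_lt(abs(var(boot) - r$auc_se^2) / var(boot), 0.15)
})

test_that("the closest-to-corner cutoff matches exhaustive search and is transform-invariant", {
  set.seed(77)
  for (i in 1:25) {
    sc <- round(c(rnorm(12, 0), rnorm(9, 1.2)), 1)
    lab <- rep(c(TRUE, FALSE), c(12, 9))
    r <- roc_auc(sc, lab, "lower")
    cut <- optimal_cutoff(r)
    d <- sqrt((1 - r$tpr)^2 + r$fpr^2)
    expect_equal(cut$distance, min(d), tolerance = 1e-12)
    # brute force over every curve point with the documented tie-break
    best <- which(abs(d - min(d)) < 1e-12)
    best <- best[r$fpr[best] == min(r$fpr[best])]
    expect_true(cut$fpr == min(r$fpr[best]))

    # strictly monotone transform of scores preserves the operating point
    r2 <- roc_auc(exp(sc), lab, "lower")
    cut2 <- optimal_cutoff(r2)
    expect_equal(c(cut2$tpr, cut2$fpr), c(cut$tpr, cut$fpr),
                 tolerance = 1e-12)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
    expect_equal(r2$auc_se, r$auc_se, tolerance = 1e-12)
  }
  # perfect separation reaches the corner
  rp <- roc_auc(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE), "lower")
  cp <- optimal_cutoff(rp)
  expect_identical(c(cp$tpr, cp$fpr), c(1, 0))
})

test_that("Clopper-Pearson agrees with the tail-sum bisection oracle and covers", {
  expect_identical(clopper_pearson(0, 10)[1], 0)
  expect_identical(clopper_pearson(10, 10)[2], 1)
  set.seed(12)
  for (i in 1:40) {
    n <- sample(1:50, 1); x <- sample(0:n, 1)
    expect_equal(clopper_pearson(x, n), cp_bisect(x, n), tolerance = 1e-6)
  }
  # closed-form lower bound at x = n: (alpha/2)^(1/n)
  expect_equal(clopper_pearson(20, 20)[1], (0.025)^(1 / 20),
               tolerance = 1e-10)
  expect_error(clopper_pearson(5, 4), "0 <= x <= n")

  # empirical coverage at n = 32, p = 0.9 over 10^4 draws
  set.seed(88)
  xs <- rbinom(1e4, 32, 0.9)
  bounds <- vapply(0:32, function(x) clopper_pearson(x, 32), c(0, 0))
  covered <- bounds[1, xs + 1] <= 0.9 & bounds[2, xs + 1] >= 0.9
  expect_gte(mean(covered), 0.95)
})

test_that("confusion metrics reproduce hand fractions and flag empty denominators", {
  cm <- confusion_metrics(29, 3, 2, 6)
  expect_equal(cm$value, c(29 / 32, 6 / 8, 29 / 31, 6 / 9, 35 / 40) * 100,
               tolerance = 1e-12)
  expect_true(all(cm$value >= cm$lo & cm$value <= cm$hi))

  perfect <- confusion_metrics(15, 0, 0, 5)
  expect_true(all(perfect$value == 100))
  expect_equal(perfect$lo[perfect$metric == "sensitivity"],
               (0.025)^(1 / 15) * 100, tolerance = 1e-9)

  undef <- confusion_metrics(0, 8, 0, 16)
  expect_true(is.na(undef$value[undef$metric == "ppv"]))
  expect_false(is.na(undef$value[undef$metric == "accuracy"]))
  expect_error(confusion_metrics(-1, 0, 0, 1), "nonnegative")
})

test_that("binomial accuracy test matches direct tail summation and sidedness ordering", {
  p_direct <- sum(dbinom(0:32, 40, 0.9))
  expect_equal(binomial_accuracy_test(32, 40, 0.9), p_direct,
               tolerance = 1e-12)
  expect_identical(binomial_accuracy_test(40, 40, 0.9), 1)
  for (x in c(28, 32, 36)) {
    expect_gte(binomial_accuracy_test(x, 40, 0.9, "two.sided"),
               binomial_accuracy_test(x, 40, 0.9, "less") - 1e-12)
  }
})

test_that("ICC matches the frozen ANOVA oracle, is rater-permutation invariant, 1 for identical raters", {
  m <- matrix(c(9, 2, 5, 8, 6, 1, 3, 2, 8, 4, 6, 7), nrow = 4)
  r <- icc(m, "agreement")
  expect_equal(r$icc, 0.5063291139, tolerance = 1e-9)
  expect_equal(icc(m, "consistency")$icc, 0.7582938389, tolerance = 1e-9)
  expect_equal(icc(m[, c(3, 1, 2)], "agreement")$icc, r$icc,
               tolerance = 1e-12)

  same <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc(same, "agreement")$icc, 1, tolerance = 1e-12)
  expect_error(icc(matrix(1, 1, 3)), ">= 2 subjects")
  expect_error(icc(matrix(3, 4, 3)), "zero variance")
})

test_that("Grubbs matches the closed-form critical values and flags gross outliers", {
  r3 <- grubbs(c(1, 2, 3))
  expect_equal(r3$g, 1, tolerance = 1e-12)
  expect_equal(r3$critical, 1.1543, tolerance = 1e-4)   # published n = 3 value
  expect_true(is.na(r3$flagged))

  r10 <- grubbs(rnorm(10))
  expect_equal(r10$critical, 2.290, tolerance = 1e-3)   # published n = 10 value

  for (n in 3:30) {
    x <- seq_len(n)
    t2 <- qt(1 - 0.05 / (2 * n), n - 2)^2
    crit <- (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
    expect_equal(grubbs(x)$critical, crit, tolerance = 1e-12)
  }

  r <- grubbs(c(1, 2, 3, 50))
  expect_identical(r$flagged, 4L)
  ri <- grubbs(c(1, 2, 3, 2, 1, 2, 3, 50, 30), iterative = TRUE)
  expect_true(8L %in% ri$all_flagged)
  expect_error(grubbs(c(1, 2)), "n >= 3")
  expect_error(grubbs(c(2, 2, 2)), "constant")
})

test_that("simulated group moments reproduce the published AUC ordering", {
  gm <- group_moments()
  mauc <- function(i, j, col_m, col_s, reps = 400, seed = 1) {
    simulate_mean_auc(gm$n[i], gm[[col_m]][i], gm[[col_s]][i],
                      gm$n[j], gm[[col_m]][j], gm[[col_s]][j],
                      reps = reps, seed = seed)$mean_auc
  }
  # ratio: MSA vs Control > MSA vs SCA6 > MSA vs SCA3
  a_ctrl <- mauc(1, 4, "ratio_mean", "ratio_sd")
  a_sca6 <- mauc(1, 3, "ratio_mean", "ratio_sd")
  a_sca3 <- mauc(1, 2, "ratio_mean", "ratio_sd")
  expect_gt(a_ctrl, a_sca6)
  expect_gt(a_sca6, a_sca3)
  # volume: MSA vs SCA3 is the weakest of the volume comparisons
  v_sca3 <- mauc(1, 2, "vol_mean", "vol_sd")
  v_sca6 <- mauc(1, 3, "vol_mean", "vol_sd")
  v_ctrl <- mauc(1, 4, "vol_mean", "vol_sd")
  expect_lt(v_sca3, min(v_sca6, v_ctrl))
})
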