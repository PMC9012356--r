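#!/usr/bin/env Rscript
# Step 4 — visual-rating reconstruction and inter-reviewer agreement.
#
# Reproduces every defined cell of the published reviewer-performance table
# from counts implied by the group sizes, compares reviewer accuracies with
# the quantitative marker via exact binomial tests, and estimates ICC(2,1)
# on simulated reviewer ratings.

suppressPackageStartupMessages(library(mcpratio))

dir.create("results", showWarnings = FALSE)

rep2 <- reproduce_table2()
write.csv(rep2, "results/table2_reproduction.csv", row.names = FALSE)
message(sprintf(
  "Reviewer-table reproduction: %d/%d rows match to one decimal (%d undefined 0/0 cells skipped)",
  sum(rep2$match), nrow(rep2), sum(is.na(rep2$ppv) | is.na(rep2$npv))))

t3 <- compare_accuracies_table3()
write.csv(t3, "results/accuracy_binomial_tests.csv", row.names = FALSE)
message("\nBinomial tests of reviewer accuracy vs the ratio marker (one-sided):")
print(t3[t3$sign == "mcp_hyper", ], digits = 3, row.names = FALSE)

# simulated three-reviewer ratings for an MSA-C vs SCA3 cohort
truth <- list(mcp_hyper = rep(c(TRUE, FALSE), c(32, 8)),
              hcb_grade = c(sample(rep(c(1L, 2L), c(13, 19))),
                            rep(c(0L, 1L), c(6, 2))))
set.seed(40)
model <- rater_model(sensitivity = c(0.906, 0.969, 0.844),
                     specificity = c(0.750, 0.125, 0.875),
                     ordinal_noise = 0.15)
ratings <- simulate_ratings(truth, model, seed = 41)
write.csv(ratings, "results/simulated_ratings.csv", row.names = FALSE)

icc_bin <- icc(as.matrix(ratings[grep("mcp_hyper", names(ratings))]))
icc_ord <- icc(as.matrix(ratings[grep("hcb_grade", names(ratings))]))
message(sprintf(
  "\nICC(2,1) on simulated ratings: MCP hyperintensity %.3f, HCB grade %.3f",
  icc_bin$icc, icc_ord$icc))
message("(published values on real readings: 0.762 and 0.729)")
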