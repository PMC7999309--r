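#!/usr/bin/env Rscript
# Step 2 — two-step abundance normalization.
#
# Step 1 equalizes per-protein means (dividing by mean_i / median of the
# protein means); step 2 equalizes per-sample medians (dividing by
# median_j / overall median), removing run-to-run intensity drift while
# leaving the missingness pattern untouched.

library(cytopi)

raw <- read_abundance("results/simulated/abundance.tsv")
norm <- normalize_two_step(raw)

dir.create("results/normalized", showWarnings = FALSE, recursive = TRUE)
write_abundance(norm$abundance, "results/normalized/abundance.tsv")
write_normalization_factors(norm$factors,
                            "results/normalized/factors_protein.tsv",
                            "results/normalized/factors_sample.tsv")

step1 <- step1_protein_scaling(raw)
means <- rowMeans(step1$abundance, na.rm = TRUE)
meds <- apply(norm$abundance, 2, median, na.rm = TRUE)
cat("sample scaling factors span",
    sprintf("%.3f-%.3f", min(norm$factors$sample_factor),
            max(norm$factors$sample_factor)), "\n")
cat("max relative deviation of protein means after step 1:",
    format(max(abs(means / step1$factors$grand_median_of_protein_means - 1)),
           digits = 3), "\n")
cat("max relative deviation of sample medians after step 2:",
    format(max(abs(meds / meds[1] - 1)), digits = 3), "\n")
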