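#!/usr/bin/env Rscript
# Step 3 -- ERP peak comparisons.
#
# Reads the per-animal peak table produced by step 2 and reports the
# Mann-Whitney comparisons with Holm-Sidak adjustment, plus group bar values
# (mean +/- SD) for P1/N1/P2 per region. Expected pattern on the default
# cohort: |N1| elevated in knockouts under both treatments; no P1/P2 effects;
# no treatment effect on any peak.

suppressPackageStartupMessages(library(gapassr))

erp <- utils::read.csv("results/run_p30/cohort_erp.csv")
tests <- utils::read.csv("results/run_p30/erp_tests.csv")

summ <- do.call(rbind, lapply(split(erp, list(erp$region, erp$genotype,
                                              erp$treatment)), function(s) {
  data.frame(region = s$region[1], genotype = s$genotype[1],
             treatment = s$treatment[1], n = nrow(s),
             N1_mean = mean(s$N1_uV), N1_sd = sd(s$N1_uV),
             P1_mean = mean(s$P1_uV), P2_mean = mean(s$P2_uV))
}))
utils::write.csv(summ, "results/run_p30/erp_group_summary.csv",
                 row.names = FALSE)

cat("significant ERP comparisons after Holm-Sidak (p_adj < 0.05):\n")
sig <- tests[tests$p_adj < 0.05, c("region", "measure", "comparison", "p_adj")]
print(sig, row.names = FALSE)
cat("\nall N1 rows:\n")
print(tests[tests$measure == "N1",
            c("region", "comparison", "mean_1", "mean_2", "U", "p_adj")],
      row.names = FALSE)
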