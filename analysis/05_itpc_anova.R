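#!/usr/bin/env Rscript
# Step 5 -- Gap-ASSR ITPC group analysis.
#
# Reads the per-animal mean 40 Hz ITPC table from step 2, re-runs the mixed
# repeated-measures ANOVA (genotype x treatment between, gap width within,
# Greenhouse-Geisser corrected) per region, reports the Sidak post hoc
# treatment contrasts, and draws ITPC-vs-gap-width profiles with SD error
# bars. Expected pattern on the default P30 cohort: a treatment main effect
# (NLX101 raises ITPC) in both regions, and ITPC increasing with gap width.

suppressPackageStartupMessages(library(gapassr))

itpc <- utils::read.csv("results/run_p30/cohort_itpc.csv")
for (ch in c("AC", "FC")) {
  sub <- itpc[itpc$region == ch, ]
  an <- rm_anova(sub, between = c("genotype", "treatment"),
                 within = "gap_width_ms", dv = "mean_itpc")
  cat(sprintf("\n== %s (Greenhouse-Geisser epsilon %.3f) ==\n", ch,
              attr(an, "gg_epsilon")))
  print(an[, c("effect", "F", "df", "df_err", "p", "gg_p", "p_use")],
        row.names = FALSE)
  ph <- sidak_posthoc(sub, factor = "treatment", by = "genotype",
                      dv = "mean_itpc")
  print(ph[, c("stratum", "level_1", "level_2", "mean_1", "mean_2",
               "p_sidak")], row.names = FALSE)

  png(sprintf("results/run_p30/figures/itpc_%s.png", ch), 700, 500)
  grp <- interaction(sub$genotype, sub$treatment)
  cols <- c("grey30", "grey60", "red3", "salmon")
  plot(NULL, xlim = c(3, 9), ylim = c(0, 1), xlab = "gap width (ms)",
       ylab = "mean 40 Hz ITPC", main = sprintf("gap-ASSR ITPC (%s)", ch))
  for (i in seq_along(levels(grp))) {
    g <- levels(grp)[i]
    s <- sub[grp == g, ]
    m <- tapply(s$mean_itpc, s$gap_width_ms, mean)
    sdv <- tapply(s$mean_itpc, s$gap_width_ms, sd)
    w <- as.numeric(names(m))
    lines(w, m, col = cols[i], lwd = 2)
    arrows(w, m - sdv, w, m + sdv, angle = 90, code = 3, length = 0.03,
           col = cols[i])
  }
  legend("bottomright", levels(grp), col = cols, lwd = 2, bty = "n")
  dev.off()
}
cat("\nfigures under results/run_p30/figures/\n")
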