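#!/usr/bin/env Rscript
# Step 4 -- STP group difference maps.
#
# Reads the cluster-test table from step 2 and renders group-mean STP maps
# and difference heatmaps for the four comparisons. Expected pattern on the
# default P30 cohort: a significant gamma-band (30-100 Hz) cluster for
# KO-saline vs WT-saline and for KO-NLX101 vs KO-saline in both regions, and
# no significant cluster for WT-NLX101 vs WT-saline or KO-NLX101 vs
# WT-saline (the treatment "rescue").

suppressPackageStartupMessages(library(gapassr))

clusters_path <- "results/run_p30/stp_clusters.csv"
if (file.exists(clusters_path)) {
  cl <- utils::read.csv(clusters_path)
  cat("significant STP clusters:\n")
  print(cl[cl$significant == "TRUE" | cl$significant == TRUE,
           c("comparison", "region", "sign", "area", "f_min_hz", "f_max_hz",
             "null_percentile")], row.names = FALSE)
} else {
  cat("no clusters at all were formed (no supra-threshold points)\n")
}

dir.create("results/run_p30/figures", showWarnings = FALSE, recursive = TRUE)
maps_dir <- "results/run_p30/stp_maps"
pairs <- list(KOsal_vs_WTsal = c("KO.saline", "WT.saline"),
              KOnlx_vs_WTsal = c("KO.NLX101", "WT.saline"))
for (ch in c("AC", "FC")) {
  for (nm in names(pairs)) {
    f1 <- file.path(maps_dir, sprintf("mean_%s_%s.csv", ch, pairs[[nm]][1]))
    f2 <- file.path(maps_dir, sprintf("mean_%s_%s.csv", ch, pairs[[nm]][2]))
    if (!file.exists(f1) || !file.exists(f2)) next
    d <- as.matrix(utils::read.csv(f1)) - as.matrix(utils::read.csv(f2))
    png(file.path("results/run_p30/figures",
                  sprintf("stp_diff_%s_%s.png", nm, ch)), 700, 500)
    image(seq(-0.25, 0.5, length.out = ncol(d)), 5:100, t(d),
          col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
          xlab = "time (s)", ylab = "frequency (Hz)",
          main = sprintf("STP difference %s (%s)", nm, ch))
    abline(v = 0, lty = 2)
    dev.off()
  }
}
cat("difference heatmaps under results/run_p30/figures/\n")
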