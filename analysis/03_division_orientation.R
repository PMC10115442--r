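#!/usr/bin/env Rscript
# Division-orientation analysis of the simulated +1 hr angles: bin
# proportions per genotype, cumulative frequency distributions, and
# Kolmogorov-Smirnov comparisons of each knockout against WT.

suppressPackageStartupMessages(library(epiorient))
dir.create("results/orientation", recursive = TRUE, showWarnings = FALSE)

angles <- read_angle_table("results/data/division_angles.csv")

message("-- orientation-bin proportions (+1 hr) --")
t60 <- data.frame(genotype = angles$genotype, angle = angles$angle_t60)
props <- bin_proportions(t60)
utils::write.csv(props, "results/orientation/bin_proportions.csv",
                 row.names = FALSE)
for (g in unique(props$group)) {
  p <- props[props$group == g, ]
  message(sprintf("   %-8s planar %.2f  oblique %.2f  perpendicular %.2f",
                  g, p$fraction[p$bin == "planar"],
                  p$fraction[p$bin == "oblique"],
                  p$fraction[p$bin == "perpendicular"]))
}

message("-- cumulative frequency distributions --")
for (g in unique(angles$genotype)) {
  e <- angle_ecdf(angles$angle_t60[angles$genotype == g])
  utils::write.csv(e, sprintf("results/orientation/ecdf_%s.csv", g),
                   row.names = FALSE)
}

message("-- KS comparisons against WT (+1 hr angles) --")
wt <- angles$angle_t60[angles$genotype == "WT"]
ks_rows <- lapply(setdiff(unique(angles$genotype), "WT"), function(g) {
  r <- ks_two_sample(wt, angles$angle_t60[angles$genotype == g])
  message(sprintf("   WT vs %-8s D = %.3f, p = %.3g", g, r$D, r$p))
  data.frame(comparison = paste0("WT_vs_", g), D = r$D, p = r$p)
})
utils::write.csv(do.call(rbind, ks_rows), "results/orientation/ks_tests.csv",
                 row.names = FALSE)
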