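#!/usr/bin/env Rscript
# Telophase-correction analysis: classify every anaphase-onset/+1 hr
# trajectory, build the genotype x correction-direction table for obliques
# (cells that remain oblique are excluded and reported), and test each
# knockout against WT with Fisher's exact test.

suppressPackageStartupMessages(library(epiorient))
dir.create("results/correction", recursive = TRUE, showWarnings = FALSE)

angles <- read_angle_table("results/data/division_angles.csv")

traj <- classify_trajectory(angles$angle_t0, angles$angle_t60)
traj$genotype <- angles$genotype
traj$cell_id <- angles$cell_id
utils::write.csv(traj, "results/correction/trajectories.csv",
                 row.names = FALSE)

ct <- correction_table(angles)
utils::write.csv(as.data.frame(ct$counts),
                 "results/correction/correction_counts.csv")
message("-- oblique correction by genotype --")
for (g in rownames(ct$counts)) {
  tot <- sum(ct$counts[g, ])
  message(sprintf(
    "   %-8s %2d/%2d corrected to perpendicular (%.0f%%), %d remained oblique",
    g, ct$counts[g, "corrected_to_perpendicular"], tot,
    100 * ct$counts[g, "corrected_to_perpendicular"] / tot,
    ct$remained_oblique[[g]]))
}

message("-- Fisher exact tests vs WT --")
rows <- lapply(setdiff(rownames(ct$counts), "WT"), function(g) {
  r <- fisher_exact_2x2(ct$counts[c("WT", g), ])
  message(sprintf("   WT vs %-8s p = %.4g (OR %.2f)", g, r$p, r$odds_ratio))
  data.frame(comparison = paste0("WT_vs_", g), p = r$p,
             odds_ratio = r$odds_ratio)
})
utils::write.csv(do.call(rbind, rows), "results/correction/fisher_tests.csv",
                 row.names = FALSE)
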