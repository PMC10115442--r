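#!/usr/bin/env Rscript
# Clone-fate analysis: classify every lineage-tracing clone (SCD / ACD /
# delamination, with exclusions), compute fate proportions per genotype,
# compare genotypes by chi-square, and measure spinous thickness from the
# simulated K10 channel.

suppressPackageStartupMessages(library(epiorient))
dir.create("results/fate", recursive = TRUE, showWarnings = FALSE)

clones <- read_clone_table("results/data/clones.csv")
cls <- classify_clone(clones$n_basal, clones$n_suprabasal,
                      clones$first_spinous)
clones$fate_class <- cls$fate_class
utils::write.csv(clones, "results/fate/classified_clones.csv",
                 row.names = FALSE)

fp <- fate_proportions(clones)
utils::write.csv(fp, "results/fate/fate_proportions.csv", row.names = FALSE)
message("-- fate proportions --")
for (i in seq_len(nrow(fp))) {
  message(sprintf(
    "   %-8s SCD:ACD among divisions %.2f:%.2f; delamination among differentiative %.2f",
    fp$genotype[i], fp$scd_frac_div[i], fp$acd_frac_div[i],
    fp$delam_frac_diff[i]))
}

message("-- chi-square comparisons vs WT --")
count_mat <- as.matrix(fp[, c("n_scd", "n_acd", "n_delam")])
rownames(count_mat) <- fp$genotype
rows <- lapply(setdiff(fp$genotype, "WT"), function(g) {
  # SCD vs ACD among division clones
  r_div <- chi_square_test(count_mat[c("WT", g), c("n_scd", "n_acd")])
  # ACD vs delamination among differentiative clones
  r_dif <- chi_square_test(count_mat[c("WT", g), c("n_acd", "n_delam")])
  message(sprintf("   WT vs %-8s SCD/ACD p = %.3g; ACD/delam p = %.3g",
                  g, r_div$p, r_dif$p))
  data.frame(comparison = paste0("WT_vs_", g),
             p_scd_vs_acd = r_div$p, p_acd_vs_delam = r_dif$p)
})
utils::write.csv(do.call(rbind, rows), "results/fate/chi_square_tests.csv",
                 row.names = FALSE)

message("-- spinous thickness from the K10 mask --")
channels <- read_image("results/data/tissue_k10_k14.tif")
poly <- as.matrix(utils::read.csv("results/data/basement_polyline.csv"))
tm <- measure_thickness(channels[[1]], poly, threshold = "otsu",
                        pixel_size = 0.5)
utils::write.csv(data.frame(k10_area_um2 = tm$k10_area,
                            basement_length_um = tm$basement_length,
                            thickness_um = tm$thickness,
                            threshold = tm$threshold_value),
                 "results/fate/thickness.csv", row.names = FALSE)
message(sprintf("   thickness = %.2f um (mask area %.0f um2 / membrane %.0f um)",
                tm$thickness, tm$k10_area, tm$basement_length))
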