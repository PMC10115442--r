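#!/usr/bin/env Rscript
# Build the synthetic study cohort that the downstream analyses consume:
# - paired division-angle tables for WT, AGS3-KO and LGN-KO presets
#   (live-imaging emulation: anaphase onset and +1 hr),
# - clone composition tables per genotype (lineage-tracing emulation),
# - mitotic cell images with cortical crescents for two reporter groups
#   (RFP- control vs RFP+ knockdown, the latter with enhanced cortical
#   signal) plus their perimeter linescans,
# - a two-layer tissue section for thickness measurement.
# Everything is seeded and carries ground truth.

suppressPackageStartupMessages(library(epiorient))
seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- division angles: 300 cells per genotype --")
angles <- do.call(rbind, lapply(seq_along(c("WT", "AGS3_KO", "LGN_KO")),
  function(i) {
    g <- c("WT", "AGS3_KO", "LGN_KO")[i]
    simulate_division_angles(genotype_preset(g, n = 300, seed = seed + i),
                             genotype_label = g)$angles
  }))
write_angle_table(angles, file.path(out, "division_angles.csv"))
message(sprintf("   wrote %d angle pairs", nrow(angles)))

message("-- clones: 400 per genotype --")
clone_p <- list(WT = c(0.45, 0.35, 0.20), AGS3_KO = c(0.30, 0.50, 0.20),
                LGN_KO = c(0.55, 0.15, 0.30))
clones <- do.call(rbind, lapply(seq_along(clone_p), function(i) {
  g <- names(clone_p)[i]
  p <- clone_p[[g]]
  simulate_clones(clone_sim_params(400, p[1], p[2], p[3], seed = seed + 10 + i),
                  genotype_label = g)$clones
}))
write_clone_table(clones, file.path(out, "clones.csv"))
message(sprintf("   wrote %d clones", nrow(clones)))

message("-- mitotic cell images: 25 RFP- and 25 RFP+ cells --")
# RFP+ (knockdown) cells carry brighter, broader crescents than controls;
# backgrounds match the equivalent cytoplasmic levels of the two groups.
geom <- make_round_cell()
make_group <- function(reporter, n, amp_range, cov_range, bg, seed0) {
  lapply(seq_len(n), function(i) {
    tr <- withr::with_seed(seed0 + i, crescent_truth(
      center_position = runif(1, 35, 65),
      coverage = runif(1, cov_range[1], cov_range[2]),
      amplitude = runif(1, amp_range[1], amp_range[2]),
      background = bg, noise_sd = 4))
    cell <- generate_cell_image(geom, tr, seed = seed0 + 500 + i)
    sample_linescan(cell$image, cell$contour, cell$boundary_mask,
                    cell_id = sprintf("%s_%02d", reporter, i),
                    reporter_status = reporter)
  })
}
neg <- make_group("RFP-", 25, c(25, 55), c(12, 30), 11.6, seed + 100)
pos <- make_group("RFP+", 25, c(45, 90), c(20, 45), 12.4, seed + 200)
write_linescan_table(c(neg, pos), file.path(out, "linescans.csv"))
# keep one example image of each group on disk
ex <- generate_cell_image(geom, crescent_truth(50, 25, 40, 11.6, 4),
                          seed = seed + 300)
write_image(ex$image, file.path(out, "example_cell_rfpneg.tif"))
ex2 <- generate_cell_image(geom, crescent_truth(50, 35, 70, 12.4, 4),
                           seed = seed + 301)
write_image(ex2$image, file.path(out, "example_cell_rfppos.tif"))
message("   wrote linescans.csv and two example TIFFs")

message("-- tissue section: 20 um spinous band over a wavy membrane --")
tis <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.5,
                             wave_amplitude = 6, noise_sd = 5,
                             seed = seed + 400)
write_image(list(tis$k10_channel, tis$k14_channel),
            file.path(out, "tissue_k10_k14.tif"))
utils::write.csv(data.frame(x = tis$basement_polyline[, 1],
                            y = tis$basement_polyline[, 2]),
                 file.path(out, "basement_polyline.csv"), row.names = FALSE)
message(sprintf("   truth thickness: %.2f um", tis$truth$labels$thickness_um))
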