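#' Run the synthetic study pipeline end to end
#'
#' Executes the stages in dependency order with the master seed propagated
#' to every stochastic stage, writes all tables and reports under
#' `out_dir`, and returns (and writes) a run manifest with the config, the
#' package version and a checksum for every output file. Re-running with
#' the same config reproduces identical checksums.
#'
#' Stages: paired-angle simulation per genotype preset -> orientation
#' summary (bin proportions, ECDFs, KS comparisons against WT) ->
#' telophase-correction tables and Fisher tests -> clone simulation and
#' fate proportions -> synthetic crescent cells, linescan metrics and
#' threshold sensitivity -> tissue thickness.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  add <- function(path) outputs[[length(outputs) + 1L]] <<- path

  # -- stage 1: paired division angles per genotype -------------------------
  say("simulating division angles (%d cells x %d genotypes)",
      config$n_cells_per_genotype, length(config$genotypes))
  angle_sets <- lapply(seq_along(config$genotypes), function(i) {
    g <- config$genotypes[i]
    simulate_division_angles(
      genotype_preset(g, n = config$n_cells_per_genotype,
                      seed = config$seed + i), genotype_label = g)
  })
  names(angle_sets) <- config$genotypes
  angles <- do.call(rbind, lapply(angle_sets, `[[`, "angles"))
  f <- file.path(out_dir, "division_angles.csv")
  write_angle_table(angles, f); add(f)

  # -- stage 2: orientation summary ----------------------------------------
  say("orientation summary")
  t60 <- data.frame(genotype = angles$genotype, angle = angles$angle_t60)
  props <- bin_proportions(t60)
  f <- file.path(out_dir, "bin_proportions_t60.csv")
  utils::write.csv(props, f, row.names = FALSE); add(f)

  ks <- list()
  if ("WT" %in% config$genotypes) {
    wt <- angles$angle_t60[angles$genotype == "WT"]
    for (g in setdiff(config$genotypes, "WT")) {
      ks[[paste0("WT_vs_", g)]] <-
        ks_two_sample(wt, angles$angle_t60[angles$genotype == g])
    }
  }
  f <- file.path(out_dir, "ks_tests.json")
  jsonlite::write_json(ks, f, auto_unbox = TRUE, digits = NA); add(f)

  # -- stage 3: telophase correction ---------------------------------------
  say("telophase correction")
  ct <- correction_table(angles)
  fisher <- list()
  if ("WT" %in% rownames(ct$counts)) {
    for (g in setdiff(rownames(ct$counts), "WT")) {
      fisher[[paste0("WT_vs_", g)]] <-
        fisher_exact_2x2(ct$counts[c("WT", g), ])["p"]
    }
  }
  f <- file.path(out_dir, "correction.json")
  jsonlite::write_json(
    list(counts = as.data.frame(ct$counts),
         remained_oblique = as.list(ct$remained_oblique),
         fisher = fisher),
    f, auto_unbox = TRUE, digits = NA); add(f)

  # -- stage 4: clones ------------------------------------------------------
  say("clone fates")
  clone_presets <- list(WT = c(0.45, 0.35, 0.20),
                        AGS3_KO = c(0.30, 0.50, 0.20),
                        LGN_KO = c(0.55, 0.15, 0.30))
  clone_sets <- lapply(seq_along(config$genotypes), function(i) {
    g <- config$genotypes[i]
    p <- clone_presets[[g]]
    simulate_clones(clone_sim_params(config$n_clones_per_genotype,
                                     p[1], p[2], p[3],
                                     seed = config$seed + 100L + i),
                    genotype_label = g)
  })
  clones <- do.call(rbind, lapply(clone_sets, `[[`, "clones"))
  f <- file.path(out_dir, "clones.csv")
  write_clone_table(clones, f); add(f)
  f <- file.path(out_dir, "fate_proportions.csv")
  utils::write.csv(fate_proportions(clones), f, row.names = FALSE); add(f)

  # -- stage 5: crescent quantification ------------------------------------
  say("crescent quantification (%d cells)", config$n_crescent_cells)
  geom <- make_round_cell()
  profiles <- withr::with_seed(config$seed + 200L, {
    lapply(seq_len(config$n_crescent_cells), function(i) {
      truth <- crescent_truth(
        center_position = stats::runif(1, 35, 65),
        coverage = stats::runif(1, 15, 50),
        amplitude = stats::runif(1, 30, 90),
        background = 12, noise_sd = 3)
      cell <- generate_cell_image(geom, truth,
                                  seed = config$seed + 200L + i)
      sample_linescan(cell$image, cell$contour, cell$boundary_mask,
                      n_points = config$n_linescan_points,
                      band_halfwidth = config$band_halfwidth,
                      cell_id = sprintf("cell_%03d", i))
    })
  })
  metrics <- lapply(profiles, compute_crescent_metrics,
                    threshold = config$threshold)
  mdf <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(cell_id = m$cell_id, max_fi = m$max_fi,
               integrated_fi = m$integrated_fi, coverage = m$coverage,
               position = m$position, threshold = m$threshold,
               localization = classify_localization(m))
  }))
  f <- file.path(out_dir, "crescent_metrics.csv")
  utils::write.csv(mdf, f, row.names = FALSE); add(f)

  # -- stage 6: tissue thickness -------------------------------------------
  say("tissue thickness")
  tissue <- generate_tissue_image(noise_sd = 5, seed = config$seed + 300L)
  tm <- measure_thickness(tissue$k10_channel, tissue$basement_polyline,
                          threshold = "otsu",
                          pixel_size = tissue$pixel_size)
  f <- file.path(out_dir, "thickness.json")
  jsonlite::write_json(unclass(tm), f, auto_unbox = TRUE, digits = NA); add(f)

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "epiorient",
    version = as.character(utils::packageVersion("epiorient")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
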