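# File IO with schema validation. Images are TIFF; tables are comma-separated
# UTF-8 CSV with a header row and '.' decimal; configs are JSON or YAML.

# AU full scale used to store arbitrary-unit intensities in [0,1] TIFF floats.
.AU_SCALE <- 65535

#' Read / write intensity images as TIFF
#'
#' Images are stored as 32-bit-float TIFF scaled by a fixed 65535 AU full
#' scale; multi-channel images go to multi-page files. `read_image` returns
#' a single matrix or a list of channel matrices.
#'
#' @param path file path.
#' @param channels for `read_image`: optional channel indices to keep; an
#'   out-of-range index is an error naming the channel.
#' @return `read_image`: matrix (single page) or list of matrices.
#' @export
read_image <- function(path, channels = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * .AU_SCALE)
  if (!is.null(channels)) {
    bad <- channels[channels < 1 | channels > length(pages)]
    if (length(bad) > 0) {
      stop(sprintf("channel %d not present (file has %d)", bad[1],
                   length(pages)), call. = FALSE)
    }
    pages <- pages[channels]
  }
  if (length(pages) == 1L) pages[[1]] else pages
}

#' @rdname read_image
#' @param image matrix or list of matrices (AU).
#' @export
write_image <- function(image, path) {
  if (is.matrix(image)) image <- list(image)
  scaled <- lapply(image, function(m) pmin(pmax(m / .AU_SCALE, 0), 1))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

validate_columns <- function(df, schema, path) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

fail_row <- function(path, col, row, why) {
  stop(sprintf("%s: column `%s`, row %d: %s", path, col, row, why),
       call. = FALSE)
}

#' Read / write paired division-angle tables
#'
#' Schema: `cell_id, genotype, angle_t0, angle_t60`; both angles must lie in
#' `[0, 90]` degrees — a violation is reported with its row number.
#'
#' @param path CSV path.
#' @return data.frame with typed columns.
#' @export
read_angle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_columns(df, c(cell_id = "c", genotype = "c",
                         angle_t0 = "n", angle_t60 = "n"), path)
  for (col in c("angle_t0", "angle_t60")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 90)
    if (length(bad) > 0) fail_row(path, col, bad[1], "angle outside [0, 90]")
  }
  if (any(!nzchar(df$cell_id))) {
    fail_row(path, "cell_id", which(!nzchar(df$cell_id))[1], "empty id")
  }
  df
}

#' @rdname read_angle_table
#' @param df data.frame to write.
#' @export
write_angle_table <- function(df, path) {
  out <- df[, c("cell_id", "genotype", "angle_t0", "angle_t60")]
  # full-precision formatting so tables round-trip bit-identically
  out$angle_t0 <- sprintf("%.17g", out$angle_t0)
  out$angle_t60 <- sprintf("%.17g", out$angle_t60)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write clone composition tables
#'
#' Schema: `clone_id, embryo_id, genotype, n_basal, n_suprabasal,
#' first_spinous`; counts must be nonnegative integers and every clone must
#' contain at least one cell.
#'
#' @param path CSV path.
#' @return data.frame with typed columns (`first_spinous` logical).
#' @export
read_clone_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_columns(df, c(clone_id = "c", embryo_id = "c", genotype = "c",
                         n_basal = "i", n_suprabasal = "i",
                         first_spinous = "l"), path)
  for (col in c("n_basal", "n_suprabasal")) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) fail_row(path, col, bad[1],
                                  "count must be a nonnegative integer")
  }
  empty <- which(df$n_basal + df$n_suprabasal < 1)
  if (length(empty) > 0) fail_row(path, "n_basal", empty[1],
                                  "clone contains no cells")
  df$first_spinous <- as.logical(df$first_spinous)
  df
}

#' @rdname read_clone_table
#' @param df data.frame to write.
#' @export
write_clone_table <- function(df, path) {
  utils::write.csv(df[, c("clone_id", "embryo_id", "genotype", "n_basal",
                          "n_suprabasal", "first_spinous")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write linescan tables
#'
#' Wide per-cell format: `cell_id, reporter, pos_0 ... pos_<n-1>,
#' background`.
#'
#' @param path CSV path.
#' @return List of [linescan_profile()] objects.
#' @export
read_linescan_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pos_cols <- grep("^pos_[0-9]+$", names(df), value = TRUE)
  if (length(pos_cols) == 0) {
    stop(sprintf("%s: no pos_* columns found", path), call. = FALSE)
  }
  pos_cols <- pos_cols[order(as.integer(sub("pos_", "", pos_cols)))]
  lapply(seq_len(nrow(df)), function(i) {
    linescan_profile(as.numeric(df[i, pos_cols]),
                     background = df$background[i],
                     cell_id = df$cell_id[i],
                     reporter_status = df$reporter[i],
                     n_points = length(pos_cols))
  })
}

#' @rdname read_linescan_table
#' @param profiles list of [linescan_profile()] objects.
#' @export
write_linescan_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    v <- as.list(sprintf("%.17g", p$intensities))
    names(v) <- paste0("pos_", seq_along(v) - 1L)
    c(list(cell_id = p$cell_id, reporter = p$reporter_status), v,
      list(background = sprintf("%.17g", p$background)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated bag of the tunable parameters of the synthetic study pipeline.
#'
#' @param seed integer master seed.
#' @param threshold AU crescent threshold.
#' @param band_halfwidth linescan sampling band half-width, pixels.
#' @param n_linescan_points perimeter samples per cell.
#' @param bin_edges orientation bin edges, degrees.
#' @param n_cells_per_genotype cells per genotype for the angle simulation.
#' @param n_clones_per_genotype clones per genotype.
#' @param n_crescent_cells synthetic crescent images to quantify.
#' @param genotypes genotype preset names to simulate.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, threshold = 20, band_halfwidth = 3,
                            n_linescan_points = 100L,
                            bin_edges = c(30, 60),
                            n_cells_per_genotype = 200L,
                            n_clones_per_genotype = 500L,
                            n_crescent_cells = 20L,
                            genotypes = c("WT", "AGS3_KO", "LGN_KO")) {
  stop_if_not_scalar_number(seed, "seed")
  stop_if_not_scalar_number(threshold, "threshold", lo = 0)
  stop_if_not_scalar_number(band_halfwidth, "band_halfwidth", lo = 0.5)
  stop_if_not_scalar_number(n_linescan_points, "n_linescan_points", lo = 10)
  if (!identical(sort(as.numeric(bin_edges)), c(30, 60)) &&
      !(length(bin_edges) == 2 && all(diff(c(0, sort(bin_edges), 90)) > 0))) {
    stop("`bin_edges` must be two increasing values inside (0, 90)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(n_cells_per_genotype, "n_cells_per_genotype", 1)
  stop_if_not_scalar_number(n_clones_per_genotype, "n_clones_per_genotype", 1)
  stop_if_not_scalar_number(n_crescent_cells, "n_crescent_cells", 1)
  genotypes <- match.arg(genotypes, c("WT", "AGS3_KO", "LGN_KO"),
                         several.ok = TRUE)
  structure(list(seed = as.integer(seed), threshold = as.numeric(threshold),
                 band_halfwidth = as.numeric(band_halfwidth),
                 n_linescan_points = as.integer(n_linescan_points),
                 bin_edges = as.numeric(bin_edges),
                 n_cells_per_genotype = as.integer(n_cells_per_genotype),
                 n_clones_per_genotype = as.integer(n_clones_per_genotype),
                 n_crescent_cells = as.integer(n_crescent_cells),
                 genotypes = genotypes),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop(sprintf("unsupported config format: .%s", ext), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(x, path)
  } else {
    stop(sprintf("unsupported config format: .%s", ext), call. = FALSE)
  }
  invisible(path)
}
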