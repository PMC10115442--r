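#' Classify mitotic lineage-tracing clones
#'
#' Two-cell clone rubric over a short tracing window: two basal cells is a
#' symmetric cell division (`SCD`); one basal plus one suprabasal an
#' asymmetric cell division (`ACD`); a single suprabasal cell *in the first
#' spinous layer* a `delamination` event. Every other composition —
#' including single suprabasal cells above the first spinous layer (likely
#' labelled after differentiation) and clones of more than two cells — is
#' `excluded`, with the reason reported.
#'
#' @param n_basal,n_suprabasal nonnegative integer vectors (recycled).
#' @param first_spinous logical vector: suprabasal cell(s) lie in the first
#'   spinous layer.
#' @return data.frame `n_basal, n_suprabasal, first_spinous, fate_class,
#'   exclusion_reason` (`NA` for classified clones).
#' @export
classify_clone <- function(n_basal, n_suprabasal, first_spinous = FALSE) {
  k <- max(length(n_basal), length(n_suprabasal), length(first_spinous))
  n_basal <- rep_len(as.integer(n_basal), k)
  n_suprabasal <- rep_len(as.integer(n_suprabasal), k)
  first_spinous <- rep_len(as.logical(first_spinous), k)
  if (any(n_basal < 0) || any(n_suprabasal < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  if (any(n_basal + n_suprabasal < 1)) {
    stop("every clone must contain at least one cell", call. = FALSE)
  }
  fate <- rep("excluded", k)
  reason <- rep(NA_character_, k)
  fate[n_basal == 2L & n_suprabasal == 0L] <- "SCD"
  fate[n_basal == 1L & n_suprabasal == 1L] <- "ACD"
  delam <- n_basal == 0L & n_suprabasal == 1L & first_spinous
  fate[delam] <- "delamination"
  excl <- fate == "excluded"
  reason[excl & n_basal == 0L & n_suprabasal == 1L & !first_spinous] <-
    "single suprabasal cell above first spinous layer"
  reason[excl & n_basal == 1L & n_suprabasal == 0L] <-
    "single basal cell (no division or differentiation)"
  reason[excl & n_basal + n_suprabasal > 2L] <-
    "clone larger than two cells (more than one division)"
  reason[excl & is.na(reason)] <- "composition outside the two-cell rubric"
  data.frame(n_basal = n_basal, n_suprabasal = n_suprabasal,
             first_spinous = first_spinous, fate_class = fate,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Clone fate proportions per genotype
#'
#' Among *division* clones, the SCD : ACD split; among *differentiative*
#' clones, the ACD : delamination split. Both denominators are emitted so
#' either convention for the SCD/ACD comparison (with or without
#' delamination clones in the denominator) can be read off the counts.
#'
#' @param clones data.frame with columns `genotype, n_basal, n_suprabasal,
#'   first_spinous`.
#' @return data.frame with one row per genotype: counts `n_scd, n_acd,
#'   n_delam, n_excluded, n_total`, and fractions `scd_frac_div`
#'   (= SCD / (SCD + ACD)), `acd_frac_div`, `acd_frac_diff`
#'   (= ACD / (ACD + delamination)), `delam_frac_diff`.
#' @export
fate_proportions <- function(clones) {
  stopifnot(is.data.frame(clones),
            all(c("genotype", "n_basal", "n_suprabasal", "first_spinous")
                %in% names(clones)))
  cls <- classify_clone(clones$n_basal, clones$n_suprabasal,
                        clones$first_spinous)$fate_class
  genos <- unique(clones$genotype)
  rows <- lapply(genos, function(g) {
    cg <- cls[clones$genotype == g]
    n_scd <- sum(cg == "SCD"); n_acd <- sum(cg == "ACD")
    n_del <- sum(cg == "delamination"); n_exc <- sum(cg == "excluded")
    ndiv <- n_scd + n_acd; ndiff <- n_acd + n_del
    data.frame(
      genotype = g, n_scd = n_scd, n_acd = n_acd, n_delam = n_del,
      n_excluded = n_exc, n_total = length(cg),
      scd_frac_div = if (ndiv > 0) n_scd / ndiv else NA_real_,
      acd_frac_div = if (ndiv > 0) n_acd / ndiv else NA_real_,
      acd_frac_diff = if (ndiff > 0) n_acd / ndiff else NA_real_,
      delam_frac_diff = if (ndiff > 0) n_del / ndiff else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spinous-layer thickness from a K10 channel
#'
#' Thresholds the K10 signal into a binary mask (Otsu by default, or a fixed
#' AU value), and divides the supra-threshold area by the arc length of the
#' basement-membrane polyline: thickness = area / length, in microns.
#'
#' @param k10_channel intensity matrix (`[y, x]`, AU).
#' @param basement_polyline n x 2 matrix of `(x, y)` pixel points tracing
#'   the basement membrane.
#' @param threshold `"otsu"` or a fixed AU value.
#' @param pixel_size microns per pixel.
#' @return An object of class `tissue_measurement`: list with `k10_area`
#'   (µm²), `basement_length` (µm), `thickness` (µm), `threshold_method`,
#'   `threshold_value`.
#' @export
measure_thickness <- function(k10_channel, basement_polyline,
                              threshold = "otsu", pixel_size = 1) {
  basement_polyline <- as.matrix(basement_polyline)
  if (nrow(basement_polyline) < 2L) {
    stop("basement polyline must contain at least 2 points", call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size, "pixel_size", lo = 1e-9)
  rng <- range(k10_channel)
  if (identical(threshold, "otsu")) {
    method <- "otsu"
    if (rng[2] <= rng[1]) {
      # constant image: nothing to segment
      thr <- rng[2]
      mask <- k10_channel > thr
    } else {
      scaled <- (k10_channel - rng[1]) / (rng[2] - rng[1])
      thr01 <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
      thr <- rng[1] + thr01 * (rng[2] - rng[1])
      mask <- k10_channel > thr
    }
  } else {
    method <- "fixed"
    thr <- stop_if_not_scalar_number(threshold, "threshold")
    mask <- k10_channel > thr
  }
  area <- sum(mask) * pixel_size^2
  len <- polyline_length(basement_polyline) * pixel_size
  if (len <= 0) stop("basement polyline has zero length", call. = FALSE)
  structure(list(k10_area = area, basement_length = len,
                 thickness = area / len, threshold_method = method,
                 threshold_value = thr),
            class = "tissue_measurement")
}
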