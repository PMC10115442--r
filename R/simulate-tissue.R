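#' Render a synthetic two-layer tissue section
#'
#' Emulates a sagittal epidermal section for thickness measurement: a
#' basal (K14) band sitting on the basement membrane and a suprabasal (K10)
#' band of stated height directly above it. The basement membrane may be
#' flat or sinusoidal; the suprabasal band is painted with constant vertical
#' height above it.
#'
#' @param basal_height,suprabasal_height band heights in microns.
#' @param length lateral extent of the section in microns.
#' @param pixel_size microns per pixel.
#' @param noise_sd additive Gaussian noise sd (AU), clamped at 0.
#' @param intensity in-band signal level (AU).
#' @param wave_amplitude,wave_period basement-membrane sinusoid in microns
#'   (`wave_amplitude = 0` gives a flat membrane).
#' @param seed integer seed for the noise.
#' @return A list with `k10_channel` and `k14_channel` (matrices, AU),
#'   `basement_polyline` (n x 2 matrix of pixel `(x, y)` points along the
#'   membrane), `pixel_size`, and `truth` — a `synthetic_truth` whose labels
#'   give the painted suprabasal area (µm²), the membrane arc length (µm)
#'   and the implied thickness = area / length (µm).
#' @export
generate_tissue_image <- function(basal_height = 10, suprabasal_height = 20,
                                  length = 100, pixel_size = 0.5,
                                  noise_sd = 0, intensity = 100,
                                  wave_amplitude = 0,
                                  wave_period = length / 2, seed = NULL) {
  for (nm in c("basal_height", "suprabasal_height", "length", "noise_sd",
               "intensity", "wave_amplitude")) {
    stop_if_not_scalar_number(get(nm), nm, lo = 0)
  }
  stop_if_not_scalar_number(pixel_size, "pixel_size", lo = 1e-9)
  if (length <= 0) stop("`length` must be positive", call. = FALSE)

  w <- max(2L, round(length / pixel_size))
  margin <- 4L
  h <- as.integer(ceiling((basal_height + suprabasal_height +
                             2 * wave_amplitude) / pixel_size) + 2L * margin)

  x <- seq_len(w)
  offset <- if (wave_amplitude > 0) {
    wave_amplitude / pixel_size *
      (1 + sin(2 * pi * x * pixel_size / wave_period))
  } else {
    rep(0, w)
  }
  y_base <- h - margin - offset
  b_px <- basal_height / pixel_size
  s_px <- suprabasal_height / pixel_size

  k14 <- matrix(0, h, w)
  k10 <- matrix(0, h, w)
  rows <- seq_len(h)
  for (j in x) {
    in_k14 <- rows > y_base[j] - b_px & rows <= y_base[j]
    in_k10 <- rows > y_base[j] - b_px - s_px & rows <= y_base[j] - b_px
    k14[in_k14, j] <- intensity
    k10[in_k10, j] <- intensity
  }
  area_um2 <- sum(k10 > 0) * pixel_size^2

  polyline <- cbind(x, y_base)
  arc_um <- polyline_length(polyline) * pixel_size
  # a single-column section has a degenerate polyline; not reachable with
  # length >= 2 * pixel_size

  if (noise_sd > 0) {
    noise <- with_seed_or_not(seed, {
      list(k10 = matrix(stats::rnorm(h * w, 0, noise_sd), h, w),
           k14 = matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
    })
    k10 <- pmax(k10 + noise$k10, 0)
    k14 <- pmax(k14 + noise$k14, 0)
  }

  truth <- synthetic_truth(
    id = "tissue",
    params = list(basal_height = basal_height,
                  suprabasal_height = suprabasal_height, length = length,
                  pixel_size = pixel_size, noise_sd = noise_sd,
                  wave_amplitude = wave_amplitude, wave_period = wave_period),
    labels = list(k10_area_um2 = area_um2, basement_length_um = arc_um,
                  thickness_um = if (arc_um > 0) area_um2 / arc_um else 0))
  list(k10_channel = k10, k14_channel = k14, basement_polyline = polyline,
       pixel_size = pixel_size, truth = truth)
}
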