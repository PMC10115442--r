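#' Cell geometry for the synthetic image generator
#'
#' Describes one mitotic cell to be rendered: a simple closed boundary
#' polygon, the basement-membrane reference line, the image canvas and the
#' pixel size.
#'
#' @param boundary n x 2 matrix of `(x, y)` vertex coordinates (pixels) of a
#'   simple closed polygon lying inside the image.
#' @param basement_line 2 x 2 matrix of `(x, y)` points defining the
#'   basement-membrane direction; must have nonzero length.
#' @param image_shape integer vector `c(height, width)` in pixels.
#' @param pixel_size microns per pixel.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(boundary, basement_line, image_shape,
                          pixel_size = 1) {
  boundary <- as.matrix(boundary)
  basement_line <- as.matrix(basement_line)
  if (ncol(boundary) != 2L || nrow(boundary) < 3L) {
    stop("`boundary` must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (!identical(dim(basement_line), c(2L, 2L))) {
    stop("`basement_line` must be a 2 x 2 matrix of two points",
         call. = FALSE)
  }
  if (sum((basement_line[2, ] - basement_line[1, ])^2) == 0) {
    stop("basement line has zero length", call. = FALSE)
  }
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 4L))
  bad <- which(boundary[, 1] < 1 | boundary[, 1] > image_shape[2] |
                 boundary[, 2] < 1 | boundary[, 2] > image_shape[1])
  if (length(bad) > 0) {
    stop(sprintf(
      "boundary vertex %d at (%.1f, %.1f) lies outside the %d x %d image",
      bad[1], boundary[bad[1], 1], boundary[bad[1], 2],
      image_shape[1], image_shape[2]), call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size, "pixel_size", lo = 1e-9)
  structure(list(boundary = boundary, basement_line = basement_line,
                 image_shape = image_shape, pixel_size = pixel_size),
            class = "cell_geometry")
}

#' Convenience constructor: a roughly circular basal cell above a horizontal
#' basement membrane
#'
#' @param center `(x, y)` center in pixels; defaults to the image center.
#' @param radius cell radius in pixels.
#' @param n_vertices number of polygon vertices.
#' @param image_shape `c(height, width)` in pixels.
#' @param pixel_size microns per pixel.
#' @return A [cell_geometry()] whose basement line runs horizontally below
#'   the cell, so perimeter position 0 is the bottom of the cell and 50 the
#'   apex.
#' @export
make_round_cell <- function(radius = 30, image_shape = c(96, 96),
                            center = NULL, n_vertices = 96, pixel_size = 1) {
  if (is.null(center)) center <- c(image_shape[2] / 2, image_shape[1] / 2 - 2)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  boundary <- cbind(center[1] + radius * cos(th),
                    center[2] + radius * sin(th))
  y_base <- min(center[2] + radius + 3, image_shape[1] - 1)
  basement <- rbind(c(1, y_base), c(image_shape[2], y_base))
  cell_geometry(boundary, basement, image_shape, pixel_size)
}

#' Ground-truth crescent parameters
#'
#' Generative parameters of a cortical crescent: where it sits on the
#' perimeter, how much of the perimeter it spans, and how bright it is over
#' the cytoplasmic background.
#'
#' @param center_position crescent center, perimeter percent in `[0, 100)`.
#' @param coverage crescent extent, perimeter percent in `[0, 100]`;
#'   `coverage = 0` means no crescent regardless of amplitude.
#' @param amplitude peak intensity above background, AU >= 0.
#' @param background cytoplasmic intensity, AU >= 0.
#' @param noise_sd additive noise standard deviation, AU >= 0.
#' @return An object of class `crescent_truth`.
#' @export
crescent_truth <- function(center_position, coverage, amplitude,
                           background, noise_sd = 0) {
  stop_if_not_scalar_number(center_position, "center_position", 0, 100 - 1e-12)
  stop_if_not_scalar_number(coverage, "coverage", 0, 100)
  stop_if_not_scalar_number(amplitude, "amplitude", 0)
  stop_if_not_scalar_number(background, "background", 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(center_position = as.numeric(center_position),
                 coverage = as.numeric(coverage),
                 amplitude = as.numeric(amplitude),
                 background = as.numeric(background),
                 noise_sd = as.numeric(noise_sd)),
            class = "crescent_truth")
}

# Crescent intensity window over circular perimeter distance delta (percent).
# Raised cosine (Hann) reaches 1 at the center and 0 at +/- coverage/2;
# the rectangular option is 1 on the same support.
crescent_window <- function(delta, coverage, window) {
  if (coverage <= 0) return(rep(0, length(delta)))
  inside <- delta <= coverage / 2
  w <- numeric(length(delta))
  if (window == "rectangular") {
    w[inside] <- 1
  } else {
    w[inside] <- 0.5 * (1 + cos(2 * pi * delta[inside] / coverage))
  }
  w
}

#' Render a synthetic mitotic cell image with a cortical crescent
#'
#' Paints a cell interior at the cytoplasmic background level, a cortical
#' band of stated width along the boundary carrying
#' `background + amplitude * w(s)` — where `w` is a raised-cosine (default)
#' or rectangular window of width `coverage` centered at `center_position`
#' in perimeter percent — and adds noise. Pixels outside the cell are 0
#' before noise.
#'
#' @param geometry a [cell_geometry()].
#' @param truth a [crescent_truth()].
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical image. `NULL` uses the current RNG stream.
#' @param band_width width of the painted cortical band, pixels (measured
#'   inward from the boundary).
#' @param window `"raised_cosine"` (graded shoulders, as antibody crescents
#'   show) or `"rectangular"` (sharp-edged oracle mode).
#' @param noise_model `"gaussian"` (additive, clamped at 0) or `"poisson"`.
#' @return A list with `image` (height x width matrix, AU),
#'   `boundary_mask` (0/1 matrix), `contour` (the canonical
#'   `perimeter_contour` used for painting) and `truth` (a `synthetic_truth`
#'   record wrapping the inputs).
#' @export
generate_cell_image <- function(geometry, truth, seed = NULL, band_width = 3,
                                window = c("raised_cosine", "rectangular"),
                                noise_model = c("gaussian", "poisson")) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(truth, "crescent_truth"))
  window <- match.arg(window)
  noise_model <- match.arg(noise_model)
  stop_if_not_scalar_number(band_width, "band_width", lo = 0.5)

  h <- geometry$image_shape[1]; w <- geometry$image_shape[2]
  contour <- canonicalize_contour(geometry$boundary, geometry$basement_line)

  px <- as.matrix(expand.grid(x = seq_len(w), y = seq_len(h)))
  inside <- pracma::inpolygon(px[, 1], px[, 2],
                              contour$points[, 1], contour$points[, 2],
                              boundary = TRUE)
  img <- matrix(0, h, w)
  vals <- numeric(sum(inside))
  vals[] <- truth$background

  near <- contour_nearest(contour, px[inside, , drop = FALSE])
  in_band <- near$d <= band_width
  if (any(in_band) && truth$coverage > 0 && truth$amplitude > 0) {
    delta <- circ_dist_pct(near$s[in_band], truth$center_position)
    vals[in_band] <- truth$background +
      truth$amplitude * crescent_window(delta, truth$coverage, window)
  }
  img[cbind(px[inside, 2], px[inside, 1])] <- vals

  img <- with_seed_or_not(seed, {
    if (noise_model == "gaussian") {
      if (truth$noise_sd > 0) {
        pmax(img + matrix(stats::rnorm(h * w, 0, truth$noise_sd), h, w), 0)
      } else img
    } else {
      matrix(stats::rpois(h * w, lambda = img), h, w)
    }
  })

  mask <- matrix(0L, h, w)
  mask[cbind(px[inside, 2], px[inside, 1])] <- 1L

  list(image = img, boundary_mask = mask, contour = contour,
       truth = synthetic_truth(
         id = "cell", params = truth,
         labels = list(window = window, band_width = band_width,
                       seed = seed)))
}

#' Ground-truth record attached to generated data
#'
#' Every generated image or table carries exactly one of these, pairing the
#' generating parameter object with per-item latent labels so downstream
#' stages can be tested by parameter recovery.
#'
#' @param id record identifier.
#' @param params the generating parameter object.
#' @param labels list or data.frame of per-item latent labels.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(id, params, labels = NULL) {
  structure(list(id = id, params = params, labels = labels),
            class = "synthetic_truth")
}
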