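#' Extract the ordered cell perimeter from a boundary mask
#'
#' Traces the outer contour of the single connected region in
#' `boundary_mask`, orders it counterclockwise, starts it at the basal-most
#' point — the contour point of minimal perpendicular distance to the
#' basement-membrane line (ties broken toward smaller x) — and
#' parameterizes it by cumulative arc length in perimeter percent.
#'
#' @param boundary_mask binary matrix (`[y, x]`, nonzero = cell).
#' @param basement_line 2 x 2 matrix; two points defining the
#'   basement-membrane direction.
#' @return A `perimeter_contour` (see [canonicalize_contour()]).
#' @export
extract_perimeter <- function(boundary_mask, basement_line) {
  m <- (boundary_mask != 0) * 1
  lab <- EBImage::bwlabel(EBImage::Image(t(m)))
  n_regions <- max(lab)
  if (n_regions != 1L) {
    stop(sprintf("boundary mask must contain exactly 1 connected region, found %d",
                 n_regions), call. = FALSE)
  }
  oc <- EBImage::ocontour(lab)[[1]]
  pts <- oc + 1  # EBImage contours are 0-based (x, y)
  if (nrow(pts) < 8L) {
    stop(sprintf("degenerate contour: only %d points (need >= 8)", nrow(pts)),
         call. = FALSE)
  }
  canonicalize_contour(pts, basement_line)
}

#' Perimeter linescan of one cell
#'
#' Container for the intensity profile around a mitotic cell perimeter,
#' compressed to `n` evenly spaced perimeter-percent positions (position 0 at
#' the basal-most point).
#'
#' @param intensities numeric vector of per-position intensities, AU.
#' @param background cytoplasmic background estimate, AU (NA if unknown).
#' @param background_subtracted has `background` already been subtracted
#'   from `intensities`?
#' @param cell_id cell identifier.
#' @param reporter_status `"RFP+"`, `"RFP-"`, or `NA`.
#' @param n_points expected number of samples (default 100).
#' @return An object of class `linescan_profile`; `positions` are
#'   `0, 100/n, ..., 100 - 100/n` percent.
#' @export
linescan_profile <- function(intensities, background = NA_real_,
                             background_subtracted = FALSE,
                             cell_id = NA_character_,
                             reporter_status = NA_character_,
                             n_points = 100L) {
  intensities <- as.numeric(intensities)
  if (length(intensities) != n_points) {
    stop(sprintf("expected exactly %d intensity samples, got %d",
                 n_points, length(intensities)), call. = FALSE)
  }
  if (!is.na(background) && background < 0) {
    stop("`background` must be >= 0", call. = FALSE)
  }
  structure(list(positions = seq(0, 100, length.out = n_points + 1L)[-(n_points + 1L)],
                 intensities = intensities,
                 background = as.numeric(background),
                 background_subtracted = isTRUE(background_subtracted),
                 cell_id = cell_id, reporter_status = reporter_status),
            class = "linescan_profile")
}

#' Sample a perimeter linescan from an image
#'
#' Sample `i` (for `i = 0, ..., n_points - 1`) is the mean intensity over
#' pixels within `band_halfwidth` (Euclidean, pixel centers) of the contour
#' point at perimeter position `i * 100 / n_points`. When a boundary mask is
#' supplied, only in-cell pixels enter the mean (the space outside the cell
#' is unstained and would dilute the cortical signal) and the cytoplasmic
#' background is estimated with [estimate_background()]; background is *not*
#' subtracted here.
#'
#' @param image intensity matrix (`[y, x]`, AU).
#' @param contour a `perimeter_contour` from [extract_perimeter()] or
#'   [canonicalize_contour()].
#' @param boundary_mask optional binary mask restricting the sampling band
#'   and enabling the background estimate.
#' @param n_points number of perimeter samples (default 100).
#' @param band_halfwidth sampling band half-width in pixels.
#' @param cell_id,reporter_status carried into the profile.
#' @return A [linescan_profile()].
#' @export
sample_linescan <- function(image, contour, boundary_mask = NULL,
                            n_points = 100L, band_halfwidth = 3,
                            cell_id = NA_character_,
                            reporter_status = NA_character_) {
  stopifnot(inherits(contour, "perimeter_contour"))
  h <- nrow(image); w <- ncol(image)
  s_targets <- seq(0, 100, length.out = n_points + 1L)[-(n_points + 1L)]
  pts <- contour_point_at(contour, s_targets)
  if (any(pts[, 1] < 1 - 1e-9 | pts[, 1] > w + 1e-9 |
            pts[, 2] < 1 - 1e-9 | pts[, 2] > h + 1e-9)) {
    stop("contour exits the image bounds", call. = FALSE)
  }

  r <- ceiling(band_halfwidth)
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= band_halfwidth^2 + 1e-9, ,
               drop = FALSE]
  use_mask <- !is.null(boundary_mask)

  vals <- vapply(seq_len(n_points), function(i) {
    cx <- round(pts[i, 1]); cy <- round(pts[i, 2])
    xs <- cx + offs[, 1]; ys <- cy + offs[, 2]
    ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
    xs <- xs[ok]; ys <- ys[ok]
    if (use_mask) {
      inm <- boundary_mask[cbind(ys, xs)] != 0
      xs <- xs[inm]; ys <- ys[inm]
    }
    if (length(xs) == 0) return(NA_real_)
    mean(image[cbind(ys, xs)])
  }, numeric(1))

  if (anyNA(vals)) {
    # fall back to nearest single pixel where the band missed the mask
    na_i <- which(is.na(vals))
    vals[na_i] <- image[cbind(pmin(pmax(round(pts[na_i, 2]), 1), h),
                              pmin(pmax(round(pts[na_i, 1]), 1), w))]
  }

  bg <- if (use_mask) {
    estimate_background(image, boundary_mask, cortical_band = band_halfwidth)
  } else NA_real_

  linescan_profile(vals, background = bg, background_subtracted = FALSE,
                   cell_id = cell_id, reporter_status = reporter_status,
                   n_points = n_points)
}

#' Estimate cytoplasmic background
#'
#' Mean intensity over interior pixels farther than `cortical_band` pixels
#' from the cell boundary (morphological erosion with a disc).
#'
#' @param image intensity matrix.
#' @param boundary_mask binary mask of the cell.
#' @param cortical_band pixels to strip from the boundary inward.
#' @return Background level, AU (0 for an all-zero image).
#' @export
estimate_background <- function(image, boundary_mask, cortical_band = 3) {
  m <- (boundary_mask != 0) * 1
  brush_size <- 2L * as.integer(ceiling(cortical_band)) + 1L
  eroded <- EBImage::erode(EBImage::Image(t(m)),
                           EBImage::makeBrush(brush_size, shape = "disc"))
  interior <- t(eroded@.Data) != 0
  if (!any(interior)) {
    stop(sprintf(
      "no interior pixels remain after stripping a %g-pixel cortical band; try a smaller band",
      cortical_band), call. = FALSE)
  }
  mean(image[interior])
}
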