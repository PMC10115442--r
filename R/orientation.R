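#' Division angle relative to the basement membrane
#'
#' The acute angle between the vector connecting the two daughter-cell
#' centroids and a vector parallel to the basement membrane, in degrees
#' `[0, 90]`. Symmetric in daughter order and invariant under global
#' rotation.
#'
#' @param centroid_a,centroid_b `(x, y)` daughter centroids (must differ).
#' @param basement_vector nonzero `(x, y)` direction of the basement
#'   membrane.
#' @return Angle in degrees.
#' @export
division_angle <- function(centroid_a, centroid_b, basement_vector) {
  d <- as.numeric(centroid_b) - as.numeric(centroid_a)
  if (sum(d^2) == 0) {
    stop("daughter centroids are identical", call. = FALSE)
  }
  b <- as.numeric(basement_vector)
  if (sum(b^2) == 0) {
    stop("basement vector has zero length", call. = FALSE)
  }
  cosang <- abs(sum(d * b)) / sqrt(sum(d^2) * sum(b^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Bin division angles into planar / oblique / perpendicular
#'
#' Bins are left-closed, right-open, except the top bin which is closed at
#' 90: planar `[0, 30)`, oblique `[30, 60)`, perpendicular `[60, 90]`.
#'
#' @param angle numeric vector of degrees in `[0, 90]`.
#' @return Factor with levels `planar`, `oblique`, `perpendicular`.
#' @export
bin_angle <- function(angle) {
  if (any(!is.finite(angle)) || any(angle < 0 | angle > 90)) {
    stop("angles must be finite and within [0, 90]", call. = FALSE)
  }
  cut(angle, breaks = c(-Inf, 30, 60, Inf), right = FALSE,
      labels = c("planar", "oblique", "perpendicular"))
}

#' Empirical cumulative distribution of division angles
#'
#' @param angles numeric vector of degrees.
#' @return data.frame `angle` (sorted unique values) and `cum_fraction`
#'   (right-continuous ECDF evaluated at each), nondecreasing and ending
#'   at 1.
#' @export
angle_ecdf <- function(angles) {
  if (length(angles) == 0) stop("`angles` must be non-empty", call. = FALSE)
  u <- sort(unique(angles))
  data.frame(angle = u,
             cum_fraction = vapply(u, function(a) mean(angles <= a),
                                   numeric(1)))
}

#' Orientation-bin proportions per group
#'
#' @param records data.frame with an `angle` column (degrees) and a grouping
#'   column.
#' @param group name of the grouping column (default `"genotype"`).
#' @return data.frame `group, bin, n, fraction`; fractions sum to 1 within
#'   each group.
#' @export
bin_proportions <- function(records, group = "genotype") {
  stopifnot(is.data.frame(records), "angle" %in% names(records),
            group %in% names(records))
  bins <- bin_angle(records$angle)
  tab <- table(records[[group]], bins)
  n_group <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "bin", "n")
  out$fraction <- out$n / n_group[out$group]
  out[order(out$group, match(out$bin, levels(bins))), , drop = FALSE]
}
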