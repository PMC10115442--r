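#' Canonicalize a closed cell contour
#'
#' Puts a closed boundary into the package's canonical form: vertices ordered
#' counterclockwise (positive shoelace area in stored `(x, y)` coordinates),
#' starting at the basal-most vertex — the one with minimal perpendicular
#' distance to the basement-membrane line (ties broken toward smaller x) —
#' with cumulative arc length expressed in perimeter percent spanning
#' `[0, 100)`.
#'
#' @param points n x 2 matrix of `(x, y)` vertex coordinates of a simple
#'   closed polygon (the closing edge from last to first vertex is implicit).
#' @param basement_line 2 x 2 matrix; the two points defining the
#'   basement-membrane direction.
#' @return An object of class `perimeter_contour`: a list with `points`
#'   (reordered vertices), `s` (perimeter percent of each vertex, starting at
#'   0), and `length` (total perimeter in pixel units).
#' @seealso [extract_perimeter()] for the mask-based entry point.
#' @export
canonicalize_contour <- function(points, basement_line) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L) {
    stop("`points` must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  basement_line <- as.matrix(basement_line)

  # counterclockwise = positive shoelace signed area in stored coordinates
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area2 <- sum(x * yn - xn * y)
  if (area2 == 0) stop("contour is degenerate (zero area)", call. = FALSE)
  if (area2 < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]

  d <- dist_point_line(points, basement_line[1, ], basement_line[2, ])
  cand <- which(d <= min(d) + 1e-9)
  start <- cand[which.min(points[cand, 1])]
  idx <- c(start:nrow(points), seq_len(start - 1L))
  points <- points[idx, , drop = FALSE]

  seg <- sqrt(rowSums((rbind(points[-1, , drop = FALSE], points[1, ]) -
                         points)^2))
  total <- sum(seg)
  if (total <= 0) stop("contour has zero perimeter", call. = FALSE)
  s <- c(0, cumsum(seg)[-length(seg)]) / total * 100

  structure(list(points = points, s = s, length = total),
            class = "perimeter_contour")
}

#' Interpolate points on a canonical contour at given perimeter positions
#'
#' Linear interpolation along the polygon edges, wrapping across the 0/100
#' seam.
#'
#' @param contour a `perimeter_contour`.
#' @param s_target numeric vector of perimeter positions in percent.
#' @return length(s_target) x 2 matrix of `(x, y)` coordinates.
#' @export
contour_point_at <- function(contour, s_target) {
  stopifnot(inherits(contour, "perimeter_contour"))
  s <- c(contour$s, 100)
  pts <- rbind(contour$points, contour$points[1, ])
  s_target <- s_target %% 100
  i <- findInterval(s_target, s, rightmost.closed = TRUE)
  frac <- (s_target - s[i]) / (s[i + 1] - s[i])
  frac[!is.finite(frac)] <- 0
  pts[i, , drop = FALSE] * (1 - frac) +
    pts[i + 1, , drop = FALSE] * frac
}

# Nearest perimeter position (percent) and distance for query points.
# pts: n x 2 matrix. Returns list(s = percent, d = distance in pixels).
# Distances are to the polygon edges, positions linearly interpolated.
contour_nearest <- function(contour, pts) {
  P <- contour$points
  n <- nrow(P)
  nxt <- c(2:n, 1L)
  best_d2 <- rep(Inf, nrow(pts))
  best_s <- numeric(nrow(pts))
  seg_len <- sqrt(rowSums((P[nxt, , drop = FALSE] - P)^2))
  s_vert <- contour$s
  total <- contour$length
  for (k in seq_len(n)) {
    a <- P[k, ]; b <- P[nxt[k], ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- (s_vert[k] + t[upd] * seg_len[k] / total * 100) %% 100
    }
  }
  list(s = best_s, d = sqrt(best_d2))
}
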