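# Internal helpers shared across modules.

# Circular distance between perimeter positions (percent, period 100).
circ_dist_pct <- function(a, b, period = 100) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Midpoint of a circular run starting at `start` with extent `len` (percent).
circ_mid_pct <- function(start, len, period = 100) {
  (start + len / 2) %% period
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed means "use the current RNG stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Perpendicular distance from points (n x 2 matrix) to the infinite line
# through p1 and p2.
dist_point_line <- function(pts, p1, p2) {
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len == 0) stop("basement line has zero length", call. = FALSE)
  abs((pts[, 1] - p1[1]) * v[2] - (pts[, 2] - p1[2]) * v[1]) / len
}

# Arc length of an open polyline given as an n x 2 matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}
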