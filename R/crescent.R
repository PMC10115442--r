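#' Cortical crescent metrics from a perimeter linescan
#'
#' Computes the four crescent scores from a background-subtracted linescan:
#'
#' 1. supra-threshold samples are those *strictly above* `threshold`,
#'    assessed circularly (runs may cross the 0/100 seam);
#' 2. **cortical coverage** is the extent, in perimeter percent, of the
#'    longest circularly contiguous supra-threshold run — `k` samples span
#'    `k - 1` unit intervals (a full-perimeter run spans 100);
#' 3. **integrated F.I.** (AUC) is the trapezoid sum over adjacent sample
#'    pairs inside that run of `(a_i + a_{i+1}) / 2`, with
#'    `a_i = intensity - threshold`;
#' 4. **maximum F.I.** is the highest value of the whole (subtracted)
#'    profile;
#' 5. **position** is the circular midpoint of the run.
#'
#' If the profile is not yet background subtracted its `background` is
#' subtracted first. Minor disjoint supra-threshold islands outside the
#' longest run are ignored for coverage/AUC/position but still count toward
#' the maximum. A single isolated supra-threshold sample spans zero unit
#' intervals and therefore yields coverage 0 (with the maximum still above
#' threshold).
#'
#' @param profile a [linescan_profile()].
#' @param threshold AU threshold discriminating signal from noise
#'   (default 20).
#' @return An object of class `crescent_metrics`: list with `max_fi`,
#'   `integrated_fi`, `coverage`, `position` (NA when coverage is 0),
#'   `threshold`, `cell_id`, `reporter_status`.
#' @export
compute_crescent_metrics <- function(profile, threshold = 20) {
  stopifnot(inherits(profile, "linescan_profile"))
  v <- profile$intensities
  if (any(!is.finite(v))) {
    stop(sprintf("non-finite intensities at sample indices: %s",
                 paste(which(!is.finite(v)), collapse = ", ")),
         call. = FALSE)
  }
  if (!profile$background_subtracted) {
    bg <- profile$background
    if (is.na(bg)) bg <- 0
    v <- v - bg
  }
  n <- length(v)
  spacing <- 100 / n

  supra <- v > threshold
  max_fi <- max(v)

  if (!any(supra)) {
    return(new_crescent_metrics(max_fi, 0, 0, NA_real_, threshold, profile))
  }
  if (all(supra)) {
    # full-perimeter signal: coverage spans all n intervals including the wrap
    a <- v - threshold
    auc <- sum((a + c(a[-1], a[1])) / 2) * 1  # unit interval = 1 sample step
    pos <- profile$positions[which.max(v)]
    return(new_crescent_metrics(max_fi, auc, 100, pos, threshold, profile))
  }

  run <- longest_circular_run(supra)
  k <- run$length
  coverage <- (k - 1) * spacing
  if (k < 2L) {
    return(new_crescent_metrics(max_fi, 0, 0, NA_real_, threshold, profile))
  }
  idx <- ((run$start - 1L + 0:(k - 1L)) %% n) + 1L
  a <- v[idx] - threshold
  auc <- sum((a[-k] + a[-1]) / 2)
  pos <- circ_mid_pct(profile$positions[run$start], coverage)
  new_crescent_metrics(max_fi, auc, coverage, pos, threshold, profile)
}

new_crescent_metrics <- function(max_fi, integrated_fi, coverage, position,
                                 threshold, profile) {
  structure(list(max_fi = max_fi, integrated_fi = integrated_fi,
                 coverage = coverage, position = position,
                 threshold = threshold,
                 cell_id = profile$cell_id,
                 reporter_status = profile$reporter_status),
            class = "crescent_metrics")
}

# Longest circularly contiguous run of TRUE. Assumes not all TRUE.
# Returns list(start = 1-based index, length).
longest_circular_run <- function(x) {
  n <- length(x)
  r <- rle(c(x, x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & starts <= n & r$lengths <= n
  if (!any(ok)) return(list(start = NA_integer_, length = 0L))
  best <- which(ok)[which.max(r$lengths[ok])]
  list(start = starts[best], length = min(r$lengths[best], n))
}

#' Classify the localization pattern of a cortical signal
#'
#' Rule: `absent` when coverage is 0; `unpolarized` when the signal spans
#' more than 60% of the perimeter; otherwise `apical` when the crescent
#' position falls in the apical half of the perimeter (position in
#' `(25, 75)`, apex at 50), else `basal_polarized`. The paper-style
#' three-way table collapses `basal_polarized` into `unpolarized`
#' (`collapse = TRUE`).
#'
#' @param metrics a `crescent_metrics`.
#' @param collapse collapse `basal_polarized` into `unpolarized`?
#' @return A character scalar.
#' @export
classify_localization <- function(metrics, collapse = FALSE) {
  stopifnot(inherits(metrics, "crescent_metrics"))
  if (metrics$coverage == 0) return("absent")
  if (is.na(metrics$position)) {
    stop("internal inconsistency: coverage > 0 but position undefined",
         call. = FALSE)
  }
  if (metrics$coverage > 60) return("unpolarized")
  if (metrics$position > 25 && metrics$position < 75) return("apical")
  if (collapse) "unpolarized" else "basal_polarized"
}

#' Estimate generative crescent parameters from measured metrics
#'
#' Inverts the crescent window shape: for the raised-cosine window with peak
#' amplitude `a` (estimated by the profile maximum), the supra-threshold
#' extent at threshold `t` is `W = (2C / pi) * acos(sqrt(t / a))` of the true
#' width `C`, so `C = pi * W / (2 * acos(sqrt(t / a)))`. The rectangular
#' window needs no correction. The crescent center estimate is the run
#' midpoint as reported.
#'
#' @param metrics a `crescent_metrics` computed on a background-subtracted
#'   profile.
#' @param window the generative window shape.
#' @return List with `center_position`, `coverage`, `amplitude`
#'   (all NA when no crescent was detected or the peak does not exceed the
#'   threshold).
#' @export
recover_crescent_params <- function(metrics,
                                    window = c("raised_cosine",
                                               "rectangular")) {
  stopifnot(inherits(metrics, "crescent_metrics"))
  window <- match.arg(window)
  a <- metrics$max_fi
  t <- metrics$threshold
  if (metrics$coverage <= 0 || a <= t) {
    return(list(center_position = NA_real_, coverage = NA_real_,
                amplitude = NA_real_))
  }
  coverage <- if (window == "rectangular") {
    metrics$coverage
  } else {
    min(pi * metrics$coverage / (2 * acos(sqrt(t / a))), 100)
  }
  list(center_position = metrics$position, coverage = coverage,
       amplitude = a)
}

#' Aggregate mean linescan profile with 95% confidence band
#'
#' Background-subtracts each profile (if not already) and returns the
#' per-position mean with a symmetric t-based 95% confidence interval.
#'
#' @param profiles list of [linescan_profile()] objects with a common number
#'   of samples.
#' @return data.frame `position, mean, ci_lo, ci_hi, n`; the interval is NA
#'   for a single profile and collapses to the mean when the per-position
#'   spread is zero.
#' @export
aggregate_mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "linescan_profile")))
  mat <- vapply(profiles, function(p) {
    v <- p$intensities
    if (!p$background_subtracted && !is.na(p$background)) v <- v - p$background
    v
  }, numeric(length(profiles[[1]]$intensities)))
  mat <- matrix(mat, ncol = length(profiles))
  n <- ncol(mat)
  mu <- rowMeans(mat)
  if (n == 1L) {
    half <- rep(NA_real_, nrow(mat))
  } else {
    se <- apply(mat, 1, stats::sd) / sqrt(n)
    half <- stats::qt(0.975, df = n - 1) * se
  }
  data.frame(position = profiles[[1]]$positions, mean = mu,
             ci_lo = mu - half, ci_hi = mu + half, n = n)
}

#' Threshold sensitivity of the group comparison
#'
#' Recomputes the crescent metrics of every cell at each candidate
#' threshold and compares the two groups with the two-sided Mann-Whitney
#' test, for both the integrated F.I. and the cortical coverage.
#'
#' @param profiles_a,profiles_b lists of [linescan_profile()] objects
#'   (e.g. control and knockdown cells).
#' @param thresholds numeric vector of AU thresholds to test.
#' @param metrics which per-cell scores to compare.
#' @return data.frame `threshold, metric, statistic, p, n_a, n_b`.
#' @export
threshold_sensitivity <- function(profiles_a, profiles_b,
                                  thresholds = c(10, 20, 30),
                                  metrics = c("integrated_fi", "coverage")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  for (th in thresholds) {
    ma <- lapply(profiles_a, compute_crescent_metrics, threshold = th)
    mb <- lapply(profiles_b, compute_crescent_metrics, threshold = th)
    for (m in metrics) {
      xa <- vapply(ma, `[[`, numeric(1), m)
      xb <- vapply(mb, `[[`, numeric(1), m)
      mw <- mann_whitney_test(xa, xb)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, metric = m, statistic = mw$statistic, p = mw$p,
        n_a = length(xa), n_b = length(xb))
    }
  }
  do.call(rbind, rows)
}
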