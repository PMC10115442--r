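#' Classify the telophase-correction trajectory of a division
#'
#' Maps a pair of angles (anaphase onset, +1 hr) to one of six exhaustive,
#' mutually exclusive categories from the two orientation bins: obliques
#' that move to the planar bin are `corrected_to_planar`, to the
#' perpendicular bin `corrected_to_perpendicular`, or `remained_oblique`;
#' non-oblique cells that keep their bin are `stable_planar` /
#' `stable_perpendicular`, and those that leave it are `destabilized`
#' (destination bin reported in `to_bin`).
#'
#' @param angle_t0,angle_t60 numeric vectors of degrees in `[0, 90]`
#'   (recycled to a common length).
#' @return data.frame `angle_t0, angle_t60, t0_bin, t60_bin, category`.
#' @export
classify_trajectory <- function(angle_t0, angle_t60) {
  k <- max(length(angle_t0), length(angle_t60))
  angle_t0 <- rep_len(angle_t0, k); angle_t60 <- rep_len(angle_t60, k)
  b0 <- as.character(bin_angle(angle_t0))
  b1 <- as.character(bin_angle(angle_t60))
  category <- ifelse(
    b0 == "oblique",
    ifelse(b1 == "planar", "corrected_to_planar",
           ifelse(b1 == "perpendicular", "corrected_to_perpendicular",
                  "remained_oblique")),
    ifelse(b0 == b1,
           ifelse(b0 == "planar", "stable_planar", "stable_perpendicular"),
           "destabilized"))
  data.frame(angle_t0 = angle_t0, angle_t60 = angle_t60,
             t0_bin = b0, t60_bin = b1, category = category,
             stringsAsFactors = FALSE)
}

#' Genotype-by-correction-direction contingency table
#'
#' Tabulates, per genotype, how anaphase-onset obliques resolved: counts of
#' planar- vs perpendicular-corrected cells. Obliques that remained oblique
#' are excluded from the table (as rare) and reported separately;
#' non-oblique cells never enter.
#'
#' @param pairs data.frame with columns `genotype`, `angle_t0`, `angle_t60`.
#' @return List with `counts` (genotype x `corrected_to_planar` /
#'   `corrected_to_perpendicular` matrix), `remained_oblique` (named counts
#'   per genotype) and `n_oblique` (all t0 obliques per genotype). Warns if
#'   the input contains no oblique divisions.
#' @export
correction_table <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("genotype", "angle_t0", "angle_t60") %in% names(pairs)))
  traj <- classify_trajectory(pairs$angle_t0, pairs$angle_t60)
  traj$genotype <- pairs$genotype
  obl <- traj$t0_bin == "oblique"
  genos <- unique(pairs$genotype)
  if (!any(obl)) {
    warning("no oblique divisions at anaphase onset; correction table is empty")
  }
  corr <- traj[obl & traj$category != "remained_oblique", , drop = FALSE]
  counts <- matrix(0L, nrow = length(genos), ncol = 2L,
                   dimnames = list(genos, c("corrected_to_planar",
                                            "corrected_to_perpendicular")))
  if (nrow(corr) > 0) {
    tab <- table(factor(corr$genotype, levels = genos),
                 factor(corr$category,
                        levels = c("corrected_to_planar",
                                   "corrected_to_perpendicular")))
    counts[] <- as.integer(tab)
  }
  remained <- vapply(genos, function(g) {
    sum(obl & traj$genotype == g & traj$category == "remained_oblique")
  }, integer(1))
  n_oblique <- vapply(genos, function(g) sum(obl & traj$genotype == g),
                      integer(1))
  list(counts = counts, remained_oblique = remained, n_oblique = n_oblique)
}
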