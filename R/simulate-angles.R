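#' Parameters for the paired division-angle simulator
#'
#' Encodes the generative model of telophase correction: cells enter anaphase
#' in one of the three orientation bins according to mixture weights, with the
#' angle uniform within the bin; over the following hour non-oblique angles
#' persist with truncated-Gaussian jitter while oblique angles either remain
#' oblique or correct to perpendicular/planar by a Bernoulli choice.
#'
#' @param n number of cells (> 0).
#' @param w_planar,w_oblique,w_perp anaphase-onset mixture weights over the
#'   planar `[0,30)`, oblique `[30,60)` and perpendicular `[60,90]` bins;
#'   must sum to 1 within 1e-9.
#' @param p_perp_given_oblique probability that a *correcting* oblique moves
#'   to perpendicular (else planar).
#' @param p_stay_oblique probability that an oblique remains oblique at
#'   +1 hr ("rare" in wild type; default 0.05).
#' @param jitter_sd degrees; sd of the angle jitter applied to non-oblique
#'   cells between the two timepoints (clipped to `[0, 90]`).
#' @param seed integer seed.
#' @return An object of class `angle_sim_params`.
#' @export
angle_sim_params <- function(n, w_planar = 1 / 3, w_oblique = 1 / 3,
                             w_perp = 1 / 3, p_perp_given_oblique = 0.5,
                             p_stay_oblique = 0.05, jitter_sd = 5,
                             seed = NULL) {
  stop_if_not_scalar_number(n, "n", lo = 1)
  for (nm in c("w_planar", "w_oblique", "w_perp")) {
    stop_if_not_scalar_number(get(nm), nm, 0, 1)
  }
  if (abs(w_planar + w_oblique + w_perp - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  stop_if_not_scalar_number(p_perp_given_oblique, "p_perp_given_oblique", 0, 1)
  stop_if_not_scalar_number(p_stay_oblique, "p_stay_oblique", 0, 1)
  stop_if_not_scalar_number(jitter_sd, "jitter_sd", lo = 0)
  structure(list(n = as.integer(n), w_planar = w_planar,
                 w_oblique = w_oblique, w_perp = w_perp,
                 p_perp_given_oblique = p_perp_given_oblique,
                 p_stay_oblique = p_stay_oblique, jitter_sd = jitter_sd,
                 seed = seed),
            class = "angle_sim_params")
}

#' Genotype presets for the angle simulator
#'
#' Convenience parameterizations, not claims: `WT` enters anaphase uniformly
#' across bins and corrects obliques in either direction with equal
#' probability; `AGS3_KO` biases oblique correction toward perpendicular;
#' `LGN_KO` is planar-biased at anaphase onset and corrects obliques almost
#' exclusively to planar.
#'
#' @param genotype one of `"WT"`, `"AGS3_KO"`, `"LGN_KO"`.
#' @param n number of cells.
#' @param seed integer seed.
#' @param ... overrides passed to [angle_sim_params()].
#' @return An `angle_sim_params`.
#' @export
genotype_preset <- function(genotype = c("WT", "AGS3_KO", "LGN_KO"),
                            n = 100, seed = NULL, ...) {
  genotype <- match.arg(genotype)
  base <- switch(genotype,
    WT = list(w_planar = 1 / 3, w_oblique = 1 / 3, w_perp = 1 / 3,
              p_perp_given_oblique = 0.5),
    AGS3_KO = list(w_planar = 1 / 3, w_oblique = 1 / 3, w_perp = 1 / 3,
                   p_perp_given_oblique = 0.72),
    LGN_KO = list(w_planar = 0.67, w_oblique = 0.20, w_perp = 0.13,
                  p_perp_given_oblique = 0.14))
  args <- utils::modifyList(c(list(n = n, seed = seed), base), list(...))
  do.call(angle_sim_params, args)
}

#' Simulate paired anaphase-onset / +1 hr division angles
#'
#' @param params an [angle_sim_params()].
#' @param genotype_label label stored in the output table.
#' @return A list with `angles` — a data.frame
#'   `cell_id, genotype, angle_t0, angle_t60` (degrees in `[0, 90]`) — and
#'   `truth`, a `synthetic_truth` whose `labels` data.frame records each
#'   cell's true anaphase-onset bin and oblique outcome
#'   (`"to_planar"`, `"to_perpendicular"`, `"stayed_oblique"`, or
#'   `"non_oblique"`).
#' @export
simulate_division_angles <- function(params, genotype_label = "WT") {
  stopifnot(inherits(params, "angle_sim_params"))
  n <- params$n
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  bins <- c("planar", "oblique", "perpendicular")
  lo <- c(planar = 0, oblique = 30, perpendicular = 60)
  hi <- c(planar = 30, oblique = 60, perpendicular = 90)

  out <- with_seed_or_not(params$seed, {
    bin_t0 <- sample(bins, n, replace = TRUE,
                     prob = c(params$w_planar, params$w_oblique,
                              params$w_perp))
    angle_t0 <- stats::runif(n, lo[bin_t0], hi[bin_t0])

    angle_t60 <- numeric(n)
    outcome <- rep("non_oblique", n)
    obl <- bin_t0 == "oblique"

    # non-oblique: persist with clipped Gaussian jitter
    angle_t60[!obl] <- pmin(pmax(
      angle_t0[!obl] + stats::rnorm(sum(!obl), 0, params$jitter_sd), 0), 90)

    if (any(obl)) {
      n_o <- sum(obl)
      stay <- stats::runif(n_o) < params$p_stay_oblique
      to_perp <- stats::runif(n_o) < params$p_perp_given_oblique
      t60_o <- ifelse(stay, stats::runif(n_o, 30, 60),
                      ifelse(to_perp, stats::runif(n_o, 60, 90),
                             stats::runif(n_o, 0, 30)))
      angle_t60[obl] <- t60_o
      outcome[obl] <- ifelse(stay, "stayed_oblique",
                             ifelse(to_perp, "to_perpendicular", "to_planar"))
    }
    list(bin_t0 = bin_t0, angle_t0 = angle_t0, angle_t60 = angle_t60,
         outcome = outcome)
  })

  angles <- data.frame(
    cell_id = sprintf("%s_cell_%04d", genotype_label, seq_len(n)),
    genotype = genotype_label,
    angle_t0 = out$angle_t0,
    angle_t60 = out$angle_t60,
    stringsAsFactors = FALSE)
  truth <- synthetic_truth(
    id = paste0("angles_", genotype_label), params = params,
    labels = data.frame(cell_id = angles$cell_id,
                        true_bin_t0 = out$bin_t0,
                        true_outcome = out$outcome,
                        stringsAsFactors = FALSE))
  list(angles = angles, truth = truth)
}
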