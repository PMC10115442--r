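#' Parameters for the clone simulator
#'
#' @param n number of clones.
#' @param p_scd,p_acd,p_delam probabilities of symmetric division, asymmetric
#'   division and delamination clones; must sum to 1 within 1e-9.
#' @param seed integer seed.
#' @return An object of class `clone_sim_params`.
#' @export
clone_sim_params <- function(n, p_scd = 1 / 3, p_acd = 1 / 3,
                             p_delam = 1 / 3, seed = NULL) {
  stop_if_not_scalar_number(n, "n", lo = 1)
  for (nm in c("p_scd", "p_acd", "p_delam")) {
    stop_if_not_scalar_number(get(nm), nm, 0, 1)
  }
  if (abs(p_scd + p_acd + p_delam - 1) > 1e-9) {
    stop("clone class probabilities must sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), p_scd = p_scd, p_acd = p_acd,
                 p_delam = p_delam, seed = seed),
            class = "clone_sim_params")
}

#' Simulate two-cell mitotic lineage-tracing clones
#'
#' Symmetric-division clones have two basal cells, asymmetric-division clones
#' one basal and one suprabasal cell, and delamination clones a single
#' suprabasal cell flagged as lying in the first spinous layer.
#'
#' @param params a [clone_sim_params()].
#' @param genotype_label label stored in the output table.
#' @return A list with `clones` — a data.frame `clone_id, embryo_id,
#'   genotype, n_basal, n_suprabasal, first_spinous` — and `truth`, a
#'   `synthetic_truth` with the per-clone true class.
#' @export
simulate_clones <- function(params, genotype_label = "WT") {
  stopifnot(inherits(params, "clone_sim_params"))
  n <- params$n
  cls <- with_seed_or_not(params$seed,
    sample(c("SCD", "ACD", "delamination"), n, replace = TRUE,
           prob = c(params$p_scd, params$p_acd, params$p_delam)))
  clones <- data.frame(
    clone_id = sprintf("%s_clone_%05d", genotype_label, seq_len(n)),
    embryo_id = sprintf("embryo_%d", 1L + (seq_len(n) - 1L) %% 4L),
    genotype = genotype_label,
    n_basal = ifelse(cls == "SCD", 2L, ifelse(cls == "ACD", 1L, 0L)),
    n_suprabasal = ifelse(cls == "SCD", 0L, 1L),
    first_spinous = cls == "delamination",
    stringsAsFactors = FALSE)
  truth <- synthetic_truth(
    id = paste0("clones_", genotype_label), params = params,
    labels = data.frame(clone_id = clones$clone_id, true_class = cls,
                        stringsAsFactors = FALSE))
  list(clones = clones, truth = truth)
}
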