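# Clone fate classification, proportions, thickness.

test_that("the two-cell rubric classifies and excludes as stated", {
  out <- classify_clone(c(2, 1, 0, 0, 1, 3),
                        c(0, 1, 1, 1, 0, 1),
                        c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(out$fate_class,
                   c("SCD", "ACD", "delamination", "excluded", "excluded",
                     "excluded"))
  expect_match(out$exclusion_reason[4], "above first spinous")
  expect_match(out$exclusion_reason[6], "larger than two cells")
  expect_error(classify_clone(-1, 1), "nonnegative")
  expect_error(classify_clone(0, 0), "at least one cell")
})

test_that("counts reconcile: classified + excluded = input", {
  withr::with_seed(81, {
    n <- 500
    nb <- sample(0:3, n, replace = TRUE)
    ns <- sample(0:2, n, replace = TRUE)
    keep <- nb + ns >= 1
    out <- classify_clone(nb[keep], ns[keep], sample(c(TRUE, FALSE),
                                                    sum(keep), TRUE))
    expect_equal(sum(out$fate_class != "excluded") +
                   sum(out$fate_class == "excluded"), sum(keep))
    expect_true(all(!is.na(out$exclusion_reason[out$fate_class ==
                                                  "excluded"])))
  })
})

test_that("fate proportions recover simulator parameters", {
  s <- simulate_clones(clone_sim_params(10000, 0.2, 0.5, 0.3, seed = 82))
  fp <- fate_proportions(s$clones)
  expect_equal(fp$n_excluded, 0)
  ci_scd <- binom_ci99(0.2 / 0.7, fp$n_scd + fp$n_acd)
  expect_gte(fp$scd_frac_div, ci_scd[1])
  expect_lte(fp$scd_frac_div, ci_scd[2])
  expect_equal(fp$scd_frac_div + fp$acd_frac_div, 1)
  expect_equal(fp$acd_frac_diff + fp$delam_frac_diff, 1)
  # all-SCD input
  all_scd <- data.frame(genotype = "g", n_basal = 2, n_suprabasal = 0,
                        first_spinous = FALSE)[rep(1, 10), ]
  expect_equal(fate_proportions(all_scd)$scd_frac_div, 1)
  # order invariance
  shuf <- s$clones[sample(nrow(s$clones)), ]
  expect_equal(fate_proportions(shuf), fp)
})

test_that("thickness recovers a constructed band and degenerate cases", {
  tis <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.5,
                               noise_sd = 0)
  tm <- measure_thickness(tis$k10_channel, tis$basement_polyline,
                          threshold = 50, pixel_size = 0.5)
  expect_lt(abs(tm$thickness - 20), 0.25)  # half a pixel
  # Otsu on a noisy image
  tisn <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.5,
                                noise_sd = 10, seed = 83)
  tmn <- measure_thickness(tisn$k10_channel, tisn$basement_polyline,
                           threshold = "otsu", pixel_size = 0.5)
  expect_lt(abs(tmn$thickness - 20), 1)
  # zero signal
  tis0 <- generate_tissue_image(suprabasal_height = 0, noise_sd = 0)
  tm0 <- measure_thickness(tis0$k10_channel, tis0$basement_polyline,
                           threshold = 50, pixel_size = 0.5)
  expect_equal(tm0$thickness, 0)
  expect_error(measure_thickness(tis$k10_channel, tis$basement_polyline[1, ,
                                                                        drop = FALSE]),
               "at least 2 points")
})

test_that("wavy basement membrane: thickness = area / arc length within 2%", {
  tis <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.5,
                               wave_amplitude = 8, wave_period = 40,
                               noise_sd = 0)
  tm <- measure_thickness(tis$k10_channel, tis$basement_polyline,
                          threshold = 50, pixel_size = 0.5)
  expect_lt(abs(tm$thickness - tis$truth$labels$thickness_um) /
              tis$truth$labels$thickness_um, 0.02)
  # the wavy membrane is longer than the section, so thickness < painted height
  expect_lt(tm$thickness, 20)
})

test_that("thickness is invariant to translation and zero-signal margins", {
  tis <- generate_tissue_image(suprabasal_height = 16, pixel_size = 0.5,
                               noise_sd = 0)
  tm <- measure_thickness(tis$k10_channel, tis$basement_polyline,
                          threshold = 50, pixel_size = 0.5)
  pad <- matrix(0, 10, ncol(tis$k10_channel))
  padded <- rbind(pad, tis$k10_channel)
  poly2 <- tis$basement_polyline
  poly2[, 2] <- poly2[, 2] + 10
  tm2 <- measure_thickness(padded, poly2, threshold = 50, pixel_size = 0.5)
  expect_equal(tm2$thickness, tm$thickness)
})

test_that("doubling the resolution leaves thickness within 1%", {
  t1 <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.5,
                              wave_amplitude = 6, noise_sd = 0)
  t2 <- generate_tissue_image(suprabasal_height = 20, pixel_size = 0.25,
                              wave_amplitude = 6, noise_sd = 0)
  m1 <- measure_thickness(t1$k10_channel, t1$basement_polyline,
                          threshold = 50, pixel_size = 0.5)
  m2 <- measure_thickness(t2$k10_channel, t2$basement_polyline,
                          threshold = 50, pixel_size = 0.25)
  expect_lt(abs(m1$thickness - m2$thickness) / m2$thickness, 0.01)
})
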