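# Synthetic-data generator: construction values, determinism, convergence.

test_that("degenerate crescents render as flat background", {
  geom <- make_round_cell(radius = 20, image_shape = c(64, 64))
  cell <- generate_cell_image(geom, crescent_truth(50, 30, 0, 10, 0),
                              seed = 1)
  ls <- sample_linescan(cell$image, cell$contour, cell$boundary_mask)
  expect_equal(ls$intensities, rep(10, 100))

  # coverage 0 suppresses the crescent regardless of amplitude
  cell0 <- generate_cell_image(geom, crescent_truth(50, 0, 80, 10, 0),
                               seed = 1)
  expect_equal(max(cell0$image), 10)
})

test_that("crescent peak sits at its stated position and amplitude", {
  geom <- make_round_cell()
  cell <- generate_cell_image(geom, crescent_truth(50, 20, 50, 10, 0),
                              seed = 1)
  # pixel centers quantize the perimeter position, so the peak is hit to
  # within the discretization
  expect_equal(max(cell$image), 60, tolerance = 1e-4)
  # the brightest pixels map to perimeter position ~50 (the apex)
  bright <- which(cell$image > 59.9, arr.ind = TRUE)
  near <- contour_nearest(cell$contour,
                          cbind(bright[, 2], bright[, 1]))
  expect_true(all(circ_dist_pct(near$s, 50) < 3))
})

test_that("identical seeds give bit-identical images, angles and clones", {
  geom <- make_round_cell(radius = 15, image_shape = c(48, 48))
  tr <- crescent_truth(30, 25, 40, 12, 6)
  expect_identical(generate_cell_image(geom, tr, seed = 42)$image,
                   generate_cell_image(geom, tr, seed = 42)$image)
  p <- angle_sim_params(500, seed = 9)
  expect_identical(simulate_division_angles(p), simulate_division_angles(p))
  cp <- clone_sim_params(500, 0.3, 0.3, 0.4, seed = 9)
  expect_identical(simulate_clones(cp), simulate_clones(cp))
})

test_that("geometry outside the image bounds is rejected naming the vertex", {
  expect_error(
    cell_geometry(rbind(c(5, 5), c(70, 5), c(40, 40)),
                  rbind(c(1, 45), c(64, 45)), image_shape = c(48, 64)),
    "vertex 2")
})

test_that("forced oblique correction sends every oblique to [60, 90]", {
  p <- angle_sim_params(2000, p_perp_given_oblique = 1, p_stay_oblique = 0,
                        seed = 2)
  s <- simulate_division_angles(p)
  obl <- s$truth$labels$true_bin_t0 == "oblique"
  expect_gt(sum(obl), 0)
  expect_true(all(s$angles$angle_t60[obl] >= 60 &
                    s$angles$angle_t60[obl] <= 90))
})

test_that("t=0 bin fractions converge to the mixture weights", {
  p <- angle_sim_params(30000, 1 / 3, 1 / 3, 1 / 3, seed = 7)
  s <- simulate_division_angles(p)
  frac <- table(bin_angle(s$angles$angle_t0)) / 30000
  expect_true(all(abs(frac - 1 / 3) < 0.01))
  # angles bounded
  expect_true(all(s$angles$angle_t0 >= 0 & s$angles$angle_t0 <= 90))
  expect_true(all(s$angles$angle_t60 >= 0 & s$angles$angle_t60 <= 90))
})

test_that("oblique correction direction converges to p_perp_given_oblique", {
  p <- angle_sim_params(20000, p_perp_given_oblique = 0.5,
                        p_stay_oblique = 0, seed = 12)
  s <- simulate_division_angles(p)
  out <- s$truth$labels$true_outcome
  corrected <- out %in% c("to_planar", "to_perpendicular")
  frac <- sum(out == "to_perpendicular") / sum(corrected)
  expect_lt(abs(frac - 0.5), 0.01)
})

test_that("clone compositions follow the rubric and class frequencies converge", {
  cp <- clone_sim_params(10000, p_scd = 0.105, p_acd = 0.79, p_delam = 0.105,
                         seed = 3)
  s <- simulate_clones(cp)
  cl <- s$clones
  tru <- s$truth$labels$true_class
  expect_true(all(cl$n_basal[tru == "SCD"] == 2 &
                    cl$n_suprabasal[tru == "SCD"] == 0))
  expect_true(all(cl$n_basal[tru == "ACD"] == 1 &
                    cl$n_suprabasal[tru == "ACD"] == 1))
  expect_true(all(cl$first_spinous[tru == "delamination"]))
  expect_lt(abs(mean(tru == "ACD") - 0.79), 0.01)
  ci <- binom_ci99(0.79, 10000)
  expect_gte(mean(tru == "ACD"), ci[1])
  expect_lte(mean(tru == "ACD"), ci[2])
})

test_that("invalid simulator parameters are rejected", {
  expect_error(angle_sim_params(0), "n")
  expect_error(angle_sim_params(10, 0.5, 0.5, 0.5), "sum to 1")
  expect_error(clone_sim_params(10, 0.5, 0.2, 0.2), "sum to 1")
  expect_error(simulate_division_angles(
    structure(list(n = -5), class = "angle_sim_params")))
})

test_that("tissue bands have the stated geometry", {
  tis <- generate_tissue_image(basal_height = 10, suprabasal_height = 20,
                               length = 100, pixel_size = 0.5, noise_sd = 0)
  # painted K10 area / membrane length equals the stated height
  expect_equal(tis$truth$labels$thickness_um, 20, tolerance = 0.25)
  tis0 <- generate_tissue_image(suprabasal_height = 0, noise_sd = 0)
  expect_equal(sum(tis0$k10_channel > 0), 0)
})

test_that("truth records round-trip through JSON", {
  tr <- crescent_truth(33.5, 22, 41, 12, 3.5)
  cell <- generate_cell_image(make_round_cell(radius = 12,
                                              image_shape = c(40, 40)),
                              tr, seed = 5)
  js <- jsonlite::toJSON(unclass(cell$truth$params), auto_unbox = TRUE,
                         digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_identical(do.call(crescent_truth, back), tr)
})
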