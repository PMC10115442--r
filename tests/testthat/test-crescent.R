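# Crescent metrics: pinned cases, equivariance, monotonicity, oracle match.

test_that("sub-threshold profiles yield empty metrics", {
  p <- linescan_profile(rep(5, 100), background = 0,
                        background_subtracted = TRUE)
  m <- compute_crescent_metrics(p, 20)
  expect_equal(m$coverage, 0)
  expect_equal(m$integrated_fi, 0)
  expect_true(is.na(m$position))
  expect_identical(classify_localization(m), "absent")
})

test_that("rectangular pulse: coverage 20, max 50, position 50, AUC 600", {
  v <- rep(0, 100)
  v[41:61] <- 50  # positions 40..60 inclusive
  m <- compute_crescent_metrics(
    linescan_profile(v, background = 0, background_subtracted = TRUE), 20)
  expect_equal(m$coverage, 20)
  expect_equal(m$max_fi, 50)
  expect_equal(m$position, 50)
  expect_equal(m$integrated_fi, 600)
})

test_that("circular shift moves position and preserves the other metrics", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      p <- random_profile()
      m0 <- compute_crescent_metrics(p, 20)
      k <- sample(99, 1)
      v <- p$intensities
      shifted <- linescan_profile(c(v[(100 - k + 1):100], v[1:(100 - k)]),
                                  background = 0,
                                  background_subtracted = TRUE)
      m1 <- compute_crescent_metrics(shifted, 20)
      expect_equal(m1$coverage, m0$coverage)
      expect_equal(m1$max_fi, m0$max_fi)
      expect_equal(m1$integrated_fi, m0$integrated_fi)
      if (!is.na(m0$position)) {
        expect_lt(circ_dist_pct(m1$position, (m0$position + k) %% 100), 1e-9)
      }
    }
  })
})

test_that("metrics match the brute-force oracle on random profiles", {
  withr::with_seed(22, {
    for (rep in 1:200) {
      p <- random_profile()
      th <- runif(1, 5, 40)
      m <- compute_crescent_metrics(p, th)
      o <- oracle_crescent(p$intensities, th)
      expect_equal(m$coverage, o$coverage)
      expect_equal(m$integrated_fi, o$auc, tolerance = 1e-9)
      if (!is.na(o$position)) expect_equal(m$position, o$position)
      # one-way invariant: a positive coverage needs a supra-threshold max
      if (m$coverage > 0) expect_gt(m$max_fi, th)
    }
  })
})

test_that("raising the threshold never increases coverage, nor AUC for a
           single crescent", {
  withr::with_seed(23, {
    # coverage is monotone for arbitrary multi-blob profiles: every
    # supra-threshold run at the higher threshold is nested in one at the
    # lower
    for (rep in 1:50) {
      p <- random_profile()
      th <- sort(runif(4, 0, 60))
      cov <- vapply(th, function(t)
        compute_crescent_metrics(p, t)$coverage, numeric(1))
      expect_true(all(diff(cov) <= 1e-9))
    }
    # AUC monotonicity holds once the threshold separates signal from
    # noise (its purpose): the identified run then cannot switch to a
    # noise blob, so both the run and every threshold-subtracted ordinate
    # shrink as the threshold rises
    for (rep in 1:50) {
      v <- runif(100, 0, 10)
      start <- sample(100, 1); len <- sample(10:40, 1)
      idx <- ((start - 1 + 0:(len - 1)) %% 100) + 1
      v[idx] <- v[idx] + runif(1, 30, 80) *
        0.5 * (1 + cos(seq(-pi, pi, length.out = len)))
      p <- linescan_profile(v, background = 0, background_subtracted = TRUE)
      th <- sort(runif(4, 12, 60))
      ms <- lapply(th, function(t) compute_crescent_metrics(p, t))
      expect_true(all(diff(vapply(ms, `[[`, numeric(1),
                                  "coverage")) <= 1e-9))
      expect_true(all(diff(vapply(ms, `[[`, numeric(1),
                                  "integrated_fi")) <= 1e-9))
    }
  })
})

test_that("wrap-around runs crossing the 0/100 seam are handled", {
  v <- rep(0, 100)
  v[c(96:100, 1:6)] <- 50  # basal crescent across the seam
  m <- compute_crescent_metrics(
    linescan_profile(v, background = 0, background_subtracted = TRUE), 20)
  expect_equal(m$coverage, 10)
  expect_equal(m$position, 0)  # midpoint of 95..105 mod 100
})

test_that("unsubtracted profiles are background-subtracted first", {
  v <- rep(12, 100); v[40:50] <- 72
  p_raw <- linescan_profile(v, background = 12, background_subtracted = FALSE)
  p_sub <- linescan_profile(v - 12, background = 12,
                            background_subtracted = TRUE)
  expect_equal(compute_crescent_metrics(p_raw, 20)$integrated_fi,
               compute_crescent_metrics(p_sub, 20)$integrated_fi)
})

test_that("localization classification follows the stated rule", {
  mk <- function(coverage, position) {
    structure(list(max_fi = 50, integrated_fi = 100, coverage = coverage,
                   position = position, threshold = 20,
                   cell_id = NA, reporter_status = NA),
              class = "crescent_metrics")
  }
  expect_identical(classify_localization(mk(0, NA)), "absent")
  expect_identical(classify_localization(mk(30, 50)), "apical")
  expect_identical(classify_localization(mk(70, 50)), "unpolarized")
  expect_identical(classify_localization(mk(30, 10)), "basal_polarized")
  expect_identical(classify_localization(mk(30, 10), collapse = TRUE),
                   "unpolarized")
  expect_error(classify_localization(mk(30, NA)), "inconsistency")
})

test_that("non-finite intensities are reported with their indices", {
  v <- rep(0, 100); v[c(4, 9)] <- NA
  p <- linescan_profile(v, background = 0, background_subtracted = TRUE)
  expect_error(compute_crescent_metrics(p), "4, 9")
})

test_that("aggregate profile: mean, degenerate CI, and coverage of truth", {
  p1 <- linescan_profile(rep(5, 100), background = 0,
                         background_subtracted = TRUE)
  agg1 <- aggregate_mean_profile(list(p1))
  expect_equal(agg1$mean, rep(5, 100))
  expect_true(all(is.na(agg1$ci_lo)))
  aggc <- aggregate_mean_profile(list(p1, p1, p1))
  expect_equal(aggc$ci_lo, aggc$mean)

  # t-interval covers the true curve at >= 94% of positions
  truth_curve <- 30 * exp(-((0:99 - 50) / 12)^2)
  profiles <- withr::with_seed(31, {
    lapply(1:1000, function(i) {
      linescan_profile(truth_curve + rnorm(100, 0, 8), background = 0,
                       background_subtracted = TRUE)
    })
  })
  agg <- aggregate_mean_profile(profiles)
  inside <- agg$ci_lo <= truth_curve & truth_curve <= agg$ci_hi
  expect_gte(mean(inside), 0.94)
})

test_that("threshold sensitivity recomputes the comparison per threshold", {
  withr::with_seed(32, {
    mk_group <- function(shift) {
      lapply(1:8, function(i) {
        v <- rep(0, 100)
        v[40:60] <- 40 + shift + rnorm(1, 0, 2)
        linescan_profile(v, background = 0, background_subtracted = TRUE)
      })
    }
    tab <- threshold_sensitivity(mk_group(0), mk_group(25),
                                 thresholds = c(10, 20, 30))
    expect_setequal(unique(tab$threshold), c(10, 20, 30))
    expect_true(all(tab$p >= 0 & tab$p <= 1))
    # clearly separated groups: small p at every threshold for the AUC metric
    expect_true(all(tab$p[tab$metric == "integrated_fi"] < 0.05))
  })
  # identical groups -> p = 1 in exact mode
  g <- lapply(1:5, function(i) {
    v <- rep(0, 100); v[40:50] <- 30 + i
    linescan_profile(v, background = 0, background_subtracted = TRUE)
  })
  tab_eq <- threshold_sensitivity(g, g, thresholds = 20,
                                  metrics = "integrated_fi")
  expect_equal(tab_eq$p, 1)
})
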