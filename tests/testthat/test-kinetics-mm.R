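test_that("initial rates recover linear slopes and flat curves", {
  t <- seq(0, 300, 20)
  curve <- tibble::tibble(time = t, signal = 0.01 + 0.002 * t)
  expect_equal(estimate_initial_rate(curve, calibration = 0.5), 0.004,
               tolerance = 1e-12)
  flat <- tibble::tibble(time = t, signal = rep(0.3, length(t)))
  expect_equal(estimate_initial_rate(flat, calibration = 1), 0)
  expect_error(estimate_initial_rate(curve[1:3, ], 1), "4 points")
})

test_that("initial rate from an integrated progress curve matches kcat*E at saturation", {
  # [S] = 100 * KM: v0 should be within 2% of kcat * E
  curve <- simulate_progress_curve(s0 = 1530, kcat = 48, KM = 15.3,
                                   enzyme_nM = 60,
                                   times = seq(0, 300, 10))
  v <- estimate_initial_rate(curve, calibration = 1, substrate_uM = 1530)
  expect_equal(v, 48 * 0.06, tolerance = 0.02)
})

test_that("noiseless Michaelis-Menten data are recovered to machine accuracy", {
  s <- c(2, 5, 10, 20, 50, 100, 200)
  v <- 48.0 * 0.06 * s / (15.3 + s)
  fit <- fit_michaelis_menten(tibble::tibble(substrate_uM = s, rate = v),
                              enzyme_nM = 60)
  expect_equal(fit$kcat, 48.0, tolerance = 1e-6)
  expect_equal(fit$KM, 15.3, tolerance = 1e-6)
  expect_equal(fit$efficiency, 48.0 / 15.3e-6, tolerance = 1e-6)
  expect_false(fit$flagged)
  # v = Vmax/2 at [S] = KM, by definition of the fitted curve
  v_at_km <- fit$kcat * fit$enzyme_active_uM * fit$KM / (fit$KM + fit$KM)
  expect_equal(v_at_km, fit$kcat * fit$enzyme_active_uM / 2,
               tolerance = 1e-12)
})

test_that("the efficiency identity and tidy/glance accessors hold", {
  d <- simulate_mm_rates(seed = 8)
  fit <- fit_michaelis_menten(d, enzyme_nM = 60)
  expect_equal(fit$efficiency, fit$kcat / (fit$KM * 1e-6),
               tolerance = 1e-9)
  td <- tidy(fit)
  expect_setequal(td$term, c("kcat", "KM", "efficiency"))
  expect_true(all(td$std.error > 0))
  expect_equal(glance(fit)$kcat, fit$kcat)
})

test_that("the nonlinear fit attains the 200x200 log-grid-search optimum", {
  d <- simulate_mm_rates(kcat = 48, KM = 15.3, noise_cv = 0.05, seed = 13)
  fit <- fit_michaelis_menten(d, enzyme_nM = 60)
  e_uM <- 0.06
  rss <- function(kcat, km) {
    sum((d$rate - kcat * e_uM * d$substrate_uM / (km + d$substrate_uM))^2)
  }
  kcat_grid <- exp(seq(log(24), log(96), length.out = 200))
  km_grid <- exp(seq(log(7.65), log(30.6), length.out = 200))
  grid_rss <- outer(kcat_grid, km_grid, Vectorize(rss))
  best <- arrayInd(which.min(grid_rss), dim(grid_rss))
  # the analytic fit is at least as good as the exhaustive grid optimum
  expect_lte(rss(fit$kcat, fit$KM), min(grid_rss) * (1 + 1e-9))
  # and the grid argmin agrees with the fit to within one log-step (<1%)
  expect_equal(fit$kcat, kcat_grid[best[1]], tolerance = 0.01)
  expect_equal(fit$KM, km_grid[best[2]], tolerance = 0.01)
})

test_that("degenerate designs are rejected", {
  expect_error(
    fit_michaelis_menten(tibble::tibble(substrate_uM = c(1, 2, 3, 4),
                                        rate = 1:4), enzyme_nM = 60),
    "5 distinct"
  )
})
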