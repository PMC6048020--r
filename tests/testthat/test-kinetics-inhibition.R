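test_that("the Eadie-Hofstee transform linearizes noiseless kinetics", {
  s <- c(2, 5, 10, 20, 50, 100)
  vmax <- 2.88; km <- 15.3
  d <- tibble::tibble(substrate_uM = s, rate = vmax * s / (km + s))
  eh <- eadie_hofstee(d)
  fit <- lm(v ~ v_over_s, data = eh)
  expect_equal(unname(coef(fit)[2]), -km, tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1]), vmax, tolerance = 1e-9)
})

test_that("noncompetitive truth yields parallel Eadie-Hofstee lines", {
  s <- c(2, 5, 10, 20, 50, 100)
  km <- 15.3; vmax <- 2.88; ki <- 3.6
  panel <- tidyr::expand_grid(substrate_uM = s,
                              inhibitor_uM = c(0, 2, 5, 15))
  panel$rate <- (vmax / (1 + panel$inhibitor_uM / ki)) *
    panel$substrate_uM / (km + panel$substrate_uM)
  eh <- eadie_hofstee(panel)
  slopes <- vapply(split(eh, eh$inhibitor_uM), function(g) {
    unname(coef(lm(v ~ v_over_s, data = g))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - (-km)) < 1e-9))
  # competitive truth shares the Vmax intercept instead
  panel$rate <- vmax * panel$substrate_uM /
    (km * (1 + panel$inhibitor_uM / ki) + panel$substrate_uM)
  eh2 <- eadie_hofstee(panel)
  intercepts <- vapply(split(eh2, eh2$inhibitor_uM), function(g) {
    unname(coef(lm(v ~ v_over_s, data = g))[1])
  }, numeric(1))
  expect_true(all(abs(intercepts - vmax) < 1e-9))
})

test_that("simulated mechanisms are identified with the published Ki scale", {
  pan_nc <- simulate_inhibition_panel("noncompetitive", Ki = 3.6,
                                      noise_cv = 0.02, seed = 41)
  res <- classify_inhibition(pan_nc)
  expect_equal(res$selected, "noncompetitive")
  expect_equal(res$Ki, 3.6, tolerance = 0.1)
  # over the pure mechanisms the evidence is decisive
  res3 <- classify_inhibition(pan_nc, mechanisms = c("competitive",
                                                     "noncompetitive",
                                                     "uncompetitive"))
  expect_equal(res3$selected, "noncompetitive")
  expect_gt(max(res3$table$weight), 0.9)

  pan_c <- simulate_inhibition_panel("competitive", Ki = 3.6,
                                     noise_cv = 0.02, seed = 42)
  expect_equal(classify_inhibition(pan_c)$selected, "competitive")
  expect_true(all(abs(res$table$weight |> sum() - 1) < 1e-9))
})

test_that("model selection is accurate for every mechanism at 2% noise", {
  mechanisms <- c("competitive", "noncompetitive", "uncompetitive", "mixed")
  n_panel <- 50
  for (mech in mechanisms) {
    hits <- 0
    for (i in seq_len(n_panel)) {
      pan <- simulate_inhibition_panel(
        mech, Ki = 3.6, alpha = if (mech == "mixed") 4 else 1,
        noise_cv = 0.02, replicates = 1, seed = 1000 + i
      )
      sel <- tryCatch(classify_inhibition(pan)$selected,
                      error = function(e) NA_character_)
      hits <- hits + identical(sel, mech)
    }
    expect_gte(hits / n_panel, 0.9)
  }
})

test_that("degenerate panels are rejected", {
  pan <- simulate_inhibition_panel(inhibitor_uM = c(0, 5), seed = 1)
  expect_error(classify_inhibition(pan), "2 nonzero")
  pan2 <- simulate_inhibition_panel(inhibitor_uM = c(1, 5, 10), seed = 1)
  expect_error(classify_inhibition(pan2), "inhibitor_uM = 0")
})
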