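test_that("generators are pure functions of their seed", {
  p1 <- generate_proteome(20, seed = 4)
  p2 <- generate_proteome(20, seed = 4)
  expect_identical(p1$sequence, p2$sequence)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p1, f1); write_fasta(p2, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(simulate_psscl(seed = 6), simulate_psscl(seed = 6))
  q1 <- simulate_pics_experiment(p1, n_true = 5, n_decoy = 10, seed = 6)
  q2 <- simulate_pics_experiment(p1, n_true = 5, n_decoy = 10, seed = 6)
  expect_identical(q1$peptide, q2$peptide)
  expect_identical(q1$intensity_treated, q2$intensity_treated)
  expect_identical(simulate_kinetics("mm", seed = 2),
                   simulate_kinetics("mm", seed = 2))
  # different seeds differ
  expect_false(identical(generate_proteome(20, seed = 5)$sequence,
                         p1$sequence))
})

test_that("a composition without Glu forces single-fragment digests", {
  comp <- ecoli_composition()
  comp[["E"]] <- 0
  comp <- comp / sum(comp)
  p <- generate_proteome(10, 100, composition = comp, seed = 3)
  d <- digest_proteome(p, digest_rule(), length_range = NULL)
  expect_equal(nrow(d), 10)
  expect_equal(d$peptide, p$sequence)
})

test_that("every simulated dataset carries a sufficient truth record", {
  p <- generate_proteome(30, seed = 8)
  expect_named(attr(p, "truth"),
               c("generator", "seed", "n_proteins", "mean_length",
                 "composition"))
  q <- simulate_pics_experiment(p, n_true = 8, n_decoy = 10, seed = 8)
  tr <- attr(q, "truth")
  expect_equal(tr$expected_accepted, 8)
  expect_s3_class(tr$events, "tbl_df")
  expect_true(all(c("protein_id", "p1_index", "window") %in%
                    names(tr$events)))
  pl <- simulate_psscl(seed = 8)
  expect_s3_class(attr(pl, "truth")$profile, "specificity_matrix")
  expect_equal(attr(pl, "assay")$enzyme_nM, 60)
  d <- simulate_dose_response(seed = 8)
  expect_equal(attr(d, "truth")$ic50, 3.6)
})

test_that("plate noise at 5% leaves column profiles highly correlated with truth", {
  plate <- simulate_psscl(noise_cv = 0.05, seed = 14)
  m <- reduce_psscl(plate, "rate")
  truth <- klk8_psscl_profile()$values
  for (j in colnames(truth)) {
    expect_gt(cor(m$values[, j], truth[, j]), 0.99)
  }
  expect_error(simulate_psscl(noise_cv = -0.1), "noise_cv")
})

test_that("progress-curve integration agrees with the closed-form initial slope", {
  # at <= 5% depletion the mean slope matches the algebraic rate within 0.5%
  curve <- simulate_progress_curve(s0 = 200, kcat = 48, KM = 15.3,
                                   enzyme_nM = 60, times = seq(0, 3, 0.5))
  v_alg <- 48 * 0.06 * 200 / (15.3 + 200)
  depletion <- 1 - min(curve$substrate_uM) / 200
  expect_lt(depletion, 0.05)
  v_num <- (curve$signal[nrow(curve)] - curve$signal[1]) /
    (curve$time[nrow(curve)] - curve$time[1])
  expect_equal(v_num, v_alg, tolerance = 0.005)
})

test_that("an empty plant yields a pipeline with no events", {
  p <- generate_proteome(40, seed = 9)
  q <- simulate_pics_experiment(p, n_true = 0, n_decoy = 15, seed = 9)
  expect_error(run_pics(p, q), "no events")
})

test_that("unknown kinetic models are rejected", {
  expect_error(simulate_kinetics("sigmoidal", seed = 1))
  expect_error(
    simulate_inhibition_panel("allosteric", seed = 1) |>
      attr("truth"),
    "unknown mechanism"
  )
})
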