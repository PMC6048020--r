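make_plate <- function(rates_fun, replicates = 3) {
  grid <- expand.grid(
    fixed_residue = psscl_alphabet(),
    sublibrary = paste0("P", 4:1),
    replicate = seq_len(replicates),
    stringsAsFactors = FALSE
  )
  grid$rate <- rates_fun(grid)
  tibble::as_tibble(grid[, c("sublibrary", "fixed_residue", "replicate",
                             "rate")])
}

test_that("plate reduction takes replicate means of blanked rates", {
  # identical replicates reproduce the common value
  plate <- make_plate(function(g) 7)
  m <- reduce_psscl(plate, "rate")
  expect_true(all(m$values == 7))

  # hand arithmetic on a three-replicate well group
  plate2 <- make_plate(function(g) 10)
  sel <- plate2$sublibrary == "P1" & plate2$fixed_residue == "R"
  plate2$rate[sel] <- c(10, 12, 14)
  m2 <- reduce_psscl(plate2, "rate")
  expect_equal(m2$values["R", "P1"], 12)

  # blank column is subtracted well-wise
  plate3 <- make_plate(function(g) 10)
  plate3$blank <- 2
  m3 <- reduce_psscl(plate3, "rate")
  expect_true(all(m3$values == 8))
})

test_that("negative blanked means are clipped with a warning", {
  plate <- make_plate(function(g) 5)
  plate$blank <- 0
  sel <- plate$sublibrary == "P2" & plate$fixed_residue == "A"
  plate$blank[sel] <- 9
  expect_warning(m <- reduce_psscl(plate, "rate"), "clipped")
  expect_equal(m$values["A", "P2"], 0)
})

test_that("reduction is invariant to well order and rate rescaling", {
  set.seed(3)
  plate <- make_plate(function(g) runif(nrow(g), 1, 50))
  m1 <- reduce_psscl(plate, "pct_max")
  m2 <- reduce_psscl(plate[sample(nrow(plate)), ], "pct_max")
  expect_equal(m1$values, m2$values)
  plate2 <- plate; plate2$rate <- plate2$rate * 2
  expect_equal(reduce_psscl(plate2, "pct_max")$values, m1$values,
               tolerance = 1e-12)
  expect_equal(reduce_psscl(plate2, "pct_sum")$values,
               reduce_psscl(plate, "pct_sum")$values, tolerance = 1e-12)
})

test_that("incomplete plates are rejected", {
  plate <- make_plate(function(g) 5)
  expect_error(
    reduce_psscl(plate[!(plate$sublibrary == "P1" &
                           plate$fixed_residue == "R"), ], "rate"),
    "missing"
  )
  expect_error(reduce_psscl(plate[0, ], "rate"), "empty|missing")
})

test_that("replicate QC computes the hand CV and flags singletons", {
  plate <- make_plate(function(g) 10)
  sel <- plate$sublibrary == "P1" & plate$fixed_residue == "R"
  plate$rate[sel] <- c(10, 12, 14)  # cv = 2/12 = 0.1667
  qc <- qc_replicates(plate, cv_threshold = 0.15)
  row <- qc[qc$sublibrary == "P1" & qc$fixed_residue == "R", ]
  expect_equal(row$cv, 2 / 12, tolerance = 1e-12)
  expect_true(row$flag)
  expect_false(qc_replicates(plate, cv_threshold = 0.2)$flag[
    qc$sublibrary == "P1" & qc$fixed_residue == "R"])
  # zero-variance triplicates pass
  plate0 <- make_plate(function(g) 10)
  expect_false(any(qc_replicates(plate0)$flag))
  single <- make_plate(function(g) 5, replicates = 1)
  expect_true(all(qc_replicates(single)$flag))
})

test_that("noiseless simulated plates reduce to the truth exactly", {
  plate <- simulate_psscl(noise_cv = 0, seed = 9)
  m <- reduce_psscl(plate, "rate")
  expect_equal(m$values, klk8_psscl_profile()$values, tolerance = 1e-12)
})

test_that("the simulated KLK8-like plate keeps Lys under a quarter of Arg at P1", {
  plate <- simulate_psscl(noise_cv = 0.05, seed = 1)
  m <- reduce_psscl(plate, "pct_max")
  expect_lt(m$values["K", "P1"] / m$values["R", "P1"], 0.25)
})

test_that("the norleucine row converts onto the canonical alphabet", {
  m <- reduce_psscl(simulate_psscl(noise_cv = 0, seed = 2), "pct_sum")
  conv <- psscl_to_canonical(m)
  expect_setequal(rownames(conv$values), aa_alphabet())
  expect_false("n" %in% rownames(conv$values))
  expect_equal(conv$mode, "pct_sum")
  expect_true(all(abs(colSums(conv$values) - 100) < 1e-9))
})
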