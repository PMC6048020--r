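test_that("the fold-change filter is strictly greater-than", {
  d <- tibble::tibble(fold_change = c(8, 8.01, 0.5, 50, 7.99, 9, 100, 1, 3,
                                      12))
  acc <- filter_fold_change(d, 8)
  expect_equal(sort(acc$fold_change), c(8.01, 9, 12, 50, 100))
  expect_equal(nrow(filter_fold_change(d[0, ], 8)), 0)
})

test_that("fold changes floor zero controls instead of dividing by zero", {
  q <- tibble::tibble(peptide = c("a", "b"),
                      intensity_treated = c(100, 100),
                      intensity_control = c(10, 0))
  qq <- quantify_peptides(q)
  expect_equal(qq$fold_change[1], 10)
  expect_true(is.finite(qq$fold_change[2]) && qq$fold_change[2] > 1e6)
})

test_that("semi-specific location classifies termini against the rule", {
  prot <- tiny_proteome()  # prot1 = MAEGFKEDLL AVRTTLKE; GluC cuts after E
  # MAEGFKEDLLAVRTTLKE: cuts after E3, E7, E18(term)
  # fully specific fragment GFKE -> rejected as digestion product
  # semi-specific DLLAV (N terminus after E7 ok, C terminus neo at V12)
  # both-neo LLAVR; absent peptide
  peptides <- tibble::tibble(
    peptide = c("GFKE", "DLLAV", "LLAVR", "WWWWWWWWWWWW"),
    fold_change = c(20, 20, 20, 20)
  )
  res <- locate_semi_specific(peptides, prot, digest_rule())
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$peptide, "DLLAV")
  expect_equal(res$events$neo_terminus, "C")
  expect_equal(res$events$p1_index, 12L)
  expect_setequal(res$rejections$reason,
                  c("fully_specific", "both_termini_neo", "not_in_proteome"))
})

test_that("peptides matching several locations are excluded and counted", {
  prot <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("GGGWLRSTAKGGE", "TTWLRSTAKTTE")
  )
  pep <- tibble::tibble(peptide = "WLRSTAK", fold_change = 100)
  res <- locate_semi_specific(pep, prot, digest_rule())
  expect_equal(nrow(res$events), 0)
  expect_equal(res$rejections$reason, "ambiguous_location")
  res2 <- locate_semi_specific(pep, prot, digest_rule(),
                               multi_locus = "count_all")
  expect_equal(nrow(res2$events) + nrow(res2$rejections), 2)
})

test_that("windows are reconstructed with gap padding at protein edges", {
  prot <- tibble::tibble(id = "p", sequence = "GGISMRMAVLGG")
  ev <- tibble::tibble(protein_id = "p", p1_index = 6L)
  w <- reconstruct_window(ev, prot)$window
  expect_equal(w, "GGISMRMAVLGG")  # reactive-centre-loop-like ISMR | MAVL
  expect_equal(substr(w, 6, 6), "R")
  expect_equal(substr(w, 7, 7), "M")
  # cleavage after residue 3: P6...P4 fall outside the protein
  ev2 <- tibble::tibble(protein_id = "p", p1_index = 3L)
  w2 <- reconstruct_window(ev2, prot)$window
  expect_equal(substr(w2, 1, 3), "---")
  expect_equal(substr(w2, 4, 6), "GGI")
  expect_error(reconstruct_window(
    tibble::tibble(protein_id = "p", p1_index = 99L), prot), "out of bounds")
})

test_that("background composition matches hand counts and the generator", {
  expect_equal(unname(compute_background(
    tibble::tibble(id = "x", sequence = "AAAA"))[["A"]]), 1)
  # 30-residue hand count: 10 A, 5 R, 15 L
  bg <- compute_background(tibble::tibble(
    id = "y",
    sequence = paste0(strrep("A", 10), strrep("R", 5), strrep("L", 15))
  ))
  expect_equal(unname(bg[c("A", "R", "L")]), c(10, 5, 15) / 30)
  # large generated proteome reproduces its stated composition within 0.5%
  p <- generate_proteome(500, 300, seed = 2)
  emp <- compute_background(p)
  expect_true(all(abs(emp - ecoli_composition()) < 0.005))
})

test_that("heat maps match hand tallies and the uniform-background identity", {
  events <- tibble::tibble(window = c(
    "AAAAARGGGGGG", "CCCCCRGGGGGG", "AAAAAKGGGGGG", "DDDDDRHHHHHH",
    "-----RGGGGGG"  # N-terminal edge event: P6...P2 outside the protein
  ))
  maps <- build_heatmaps(events, uniform_background())
  # P1 column: R 4/5, K 1/5; the gap window still defines P1
  expect_equal(maps$counts$values["R", "P1"], 4)
  expect_equal(maps$counts$values["K", "P1"], 1)
  expect_equal(maps$counts$n_events[["P1"]], 5L)
  expect_equal(maps$counts$n_events[["P6"]], 4L)  # one gapped event
  expect_equal(maps$raw$values["R", "P1"], 80)
  # uniform background: corrected equals raw exactly
  expect_equal(maps$corrected$values, maps$raw$values, tolerance = 1e-12)
  # raw column sums equal the per-position event counts before normalization
  expect_equal(unname(colSums(maps$counts$values)),
               as.numeric(maps$counts$n_events))
  expect_error(build_heatmaps(events[0, ], uniform_background()),
               "no events")
})

test_that("the full pipeline recovers exactly the planted events", {
  proteome <- generate_proteome(120, seed = 31)
  quant <- simulate_pics_experiment(proteome, n_true = 25, n_decoy = 60,
                                    seed = 31)
  res <- run_pics(proteome, quant)
  truth <- attr(quant, "truth")
  expect_equal(nrow(res$events), truth$expected_accepted)
  key <- function(d) paste(d$protein_id, d$p1_index)
  expect_setequal(key(res$events), key(truth$events))
  # reconstructed windows equal the planted ones
  m <- dplyr::inner_join(res$events, truth$events,
                         by = c("protein_id", "p1_index"))
  expect_equal(m$window.x, m$window.y)
  # every accepted event has exactly one neo terminus by construction
  expect_true(all(res$events$neo_terminus %in% c("N", "C")))
  expect_error(run_pics(proteome, quant[0, ]), "no events")
})

test_that("the pipeline is deterministic for fixed inputs", {
  proteome <- generate_proteome(60, seed = 5)
  quant <- simulate_pics_experiment(proteome, n_true = 10, n_decoy = 20,
                                    seed = 5)
  r1 <- run_pics(proteome, quant)
  r2 <- run_pics(proteome, quant)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$corrected$values, r2$corrected$values)
  expect_identical(r1$report, r2$report)
})
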