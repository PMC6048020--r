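#' Packaged KLK8-like specificity profiles
#'
#' `klk8_pics_profile()` returns a P6...P6' residue-frequency matrix
#' emulating the published qualitative cleavage-site preferences of human
#' KLK8/neuropsin: a tryptic P1 strongly favouring Arg over Lys (Lys well
#' under a quarter of Arg), aliphatic P2 (Val/Leu/Ile), the unusual basic P3
#' (Arg/Lys) with acidic residues disfavoured, moderate P4 Thr/Trp, prime
#' side with Ser/Met standing out at P1' and Ile/Trp at P2' after abundance
#' correction, and moderate His/Tyr preferences at P5'/P6'. It is a synthetic
#' emulation constructed from those qualitative rankings - not measured data
#' - and is used as the ground truth of the cleavage-site simulator.
#'
#' `klk8_psscl_profile()` returns the corresponding P4...P1 rate-mode matrix
#' over the positional-scanning alphabet (norleucine `"n"` instead of Cys).
#'
#' @param background Composition modulating the frequency profile (default
#'   [ecoli_composition()]).
#' @return A [specificity_matrix()]; frequencies (`pct_sum`) for the P6-P6'
#'   profile, rates for the P4-P1 profile.
#' @export
#' @examples
#' klk8_pics_profile()
klk8_pics_profile <- function(background = ecoli_composition()) {
  bg <- as_background(background)
  pos <- subsite_positions()
  aa <- aa_alphabet()
  enr <- matrix(1, length(aa), length(pos), dimnames = list(aa, pos))
  bump <- function(p, ...) {
    up <- c(...)
    enr[names(up), p] <<- up
  }
  bump("P4", T = 3, W = 3, D = 0.3, E = 0.3)
  bump("P3", R = 6, K = 4, S = 1.5, A = 1.2, D = 0.15, E = 0.15)
  bump("P2", V = 4, L = 3.5, I = 3, N = 1.5, S = 1.3, T = 1.3,
       D = 0.2, E = 0.2)
  bump("P1", R = 25, K = 5, D = 0.1, E = 0.1)
  bump("P1'", S = 8, M = 9, A = 2.5)
  bump("P2'", I = 4, W = 4, A = 2, V = 2)
  bump("P4'", V = 1.8, I = 1.5)
  bump("P5'", H = 4)
  bump("P6'", Y = 4)
  freq <- sweep(enr, 1, bg[aa], "*")
  normalize_matrix(
    specificity_matrix(freq, mode = "enrichment"), "pct_sum"
  )
}

#' @rdname klk8_pics_profile
#' @export
klk8_psscl_profile <- function() {
  res <- psscl_alphabet()
  pos <- paste0("P", 4:1)
  v <- matrix(35, length(res), length(pos), dimnames = list(res, pos))
  set <- function(p, ...) {
    up <- c(...)
    v[names(up), p] <<- up
  }
  set("P4", T = 75, W = 70, D = 10, E = 10, n = 40)
  set("P3", R = 90, K = 85, S = 60, A = 55, D = 5, E = 5, n = 30)
  set("P2", L = 90, V = 85, I = 70, N = 60, S = 55, T = 50, D = 5, E = 5,
      n = 45)
  set("P1", R = 100, K = 20, A = 6, D = 1, E = 1, F = 5, G = 5, H = 6,
      I = 4, L = 5, M = 6, N = 5, P = 2, Q = 5, S = 6, T = 5, V = 4,
      W = 4, Y = 7, n = 5)
  specificity_matrix(v, mode = "rate")
}

#' Log-odds scoring model for the packaged KLK8-like profile
#'
#' Converts the packaged P6...P6' frequency profile into a position weight
#' matrix of log2-odds against the E. coli-like background, at an effective
#' depth of `n_events` cleavage events, ready for [score_window()] and
#' [scan_sequence()].
#'
#' @param n_events Effective event depth behind the profile (default 73).
#' @param pseudocount Passed to [build_log_odds()].
#' @param background Background composition.
#' @return A `log_odds_model`.
#' @export
#' @examples
#' mod <- klk8_scoring_model()
#' score_window(mod, "AANRLRATGEAA")
klk8_scoring_model <- function(n_events = 73, pseudocount = 1,
                               background = ecoli_composition()) {
  prof <- klk8_pics_profile(background)
  counts <- specificity_matrix(prof$values / 100 * n_events, "counts",
                               n_events = n_events)
  build_log_odds(counts, background, pseudocount)
}

#' Published kinetic reference values for KLK8
#'
#' Printed turnover numbers, Michaelis constants and catalytic efficiencies
#' for KLK8 with five synthetic substrates, as reported for the recombinant
#' enzyme; `printed_to` is the rounding granularity of the printed
#' efficiency (e.g. 100 means the value was printed to the nearest hundred).
#' These are inputs for arithmetic cross-checks, not fitted results.
#'
#' @return A tibble with columns `substrate`, `kcat`, `kcat_se`, `km_uM`,
#'   `km_se`, `efficiency_printed`, `efficiency_se`, `printed_to`.
#' @export
klk8_substrates <- function() {
  tibble::tribble(
    ~substrate,               ~kcat, ~kcat_se, ~km_uM, ~km_se,
    ~efficiency_printed, ~efficiency_se, ~printed_to,
    "Ac-Thr-Lys-Leu-Arg-ACC",  48.0,      2.1,   15.3,    1.5, 3137300, 333800, 100,
    "Ac-Thr-Lys-Leu-Arg-AMC",  43.9,      6.2,   14.4,    0.2, 3049000, 432600, 1000,
    "Z-Val-Val-Arg-AMC",        6.5,      0.9,   57.5,   10.7,  113000,  26200, 1000,
    "Boc-Val-Pro-Arg-AMC",      8.8,      0.4,  434.0,  100.2,   20300,   4800, 100,
    "Bz-Pro-Phe-Arg-pNA",       2.0,      0.5,  430.0,   68.0,    4650,   1380, 10
  )
}

#' Published zinc-inhibition reference values for KLK8 variants
#'
#' IC50 values (uM) for Zn2+ inhibition of wild-type KLK8 and the 99-loop
#' variants, used as true parameters when simulating dose-response data.
#'
#' @return A tibble with columns `variant`, `ic50_uM`, `ic50_se`.
#' @export
klk8_zinc_ic50 <- function() {
  tibble::tribble(
    ~variant,     ~ic50_uM, ~ic50_se,
    "wild_type",       3.6,      0.3,
    "H99A",           46.7,      3.2,
    "Y94F",            6.9,       NA
  )
}
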