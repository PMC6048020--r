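#' Default assay metadata for positional-scanning library plates
#'
#' Standard conditions for a diverse tetrapeptide acetyl-P4-P3-P2-P1-ACC
#' library screen: 60 nM enzyme, 31.25 nM per compound with 250 uM total
#' substrate, 25 C. Used by the simulator and recorded with reduced
#' matrices; the reduction arithmetic itself does not depend on it.
#'
#' @return Named list of assay conditions.
#' @export
psscl_assay_defaults <- function() {
  list(enzyme_nM = 60, per_compound_nM = 31.25, total_substrate_uM = 250,
       temperature_C = 25)
}

check_plate <- function(plate) {
  need <- c("sublibrary", "fixed_residue", "replicate", "rate")
  miss <- setdiff(need, names(plate))
  if (length(miss) > 0) {
    stop("plate is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  plate <- tibble::as_tibble(plate)
  if (nrow(plate) == 0) stop("empty plate", call. = FALSE)
  if (any(!is.finite(plate$rate))) stop("non-finite rates", call. = FALSE)
  subs <- paste0("P", 4:1)
  res <- psscl_alphabet()
  found <- unique(plate[, c("sublibrary", "fixed_residue")])
  want <- expand.grid(sublibrary = subs, fixed_residue = res,
                      stringsAsFactors = FALSE)
  missing <- dplyr::anti_join(want, found,
                              by = c("sublibrary", "fixed_residue"))
  if (nrow(missing) > 0) {
    stop("plate is missing ", nrow(missing),
         " (sublibrary, fixed_residue) combination(s), e.g. ",
         missing$sublibrary[1], "/", missing$fixed_residue[1], call. = FALSE)
  }
  plate
}

#' Reduce positional-scanning library plate readouts to a specificity matrix
#'
#' A positional-scanning synthetic combinatorial library plate contains one
#' sub-library per substrate position P4...P1; each well fixes one residue at
#' that position (19 canonical residues without Cys, plus norleucine `"n"`)
#' and mixes all residues elsewhere, so the measured fluorogenic rate reports
#' the protease's preference for the fixed residue. The reduction takes the
#' replicate mean of blank-subtracted rates per (sub-library, residue) pair,
#' clips negative means to zero (rates are physically nonnegative), and
#' optionally column-normalizes. When no `blank` column is present the blank
#' is zero.
#'
#' @param plate Data frame with columns `sublibrary` (`"P4"`...`"P1"`),
#'   `fixed_residue`, `replicate`, `rate`, optional `blank`.
#' @param normalization `"rate"` (replicate means as measured), `"pct_sum"`,
#'   or `"pct_max"`.
#' @return A [specificity_matrix()] with rows [psscl_alphabet()] and columns
#'   P4...P1.
#' @export
reduce_psscl <- function(plate, normalization = c("rate", "pct_sum",
                                                  "pct_max")) {
  normalization <- match.arg(normalization)
  plate <- check_plate(plate)
  if (!"blank" %in% names(plate)) plate$blank <- 0
  plate$blank[is.na(plate$blank)] <- 0
  means <- plate |>
    dplyr::group_by(.data$sublibrary, .data$fixed_residue) |>
    dplyr::summarise(mean_rate = mean(.data$rate - .data$blank),
                     .groups = "drop")
  if (any(means$mean_rate < 0)) {
    warn(paste0(sum(means$mean_rate < 0),
                " negative blank-subtracted mean rate(s) clipped to 0"))
    means$mean_rate <- pmax(means$mean_rate, 0)
  }
  res <- psscl_alphabet()
  subs <- paste0("P", 4:1)
  v <- matrix(0, length(res), length(subs), dimnames = list(res, subs))
  v[cbind(means$fixed_residue, means$sublibrary)] <- means$mean_rate
  m <- specificity_matrix(v, mode = "rate", n_events = NA_integer_)
  if (normalization == "rate") m else normalize_matrix(m, normalization)
}

#' Replicate quality control for a positional-scanning plate
#'
#' Flags each (sub-library, residue) well group whose replicate coefficient
#' of variation exceeds `cv_threshold`, or that has fewer than two
#' replicates (no variance estimate possible).
#'
#' @param plate Plate data frame (see [reduce_psscl()]).
#' @param cv_threshold Positive CV limit (default 0.2).
#' @return Tibble with `sublibrary`, `fixed_residue`, `n`, `mean`, `cv`,
#'   `flag` (logical) per well group.
#' @export
qc_replicates <- function(plate, cv_threshold = 0.2) {
  if (cv_threshold <= 0) stop("cv_threshold must be > 0", call. = FALSE)
  plate <- check_plate(plate)
  plate |>
    dplyr::group_by(.data$sublibrary, .data$fixed_residue) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$rate),
      cv = ifelse(dplyr::n() < 2 | mean(.data$rate) == 0, NA_real_,
                  sd(.data$rate) / mean(.data$rate)),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = .data$n < 2 | (!is.na(.data$cv) &
                                          .data$cv > cv_threshold))
}

#' Map a positional-scanning matrix onto the 20-canonical alphabet
#'
#' Positional-scanning libraries replace cysteine with norleucine (`"n"`), so
#' their matrices cannot be merged directly with proteome-derived profiles.
#' This converter drops the norleucine row and inserts a cysteine row set to
#' the background frequency of Cys times the column total, i.e. Cys is
#' assumed unenriched, then restores the input normalization mode.
#'
#' @param m A [specificity_matrix()] over [psscl_alphabet()].
#' @param background Canonical background frequencies (default
#'   [ecoli_composition()]).
#' @return A [specificity_matrix()] over [aa_alphabet()] in the same mode
#'   (rate matrices are returned as such).
#' @export
psscl_to_canonical <- function(m, background = ecoli_composition()) {
  stopifnot(inherits(m, "specificity_matrix"))
  if (!setequal(rownames(m$values), psscl_alphabet())) {
    stop("matrix rows are not the positional-scanning alphabet",
         call. = FALSE)
  }
  bg <- as_background(background)
  v <- m$values[setdiff(rownames(m$values), "n"), , drop = FALSE]
  cys <- bg[["C"]] * colSums(v)
  v <- rbind(v, C = cys)
  v <- v[order(rownames(v)), , drop = FALSE]
  out <- specificity_matrix(v, mode = if (m$mode %in% c("pct_sum", "pct_max"))
    "rate" else m$mode, n_events = m$n_events)
  if (m$mode %in% c("pct_sum", "pct_max")) {
    out <- normalize_matrix(out, m$mode)
  }
  out
}
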