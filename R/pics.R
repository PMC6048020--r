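#' Annotate a peptide quantification table with fold changes
#'
#' Adds `fold_change = intensity_treated / intensity_control`, flooring zero
#' or missing control intensities at a small epsilon (default 1e-6 of the
#' median positive control intensity) so that ratios stay finite; peptides
#' seen only in the treated sample then get very large finite fold changes
#' and pass a threshold filter, as they should.
#'
#' @param quant Data frame with columns `peptide`, `intensity_treated`,
#'   `intensity_control`.
#' @param control_floor Optional explicit epsilon; default derived from the
#'   median positive control intensity.
#' @return The input as a tibble with a `fold_change` column.
#' @export
quantify_peptides <- function(quant, control_floor = NULL) {
  need <- c("peptide", "intensity_treated", "intensity_control")
  miss <- setdiff(need, names(quant))
  if (length(miss) > 0) {
    stop("quant table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  quant <- tibble::as_tibble(quant)
  if (any(quant$intensity_treated < 0 | quant$intensity_control < 0,
          na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  ctrl <- quant$intensity_control
  pos <- ctrl[!is.na(ctrl) & ctrl > 0]
  eps <- control_floor %||%
    (if (length(pos) > 0) 1e-6 * median(pos) else 1e-6)
  ctrl[is.na(ctrl) | ctrl < eps] <- eps
  quant$fold_change <- quant$intensity_treated / ctrl
  quant
}

#' Select peptides above the fold-change acceptance threshold
#'
#' Peptides with a strictly greater than `threshold`-fold intensity increase
#' in the protease-treated sample are accepted as candidate cleavage
#' products; a peptide at exactly the threshold is rejected.
#'
#' @param peptides Tibble with a `fold_change` column (see
#'   [quantify_peptides()]).
#' @param threshold Positive acceptance threshold (default 8).
#' @return The accepted subset.
#' @export
#' @examples
#' filter_fold_change(tibble::tibble(fold_change = c(8, 8.01, 50)))
filter_fold_change <- function(peptides, threshold = 8) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  dplyr::filter(tibble::as_tibble(peptides), .data$fold_change > threshold)
}

# exact substring search of many peptides in a proteome.
# Returns a tibble (peptide, protein_id, start, end), one row per occurrence.
locate_in_proteome <- function(peptides, proteome) {
  seqs <- toupper(proteome$sequence)
  sep <- "#"
  big <- paste(seqs, collapse = sep)
  offsets <- cumsum(c(0L, nchar(seqs[-length(seqs)]) + 1L))
  hits <- stringi::stri_locate_all_fixed(big, toupper(peptides))
  purrr::map_dfr(seq_along(peptides), function(k) {
    h <- hits[[k]]
    if (nrow(h) == 0 || is.na(h[1, 1])) {
      return(tibble::tibble(peptide = character(), protein_id = character(),
                            start = integer(), end = integer()))
    }
    prot <- findInterval(h[, 1], offsets + 1L)
    # discard matches spanning the separator (cannot happen: '#' not in peptide)
    tibble::tibble(
      peptide = peptides[k],
      protein_id = proteome$id[prot],
      start = as.integer(h[, 1] - offsets[prot]),
      end = as.integer(h[, 2] - offsets[prot])
    )
  })
}

#' Locate semi-specific peptides and call cleavage events
#'
#' Each accepted peptide is matched exactly against the reference proteome.
#' Its two termini are then classified against the digestion rule: a terminus
#' is rule-conforming if it coincides with a protein terminus or with a bond
#' the library protease would cut; otherwise it is a neo terminus created by
#' the test protease. Peptides with exactly one neo terminus yield a cleavage
#' event at that terminus; fully specific peptides are plain digestion
#' products, and doubly-neo peptides are ambiguous - both are rejected with a
#' recorded reason, as are peptides absent from the proteome or (by default)
#' matching more than one location.
#'
#' @param peptides Tibble with columns `peptide` and `fold_change`.
#' @param proteome Data frame with `id`, `sequence`.
#' @param rule A [digest_rule()].
#' @param multi_locus `"exclude"` (default) rejects peptides matching several
#'   proteome locations; `"count_all"` keeps every location.
#' @return A list with `events` (tibble: `protein_id`, `p1_index`, `window`,
#'   `p1_residue`, `neo_terminus`, `peptide`, `fold_change`) and `rejections`
#'   (tibble: `peptide`, `reason`).
#' @export
locate_semi_specific <- function(peptides, proteome, rule = digest_rule(),
                                 multi_locus = c("exclude", "count_all")) {
  multi_locus <- match.arg(multi_locus)
  peptides <- tibble::as_tibble(peptides)
  if (!"fold_change" %in% names(peptides)) peptides$fold_change <- NA_real_
  loc <- locate_in_proteome(peptides$peptide, proteome)
  seq_by_id <- setNames(toupper(proteome$sequence), proteome$id)

  events <- list(); rejections <- list()
  for (k in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[k]
    h <- loc[loc$peptide == pep, ]
    if (nrow(h) == 0) {
      rejections[[length(rejections) + 1]] <-
        tibble::tibble(peptide = pep, reason = "not_in_proteome")
      next
    }
    if (nrow(h) > 1 && multi_locus == "exclude") {
      rejections[[length(rejections) + 1]] <-
        tibble::tibble(peptide = pep, reason = "ambiguous_location")
      next
    }
    for (j in seq_len(nrow(h))) {
      seq <- seq_by_id[[h$protein_id[j]]]
      n_ok <- terminus_conforms(seq, h$start[j] - 1L, rule)
      c_ok <- terminus_conforms(seq, h$end[j], rule)
      if (n_ok && c_ok) {
        rejections[[length(rejections) + 1]] <-
          tibble::tibble(peptide = pep, reason = "fully_specific")
      } else if (!n_ok && !c_ok) {
        rejections[[length(rejections) + 1]] <-
          tibble::tibble(peptide = pep, reason = "both_termini_neo")
      } else {
        p1 <- if (!n_ok) h$start[j] - 1L else h$end[j]
        events[[length(events) + 1]] <- tibble::tibble(
          protein_id = h$protein_id[j],
          p1_index = p1,
          window = extract_window(seq, p1),
          p1_residue = substring(seq, p1, p1),
          neo_terminus = if (!n_ok) "N" else "C",
          peptide = pep,
          fold_change = peptides$fold_change[k]
        )
      }
    }
  }
  empty_events <- tibble::tibble(
    protein_id = character(), p1_index = integer(), window = character(),
    p1_residue = character(), neo_terminus = character(),
    peptide = character(), fold_change = numeric()
  )
  empty_rej <- tibble::tibble(peptide = character(), reason = character())
  list(
    events = if (length(events)) dplyr::bind_rows(events) else empty_events,
    rejections = if (length(rejections)) dplyr::bind_rows(rejections) else empty_rej
  )
}

#' Reconstruct the P6...P6' window of a cleavage event
#'
#' Reads the 12-residue context around the scissile bond from the parent
#' protein; positions beyond the protein termini become the gap sentinel
#' `"-"`. This is a convenience wrapper around [extract_window()] for event
#' rows carrying `protein_id` and `p1_index`.
#'
#' @param events Tibble with `protein_id`, `p1_index`.
#' @param proteome Data frame with `id`, `sequence`.
#' @return `events` with a (re)computed `window` column.
#' @export
reconstruct_window <- function(events, proteome) {
  seq_by_id <- setNames(toupper(proteome$sequence), proteome$id)
  events <- tibble::as_tibble(events)
  events$window <- purrr::map2_chr(events$protein_id, events$p1_index,
                                   function(id, i) {
    s <- seq_by_id[[id]]
    if (is.null(s)) stop("unknown protein: ", id, call. = FALSE)
    extract_window(s, i)
  })
  events
}

#' Amino-acid background composition of a proteome
#'
#' Frequency of each canonical residue over all residues of the proteome;
#' used to correct observed cleavage-site residue frequencies for natural
#' abundance.
#'
#' @param proteome Data frame with a `sequence` column.
#' @return Named numeric vector over [aa_alphabet()] summing to 1.
#' @export
compute_background <- function(proteome) {
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  chars <- strsplit(paste(toupper(proteome$sequence), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = aa_alphabet()))
  as.vector(counts / sum(counts)) |> setNames(aa_alphabet())
}

#' Raw and abundance-corrected specificity heat maps from cleavage events
#'
#' Tallies the residues observed at each P6...P6' position over all events
#' (gap positions are excluded from that position's denominator, so
#' `n_events` is per column), yielding the raw heat map as percentages of the
#' column sum. The corrected map divides each observed frequency by the
#' background frequency of that residue (fold enrichment over natural
#' abundance) and rescales columns back to percentages, which prevents
#' abundant residues from dominating the profile. Under a uniform background
#' the correction is the identity.
#'
#' @param events Tibble with a `window` column of P6...P6' strings.
#' @param background Named frequency vector (see [compute_background()]).
#' @param positions Position labels (default P6...P6').
#' @return List with `raw` and `corrected` [specificity_matrix()] objects
#'   (both `pct_sum`) and `counts` (the raw counts matrix).
#' @export
build_heatmaps <- function(events, background,
                           positions = subsite_positions()) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  bg <- as_background(background)
  aa <- aa_alphabet()
  counts <- matrix(0, length(aa), length(positions),
                   dimnames = list(aa, positions))
  mat <- do.call(rbind, strsplit(events$window, ""))
  n_events <- integer(length(positions))
  for (j in seq_along(positions)) {
    col <- mat[, j]
    col <- col[col != "-"]
    n_events[j] <- length(col)
    tab <- table(factor(col, levels = aa))
    counts[, j] <- as.vector(tab)
  }
  counts_m <- specificity_matrix(counts, "counts", n_events = n_events)
  raw <- normalize_matrix(counts_m, "pct_sum")
  enr <- sweep(counts, 1, bg[aa], "/")
  corrected <- normalize_matrix(
    specificity_matrix(enr, "enrichment", n_events = n_events), "pct_sum"
  )
  list(raw = raw, corrected = corrected, counts = counts_m)
}

#' Run the full proteomic cleavage-site identification pipeline
#'
#' Composes fold-change annotation and filtering, semi-specific location of
#' peptides in the reference proteome, window reconstruction, and heat-map
#' construction, and reports every rejection reason. The pipeline is fully
#' deterministic for fixed inputs.
#'
#' @param proteome Data frame with `id`, `sequence`.
#' @param quant Quantification table (`peptide`, `intensity_treated`,
#'   `intensity_control`), or a table already carrying `fold_change`.
#' @param rule A [digest_rule()] describing the library protease.
#' @param threshold Fold-change acceptance threshold (default 8, strict).
#' @param multi_locus See [locate_semi_specific()].
#' @return An object of class `pics_result`: list with `events`, `raw`,
#'   `corrected`, `counts`, `background`, `report` (named counts of accepted
#'   events and each rejection reason).
#' @export
run_pics <- function(proteome, quant, rule = digest_rule(), threshold = 8,
                     multi_locus = "exclude") {
  quant <- tibble::as_tibble(quant)
  if (!"fold_change" %in% names(quant)) quant <- quantify_peptides(quant)
  if (nrow(quant) == 0) stop("no events: empty quantification table",
                             call. = FALSE)
  accepted <- filter_fold_change(quant, threshold)
  n_below <- nrow(quant) - nrow(accepted)
  located <- locate_semi_specific(accepted, proteome, rule,
                                  multi_locus = multi_locus)
  events <- located$events
  if (nrow(events) == 0) stop("no events passed the pipeline", call. = FALSE)
  bg <- compute_background(proteome)
  maps <- build_heatmaps(events, bg)
  rej <- if (nrow(located$rejections) > 0) {
    table(located$rejections$reason)
  } else table(character())
  report <- c(
    input_peptides = nrow(quant),
    below_threshold = n_below,
    accepted_events = nrow(events),
    setNames(as.integer(rej), names(rej))
  )
  structure(
    list(events = events, raw = maps$raw, corrected = maps$corrected,
         counts = maps$counts, background = bg, report = report),
    class = "pics_result"
  )
}

#' @export
print.pics_result <- function(x, ...) {
  cat("<pics_result>", x$report[["accepted_events"]], "cleavage events\n")
  cat("report:\n")
  print(x$report)
  invisible(x)
}

#' @rdname tidy.specificity_matrix
#' @export
tidy.pics_result <- function(x, ...) x$events

#' Summary counts of a cleavage-site identification run
#'
#' @param x A `pics_result`.
#' @param ... Unused.
#' @return One-row tibble of pipeline counts.
#' @export
glance.pics_result <- function(x, ...) {
  tibble::as_tibble(as.list(x$report))
}

#' @rdname autoplot.specificity_matrix
#' @export
autoplot.pics_result <- function(object, ...) {
  autoplot(object$corrected) +
    ggplot2::ggtitle("abundance-corrected cleavage-site heat map")
}
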