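#' Build a log-odds cleavage-site model from a counts matrix
#'
#' Converts a raw counts specificity matrix into a position weight matrix of
#' log2 odds against a background composition. For residue `a` at position `p`
#' with observed count `c`, column event count `n_p` and background frequency
#' `f_bg(a)`, the weight in bits is
#'
#'   `log2( (c + pseudocount * f_bg(a)) / (n_p + pseudocount) / f_bg(a) )`
#'
#' i.e. a background-scaled Laplace pseudocount followed by a log odds ratio.
#' When the observed frequencies equal the background all weights are zero,
#' so scores are in "bits above background".
#'
#' @param m A [specificity_matrix()] in `counts` mode.
#' @param background Named numeric vector of background frequencies covering
#'   every residue row of `m` (see [as_background()]).
#' @param pseudocount Positive smoothing mass (default 1, i.e. one
#'   background-distributed pseudo-event).
#' @return An object of class `log_odds_model` with elements `weights`
#'   (residue x position matrix, bits), `pseudocount`, `background`,
#'   `positions`.
#' @export
#' @examples
#' counts <- matrix(5, 20, 2, dimnames = list(aa_alphabet(), c("P1", "P1'")))
#' m <- specificity_matrix(counts, "counts", n_events = 100)
#' mod <- build_log_odds(m, setNames(rep(0.05, 20), aa_alphabet()))
#' range(mod$weights)  # all zero: observed == background
build_log_odds <- function(m, background, pseudocount = 1) {
  stopifnot(inherits(m, "specificity_matrix"))
  if (m$mode != "counts") {
    stop("log-odds models are built from counts matrices", call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  bg <- as_background(background, residues = rownames(m$values))
  bg <- bg[rownames(m$values)]
  n_p <- colSums(m$values)
  w <- m$values
  for (j in seq_len(ncol(w))) {
    freq <- (m$values[, j] + pseudocount * bg) / (n_p[j] + pseudocount)
    w[, j] <- log2(freq / bg)
  }
  structure(
    list(weights = w, pseudocount = pseudocount, background = bg,
         positions = colnames(w)),
    class = "log_odds_model"
  )
}

#' @export
print.log_odds_model <- function(x, ...) {
  cat("<log_odds_model> positions:", paste(x$positions, collapse = " "),
      "| pseudocount:", x$pseudocount, "\n")
  print(round(x$weights, 2), ...)
  invisible(x)
}

#' @rdname tidy.specificity_matrix
#' @export
tidy.log_odds_model <- function(x, ...) {
  w <- x$weights
  tibble::tibble(
    residue = rep(rownames(w), times = ncol(w)),
    position = factor(rep(colnames(w), each = nrow(w)), levels = colnames(w)),
    weight = as.vector(w)
  )
}

#' Score a P6...P6' substrate window
#'
#' A substrate window is the residue context around one scissile bond, written
#' from the outermost non-prime to the outermost prime position; positions
#' that fall outside the protein carry the gap sentinel `"-"`. The score is
#' the sum of the model's log-odds weights over the non-gap positions, so gaps
#' contribute zero and the score is additive over any split of the window.
#'
#' @param model A `log_odds_model` from [build_log_odds()].
#' @param window Character scalar (e.g. `"ATNRLRATGELL"`) or character vector
#'   of single residues, of the same length as `positions`.
#' @param positions Position labels of the window (default: the model's).
#' @return Score in bits.
#' @export
score_window <- function(model, window, positions = model$positions) {
  stopifnot(inherits(model, "log_odds_model"))
  res <- if (length(window) == 1 && nchar(window) > 1) {
    strsplit(window, "")[[1]]
  } else as.character(window)
  res <- toupper(res)
  if (length(res) != length(positions)) {
    stop("window length (", length(res), ") does not match positions (",
         length(positions), ")", call. = FALSE)
  }
  bad <- setdiff(positions, model$positions)
  if (length(bad) > 0) {
    stop("positions not in model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- res != "-"
  if (!all(res[keep] %in% rownames(model$weights))) {
    stop("window contains symbols outside the model alphabet: ",
         paste(setdiff(res[keep], rownames(model$weights)), collapse = ", "),
         call. = FALSE)
  }
  sum(model$weights[cbind(res[keep], positions[keep])])
}

#' Extract the residue window around a scissile bond
#'
#' Cleavage occurs between residues `p1_index` and `p1_index + 1` (1-based);
#' the window reads the positions given by `positions`, with `"-"` for
#' positions beyond either terminus.
#'
#' @param sequence Protein sequence (character scalar, upper case enforced).
#' @param p1_index 1-based index of the P1 residue.
#' @param positions Position labels (default P6...P6').
#' @return Character scalar window, e.g. `"---MKR|SAT..."` without the bar.
#' @export
#' @examples
#' extract_window("MARSTLK", 3)  # cleavage after R
extract_window <- function(sequence, p1_index,
                           positions = subsite_positions()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (p1_index < 1 || p1_index > n) {
    stop("p1_index out of bounds", call. = FALSE)
  }
  idx <- p1_index + subsite_offset(positions)
  res <- rep("-", length(idx))
  inside <- idx >= 1 & idx <= n
  res[inside] <- strsplit(sequence, "")[[1]][idx[inside]]
  paste(res, collapse = "")
}

#' Scan a protein sequence for candidate cleavage sites
#'
#' Slides the model over every eligible P1 position (each residue except the
#' C-terminal one, optionally restricted to a residue set such as `c("R",
#' "K")` for trypsin-like proteases), scores the P6...P6' window with
#' [score_window()], and ranks sites by descending score. Windows at the
#' sequence edges are gap-padded. Ties are broken by ascending `p1_index` so
#' output is deterministic; input case is ignored.
#'
#' @param model A `log_odds_model`.
#' @param sequence Protein sequence, length >= 1.
#' @param p1_restrict Optional character vector of allowed P1 residues.
#' @return A tibble with columns `p1_index`, `p1_residue`, `window`, `score`,
#'   `rank`, ordered by rank.
#' @export
scan_sequence <- function(model, sequence, p1_restrict = NULL) {
  stopifnot(inherits(model, "log_odds_model"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 1) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% aa_alphabet())) {
    stop("sequence contains non-canonical symbols: ",
         paste(unique(setdiff(chars, aa_alphabet())), collapse = ", "),
         call. = FALSE)
  }
  p1 <- seq_len(max(n - 1L, 0L))
  if (!is.null(p1_restrict)) {
    p1 <- p1[chars[p1] %in% toupper(p1_restrict)]
  }
  if (length(p1) == 0) {
    return(tibble::tibble(p1_index = integer(), p1_residue = character(),
                          window = character(), score = numeric(),
                          rank = integer()))
  }
  windows <- vapply(p1, function(i) extract_window(sequence, i, model$positions),
                    character(1))
  scores <- vapply(windows, function(w) score_window(model, w), numeric(1))
  ord <- order(-scores, p1)
  tibble::tibble(
    p1_index = p1[ord],
    p1_residue = chars[p1[ord]],
    window = unname(windows[ord]),
    score = unname(scores[ord]),
    rank = seq_along(ord)
  )
}

#' Assess whether an event count supports a reliable specificity profile
#'
#' Specificity profiles inferred from too few cleavage events are unstable;
#' about 30 events is the accepted minimum for a reliable determination when
#' specificity is measured by information entropy. Profiles below that limit
#' are flagged `low_confidence`. A seeded bootstrap (resampling events per
#' column from the observed residue distribution) yields a percentile
#' confidence interval for each position's entropy.
#'
#' @param m A [specificity_matrix()] in `counts` mode.
#' @param n_events Number of underlying cleavage events (default: maximum
#'   per-column event count of `m`).
#' @param n_boot Bootstrap replicates (default 1000, minimum 100).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `reliability_assessment` with `flag`
#'   (`"reliable"` or `"low_confidence"`), `n_events`, `threshold` (30), and
#'   `entropy_ci`, a tibble of per-position entropy with bootstrap CI.
#' @export
reliability_assessment <- function(m, n_events = max(m$n_events),
                                   n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(m, "specificity_matrix"))
  if (is.na(n_events) || n_events < 1) {
    stop("n_events must be >= 1", call. = FALSE)
  }
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  threshold <- 30L
  alpha <- (1 - conf) / 2
  ci <- withr::with_seed(seed, {
    purrr::map_dfr(colnames(m$values), function(p) {
      col <- m$values[, p]
      s <- sum(col)
      if (s <= 0) stop("zero column at ", p, call. = FALSE)
      pr <- col / s
      n_p <- if (is.na(m$n_events[p])) n_events else m$n_events[p]
      draws <- rmultinom(n_boot, size = n_p, prob = pr)
      h <- apply(draws, 2, function(cnt) {
        q <- cnt[cnt > 0] / sum(cnt)
        -sum(q * log2(q))
      })
      tibble::tibble(
        position = p,
        entropy = -sum(pr[pr > 0] * log2(pr[pr > 0])),
        ci_lower = unname(quantile(h, alpha)),
        ci_upper = unname(quantile(h, 1 - alpha))
      )
    })
  })
  structure(
    list(
      flag = if (n_events < threshold) "low_confidence" else "reliable",
      n_events = n_events, threshold = threshold, entropy_ci = ci
    ),
    class = "reliability_assessment"
  )
}

#' @export
print.reliability_assessment <- function(x, ...) {
  cat("<reliability_assessment>", x$flag, sprintf("(n_events=%d, limit=%d)\n",
      x$n_events, x$threshold))
  print(x$entropy_ci, ...)
  invisible(x)
}
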