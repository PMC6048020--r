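#' Amino-acid alphabets and subsite position conventions
#'
#' `aa_alphabet()` returns the 20 canonical amino acids in one-letter
#' alphabetical order. `psscl_alphabet()` returns the residue set used in
#' positional-scanning synthetic combinatorial libraries: the 19 canonical
#' residues without cysteine plus norleucine, written `"n"`, which substitutes
#' for Cys in such libraries because it is not oxidizable.
#'
#' @return Character vector of one-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
#' psscl_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
psscl_alphabet <- function() {
  # alphabetical with 'n' (norleucine) in place of C
  sort(c(setdiff(aa_alphabet(), "C"), "n"))
}

#' Subsite position labels in Schechter-Berger nomenclature
#'
#' Substrate residues N-terminal of the scissile bond are labelled P1, P2, ...
#' (P1 adjacent to the bond) and residues C-terminal of it P1', P2', ....
#' `subsite_positions()` returns position labels ordered from the outermost
#' non-prime position to the outermost prime position, e.g. P6...P1, P1'...P6'.
#'
#' @param n_nonprime Number of non-prime positions (default 6).
#' @param n_prime Number of prime positions (default 6).
#' @return Character vector of position labels.
#' @export
#' @examples
#' subsite_positions()          # P6 ... P6'
#' subsite_positions(4, 0)      # PSSCL side: P4 ... P1
subsite_positions <- function(n_nonprime = 6, n_prime = 6) {
  stopifnot(n_nonprime >= 0, n_prime >= 0, n_nonprime + n_prime >= 1)
  c(if (n_nonprime > 0) paste0("P", n_nonprime:1),
    if (n_prime > 0) paste0("P", 1:n_prime, "'"))
}

#' Signed index of a subsite position
#'
#' Maps position labels to signed offsets around the scissile bond:
#' P1 is -1, P2 is -2, ..., P1' is +1, P2' is +2, .... Given a 1-based P1
#' residue index `i` in a protein, the residue at a position with signed index
#' `k` sits at `i + k + (k > 0) - 1`, i.e. P1 at `i`, P1' at `i + 1`.
#'
#' @param labels Character vector of labels such as `"P2"` or `"P1'"`.
#' @return Integer vector of signed indices.
#' @export
#' @examples
#' subsite_index(c("P6", "P1", "P1'", "P6'"))
subsite_index <- function(labels) {
  prime <- grepl("'$", labels)
  num <- as.integer(sub("^P(\\d+)'?$", "\\1", labels))
  if (anyNA(num)) {
    stop("invalid subsite label(s): ",
         paste(labels[is.na(num)], collapse = ", "), call. = FALSE)
  }
  ifelse(prime, num, -num)
}

#' Residue offsets of subsite positions relative to P1
#'
#' Internal helper: 0 for P1, +1 for P1', -1 for P2, etc., so that
#' `p1_index + subsite_offset(label)` is the residue index of that position.
#' @noRd
subsite_offset <- function(labels) {
  k <- subsite_index(labels)
  ifelse(k > 0, k, k + 1L)
}

#' Embedded E. coli-like amino-acid composition
#'
#' Background amino-acid frequencies typical of the E. coli K-12 proteome
#' (values rounded from UniProt proteome-wide statistics), used as the default
#' composition for synthetic proteomes and as a fallback background for
#' natural-abundance correction. Frequencies are renormalized to sum to 1.
#'
#' @return Named numeric vector over [aa_alphabet()] summing to 1.
#' @export
#' @examples
#' sum(ecoli_composition())
ecoli_composition <- function() {
  f <- c(
    A = 0.0950, C = 0.0116, D = 0.0515, E = 0.0576, F = 0.0389,
    G = 0.0737, H = 0.0227, I = 0.0601, K = 0.0441, L = 0.1066,
    M = 0.0282, N = 0.0394, P = 0.0443, Q = 0.0444, R = 0.0553,
    S = 0.0581, T = 0.0541, V = 0.0707, W = 0.0153, Y = 0.0284
  )
  f / sum(f)
}

#' Validate a background composition
#'
#' A background composition is a named numeric vector of probabilities over
#' the canonical alphabet. It must cover every residue it is asked to score.
#'
#' @param bg Named numeric vector.
#' @param residues Residues that must be present (default: full alphabet).
#' @return The composition, renormalized to sum to 1, invisibly checked.
#' @export
as_background <- function(bg, residues = aa_alphabet()) {
  if (is.null(names(bg)) || !is.numeric(bg)) {
    stop("background must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(residues, names(bg))
  if (length(missing) > 0) {
    stop("background is missing residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(bg < 0) || sum(bg) <= 0) {
    stop("background frequencies must be nonnegative with positive sum",
         call. = FALSE)
  }
  bg / sum(bg)
}
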