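#' Digestion rule for in silico proteolysis
#'
#' Describes a site-specific protease used to generate a peptide library.
#' The default emulates GluC in bicarbonate buffer: cleavage C-terminal of
#' glutamate, blocked when proline follows. Aspartate cleavage (phosphate
#' buffer behaviour) can be enabled by adding `"D"` to `cleave_after`.
#'
#' @param cleave_after Residues whose C-terminal bond is cleaved (non-empty).
#' @param exclude_p1prime Residues blocking cleavage when at P1'.
#' @param missed_cleavages Maximum number of internal uncleaved sites per
#'   peptide (default 0).
#' @return An object of class `digest_rule`.
#' @export
#' @examples
#' digest_rule()                      # GluC
#' digest_rule(c("K", "R"), "P")      # trypsin
digest_rule <- function(cleave_after = "E", exclude_p1prime = "P",
                        missed_cleavages = 0) {
  cleave_after <- toupper(cleave_after)
  if (length(cleave_after) == 0) {
    stop("cleave_after must be non-empty", call. = FALSE)
  }
  stopifnot(missed_cleavages >= 0)
  structure(
    list(cleave_after = cleave_after,
         exclude_p1prime = toupper(exclude_p1prime %||% character()),
         missed_cleavages = as.integer(missed_cleavages)),
    class = "digest_rule"
  )
}

# 1-based indices i such that the rule cleaves between i and i+1
rule_cut_sites <- function(sequence, rule) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer())
  i <- which(chars[-n] %in% rule$cleave_after)
  i[!chars[i + 1] %in% rule$exclude_p1prime]
}

# is the bond after residue i a rule-conforming cut (or protein terminus)?
terminus_conforms <- function(sequence, i, rule) {
  n <- nchar(sequence)
  if (i == 0 || i == n) return(TRUE)  # protein terminus
  chars <- strsplit(sequence, "")[[1]]
  chars[i] %in% rule$cleave_after && !(chars[i + 1] %in% rule$exclude_p1prime)
}

#' Digest a proteome in silico
#'
#' Cuts every protein at the bonds selected by the rule and emits peptides
#' with provenance. With the length filter disabled and no missed cleavages,
#' the peptides of each protein tile it exactly (concatenation reconstructs
#' the protein).
#'
#' @param proteome A data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()] or [generate_proteome()]).
#' @param rule A [digest_rule()].
#' @param length_range Numeric length 2, inclusive peptide-length filter
#'   (default `c(6, 30)`, typical MS observability); `NULL` disables it.
#' @return A tibble with columns `protein_id`, `peptide`, `start`, `end`,
#'   `missed`.
#' @export
#' @examples
#' p <- tibble::tibble(id = "prot1", sequence = "MAEGFKEDLL")
#' digest_proteome(p, digest_rule(), length_range = NULL)
digest_proteome <- function(proteome, rule = digest_rule(),
                            length_range = c(6, 30)) {
  stopifnot(inherits(rule, "digest_rule"))
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(proteome)), function(k) {
    seq <- toupper(proteome$sequence[k])
    cuts <- rule_cut_sites(seq, rule)
    bounds <- c(0L, cuts, nchar(seq))
    nfrag <- length(bounds) - 1L
    pieces <- purrr::map_dfr(seq_len(nfrag), function(i) {
      jmax <- min(nfrag, i + rule$missed_cleavages)
      tibble::tibble(
        start = bounds[i] + 1L,
        end = bounds[(i + 1):(jmax + 1)],
        missed = 0:(jmax - i)
      )
    })
    tibble::tibble(
      protein_id = proteome$id[k],
      peptide = substring(seq, pieces$start, pieces$end),
      start = pieces$start, end = pieces$end, missed = pieces$missed
    )
  })
  if (!is.null(length_range)) {
    len <- nchar(out$peptide)
    out <- out[len >= length_range[1] & len <= length_range[2], ]
  }
  tibble::as_tibble(out)
}
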