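#' Read a protein FASTA file
#'
#' Record ids are taken from the header up to the first whitespace and
#' sequences are upper-cased. Records containing symbols outside the
#' canonical 20-letter alphabet are either dropped (default, with a count
#' reported via a warning) or cause an error.
#'
#' @param path FASTA file path.
#' @param invalid One of `"drop"` (default) or `"error"`.
#' @return Tibble with columns `id`, `sequence`; the number of dropped
#'   records is attached as attribute `n_dropped`.
#' @export
read_fasta <- function(path, invalid = c("drop", "error")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  ok <- !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seqs)
  if (!all(ok)) {
    if (invalid == "error") {
      stop(sum(!ok), " record(s) contain non-canonical symbols",
           call. = FALSE)
    }
    warn(paste0(sum(!ok), " record(s) with non-canonical symbols dropped"))
  }
  out <- tibble::tibble(id = ids[ok], sequence = unname(seqs[ok]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome Tibble with `id`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60) {
  set <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         comment.char = "", check.names = FALSE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Tabular readers and writers for pipeline inputs and outputs
#'
#' Thin TSV readers that validate the required columns: peptide
#' quantification tables (`peptide`, `intensity_treated`,
#' `intensity_control`), positional-scanning plates (`sublibrary`,
#' `fixed_residue`, `replicate`, `rate`, optional `blank`), and kinetic rate
#' tables. `write_tsv_plain()` writes any data frame with a header, tab
#' separation, `.` decimals and `\n` line endings, so outputs are
#' byte-stable.
#'
#' @param path File path.
#' @return A tibble (readers); `path` invisibly (writer).
#' @export
read_quant_table <- function(path) {
  read_tsv_checked(path, c("peptide", "intensity_treated",
                           "intensity_control"))
}

#' @rdname read_quant_table
#' @export
read_plate <- function(path) {
  read_tsv_checked(path, c("sublibrary", "fixed_residue", "replicate",
                           "rate"))
}

#' @rdname read_quant_table
#' @param required Column names that must be present.
#' @export
read_rate_table <- function(path, required = c("rate")) {
  read_tsv_checked(path, required)
}

#' @rdname read_quant_table
#' @param x Data frame to write.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
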