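#' Specificity matrices
#'
#' A specificity matrix tabulates, for each subsite position (column), how
#' strongly each amino acid (row) is observed or preferred there. Depending on
#' `mode` the values are raw event counts (`"counts"`), cleavage rates
#' (`"rate"`), percentages of the column sum (`"pct_sum"`), percentages of the
#' column maximum (`"pct_max"`), or background-corrected enrichments
#' (`"enrichment"`). `n_events` records, per column, how many events had that
#' position defined (edge windows leave outer positions undefined).
#'
#' @param values Numeric matrix, rows named by residues, columns by subsite
#'   position labels (see [subsite_positions()]). Values must be nonnegative.
#' @param mode One of `"counts"`, `"rate"`, `"pct_sum"`, `"pct_max"`,
#'   `"enrichment"`.
#' @param n_events Integer vector of per-column event counts, or a single
#'   number recycled; `NA` when not applicable (e.g. rate data).
#' @return An object of class `specificity_matrix`.
#' @export
#' @examples
#' m <- specificity_matrix(
#'   matrix(1, 20, 4, dimnames = list(aa_alphabet(), subsite_positions(4, 0))),
#'   mode = "counts", n_events = 20
#' )
#' normalize_matrix(m, "pct_sum")
specificity_matrix <- function(values, mode = c("counts", "rate", "pct_sum",
                                                "pct_max", "enrichment"),
                               n_events = NA_integer_) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have residue rownames and position colnames",
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("specificity values must be finite and nonnegative", call. = FALSE)
  }
  subsite_index(colnames(values))  # validates labels
  n_events <- rep_len(as.integer(round(n_events)), ncol(values))
  names(n_events) <- colnames(values)
  out <- structure(
    list(values = values, mode = mode, n_events = n_events),
    class = "specificity_matrix"
  )
  if (mode == "pct_sum") {
    cs <- colSums(values)
    if (any(abs(cs - 100) > 1e-9)) {
      stop("pct_sum columns must sum to 100", call. = FALSE)
    }
  }
  if (mode == "pct_max" && any(abs(apply(values, 2, max) - 100) > 1e-9)) {
    stop("pct_max columns must have maximum 100", call. = FALSE)
  }
  out
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix> ", nrow(x$values), " residues x ",
      ncol(x$values), " positions (", x$mode, ")\n", sep = "")
  if (!all(is.na(x$n_events))) {
    cat("n_events:", paste0(colnames(x$values), "=", x$n_events,
                            collapse = " "), "\n")
  }
  print(round(x$values, 2), ...)
  invisible(x)
}

#' @export
dim.specificity_matrix <- function(x) dim(x$values)

#' Column-normalize a specificity matrix
#'
#' Rescales each position column of a counts or rate matrix so that it sums to
#' 100 (`"pct_sum"`) or has a maximum of 100 (`"pct_max"`), the two display
#' conventions used for specificity heat maps and bar profiles.
#'
#' @param m A [specificity_matrix()] in `counts` or `rate` mode.
#' @param mode Target mode, `"pct_sum"` or `"pct_max"`.
#' @return A [specificity_matrix()] in the requested mode.
#' @export
normalize_matrix <- function(m, mode = c("pct_sum", "pct_max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "specificity_matrix"))
  if (!m$mode %in% c("counts", "rate", "enrichment")) {
    stop("normalize_matrix() expects a counts, rate or enrichment matrix",
         call. = FALSE)
  }
  v <- m$values
  denom <- switch(mode,
    pct_sum = colSums(v),
    pct_max = apply(v, 2, max)
  )
  if (any(denom <= 0)) {
    stop("degenerate all-zero column(s): ",
         paste(colnames(v)[denom <= 0], collapse = ", "), call. = FALSE)
  }
  specificity_matrix(sweep(v, 2, denom / 100, "/"), mode = mode,
                     n_events = m$n_events)
}

#' Per-position Shannon entropy and information content
#'
#' Treats each column of the matrix as a residue distribution and computes its
#' Shannon entropy H (bits) together with the information content
#' `log2(n_residues) - H`. Uniform columns attain the maximal entropy
#' `log2(20) ~ 4.32` bits (zero information); a one-hot column has H = 0.
#' Information content is the standard measure of how strict a subsite is.
#'
#' @param m A [specificity_matrix()].
#' @param positions Position labels to evaluate (default: all columns).
#' @return A tibble with columns `position`, `entropy`, `information`.
#' @export
#' @examples
#' m <- specificity_matrix(
#'   matrix(1, 20, 1, dimnames = list(aa_alphabet(), "P1")),
#'   mode = "counts", n_events = 20
#' )
#' position_entropy(m)
position_entropy <- function(m, positions = NULL) {
  stopifnot(inherits(m, "specificity_matrix"))
  v <- m$values
  positions <- positions %||% colnames(v)
  bad <- setdiff(positions, colnames(v))
  if (length(bad) > 0) {
    stop("unknown position(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  h <- vapply(positions, function(p) {
    col <- v[, p]
    s <- sum(col)
    if (s <= 0) stop("zero column at ", p, call. = FALSE)
    pr <- col / s
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }, numeric(1))
  tibble::tibble(
    position = positions,
    entropy = unname(h),
    information = log2(nrow(v)) - unname(h)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a specificity matrix into long format
#'
#' @param x A [specificity_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `residue`, `position`, `value`, `mode`.
#' @export
tidy.specificity_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    residue = rep(rownames(v), times = ncol(v)),
    position = factor(rep(colnames(v), each = nrow(v)), levels = colnames(v)),
    value = as.vector(v),
    mode = x$mode
  )
}

#' Heat-map display of a specificity matrix
#'
#' Residues run alphabetically down the y-axis and subsite positions across
#' the x-axis, the conventional orientation for cleavage-site heat maps.
#'
#' @param object A [specificity_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.specificity_matrix <- function(object, ...) {
  d <- tidy(object)
  d$residue <- factor(d$residue, levels = rev(sort(unique(d$residue))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$residue,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$mode) +
    ggplot2::labs(x = "subsite position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a specificity matrix as TSV with a JSON sidecar
#'
#' The TSV has a header row of position labels and a first column `residue`;
#' the sidecar `<path>.json` stores `mode` and per-column `n_events`, so a
#' round trip preserves the object.
#'
#' @param m A [specificity_matrix()].
#' @param path Output TSV path.
#' @return `write_specificity_matrix()` returns `path` invisibly;
#'   `read_specificity_matrix()` returns a [specificity_matrix()].
#' @export
write_specificity_matrix <- function(m, path) {
  stopifnot(inherits(m, "specificity_matrix"))
  df <- data.frame(residue = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mode = m$mode, n_events = as.list(m$n_events)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_specificity_matrix
#' @export
read_specificity_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$residue
  side <- paste0(path, ".json")
  mode <- "counts"
  n_events <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    mode <- meta$mode
    n_events <- as.integer(unlist(meta$n_events))
  }
  specificity_matrix(v, mode = mode, n_events = n_events)
}
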