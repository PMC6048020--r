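# Shared fixtures built in code.

uniform_counts <- function(n_row = 20, positions = subsite_positions(4, 0),
                           value = 1) {
  specificity_matrix(
    matrix(value, n_row, length(positions),
           dimnames = list(aa_alphabet()[seq_len(n_row)], positions)),
    mode = "counts", n_events = n_row * value
  )
}

# five hand-tallied cleavage events over two positions:
# P1 counts: A=2, C=1, D=2; P1' counts: G=4, H=1
five_event_counts <- function() {
  v <- matrix(0, 20, 2, dimnames = list(aa_alphabet(), c("P1", "P1'")))
  v["A", "P1"] <- 2; v["C", "P1"] <- 1; v["D", "P1"] <- 2
  v["G", "P1'"] <- 4; v["H", "P1'"] <- 1
  specificity_matrix(v, "counts", n_events = 5)
}

uniform_background <- function() {
  setNames(rep(0.05, 20), aa_alphabet())
}

tiny_proteome <- function() {
  tibble::tibble(
    id = c("prot1", "prot2"),
    sequence = c("MAEGFKEDLLAVRTTLKE", "GGISMRMAVLGG")
  )
}

random_aa_string <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}
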