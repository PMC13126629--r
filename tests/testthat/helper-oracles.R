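# Independent oracles used to freeze expected values: exhaustive
# enumeration for the matching algorithms, spreadsheet-style recomputation
# for the summary statistics. They share no code with the implementations
# they check.

# Minimum total |e - p| over every strictly increasing injection of the
# experimental indices into the ladder indices.
brute_force_op_cost <- function(exp, ladder) {
  n <- length(exp)
  m <- length(ladder)
  stopifnot(m >= n)
  combos <- utils::combn(m, n)
  min(apply(matrix(combos, nrow = n), 2,
            function(idx) sum(abs(exp - ladder[idx]))))
}

# Minimum window cost by direct scan.
brute_force_window_cost <- function(exp, ladder) {
  n <- length(exp)
  m <- length(ladder)
  min(vapply(seq_len(m - n + 1), function(s) {
    sum(abs(exp - ladder[s:(s + n - 1)]))
  }, numeric(1)))
}

# Random sorted matching instance.
random_instance <- function(n_max = 3, m_max = 6) {
  n <- sample(seq_len(n_max), 1)
  m <- sample(seq(n, m_max), 1)
  list(exp = sort(round(runif(n, 0, 14), 3)),
       ladder = sort(round(runif(m, 0, 14), 3)))
}

# Small multi-source entry table used by the records/curation tests.
fixture_entry_table <- function() {
  tibble::tibble(
    smiles = c("CC(=O)O", "CC(=O)O", "c1ccccc1O", "NCCc1ccccc1",
               "NCCc1ccccc1", "NC(Cc1ccccc1)C(=O)O"),
    pka_value = c("4.76", "9.26", "9.99", "9.83", "4.2", "1.83"),
    constant_kind = c("pKa", "pKb", "pKa", "pKa", "pKb", "pKa"),
    type_label = c(NA, NA, NA, NA, NA, "pKa1"),
    temperature_c = c("25", "25", "20", NA, "25", "25"),
    ionic_strength_m = NA_character_,
    cosolvent_fraction = c(NA, NA, NA, NA, NA, NA),
    source_dataset = c("A", "A", "A", "B", "B", "B"),
    remark = NA_character_
  )
}

# Temp file helper (extension preserved so readers pick the right parser).
scratch_file <- function(name) {
  tempfile(fileext = paste0(".", tools::file_ext(name)))
}
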