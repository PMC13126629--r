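test_that("entry tables map rows to entries and collect rejects", {
  tbl <- tibble::tibble(
    smiles = c("CCO", "", "CCN"),
    pka_value = c("15.9", "7.0", "not-a-number"),
    constant_kind = "pKa",
    source_dataset = "A"
  )
  got <- read_entries(tbl)
  expect_equal(nrow(got$entries), 1)
  expect_equal(got$entries$pka_value, 15.9)
  expect_equal(got$entries$smiles, "CCO")
  expect_setequal(got$rejects$reason,
                  c("unparseable structure", "unparseable numeric value"))
  expect_equal(nrow(got$entries) + nrow(got$rejects), nrow(tbl))
})

test_that("missing mandatory columns are a format error naming the column", {
  expect_error(read_entries(tibble::tibble(smiles = "CCO", pka_value = 4)),
               regexp = "constant_kind",
               class = "pkaladder_format_error")
})

test_that("reading a delimited file is lossless for mandatory fields", {
  path <- scratch_file("entries.csv")
  readr::write_csv(fixture_entry_table(), path, progress = FALSE)
  got <- read_entries(path)
  expect_equal(nrow(got$entries), 6)
  expect_equal(got$entries$pka_value[1], 4.76)
  expect_equal(got$entries$source_dataset, fixture_entry_table()$source_dataset)
  expect_equal(got$entries$temperature_c[4], NA_real_)
  # "unquantified" cosolvent text parses into the flag, not a number
  tbl <- fixture_entry_table()
  tbl$cosolvent_fraction[1] <- "unquantified"
  got2 <- read_entries(tbl)
  expect_true(got2$entries$cosolvent_unquantified[1])
  expect_true(is.na(got2$entries$cosolvent_fraction[1]))
})

test_that("structure keys ignore atom order and stereochemistry but separate molecules", {
  expect_equal(canonical_key("CCO"), canonical_key("OCC"))
  expect_equal(canonical_key("C[C@H](N)C(=O)O"), canonical_key("C[C@@H](N)C(=O)O"))
  expect_false(canonical_key("CCO") == canonical_key("CCN"))
  # deterministic across calls and equivalent drawings
  expect_equal(canonical_key("c1ccccc1O"), canonical_key("Oc1ccccc1"))
  expect_error(canonical_key("not_a_smiles"), class = "pkaladder_structure_error")
  expect_true(is.na(canonical_key("not_a_smiles", strict = FALSE)))
})

test_that("transition labels render and parse with explicit signs", {
  expect_equal(transition_label(0L), "0 to -1")
  expect_equal(transition_label(1L), "1 to 0")
  expect_equal(transition_label(-1L), "-1 to -2")
  parsed <- parse_transition_label(c("0 to -1", "2 to 1"))
  expect_equal(parsed$charge_high, c(0L, 2L))
  expect_equal(parsed$charge_low, c(-1L, 1L))
  expect_error(parse_transition_label("0 to -2"), class = "pkaladder_format_error")
})

test_that("ladders enforce ascending values, descending chained charges and the charge window", {
  lad <- macro_ladder("CC(=O)O", c(4.76, 9.8), charge_high = 0L)
  expect_equal(lad$charge_high, c(0L, -1L))
  expect_equal(lad$charge_low, c(-1L, -2L))
  expect_error(macro_ladder("C", c(5, 3), charge_high = 0L),
               class = "pkaladder_invariant_error")
  expect_error(macro_ladder("C", c(3, 5), charge_high = c(0L, 0L)),
               class = "pkaladder_invariant_error")
  expect_error(macro_ladder("C", c(3, 5), charge_high = c(2L, 0L)),
               class = "pkaladder_invariant_error")
  expect_error(macro_ladder("C", 1:14, charge_high = 6L),
               class = "pkaladder_invariant_error")
})

test_that("curated output round-trips through CSV and JSON at 2 decimals", {
  set.seed(11)
  records <- tibble::tibble(
    structure_key = rep(paste0("InChI=test/", 1:10), each = 1),
    smiles = structure_stub(0:9),
    charge_high = rep(c(0L, 1L), 5),
    charge_low = rep(c(-1L, 0L), 5),
    mean_pka = round(runif(10, 0, 14), 4),
    n_values = sample(1:4, 10, replace = TRUE)
  )
  for (fmt in c("csv", "json")) {
    path <- scratch_file(paste0("curated.", fmt))
    write_curated(records, path, fmt)
    back <- read_curated(path, fmt)
    back <- back[order(back$structure_key), ]
    recs <- records[order(records$structure_key), ]
    expect_equal(back$mean_pka, round(recs$mean_pka, 2))
    expect_equal(back$charge_high, recs$charge_high)
    expect_equal(back$n_values, recs$n_values)
  }
})

test_that("JSON export uses the field transition label convention", {
  path <- scratch_file("one.json")
  write_curated(tibble::tibble(structure_key = "k", smiles = "CC(=O)O",
                               charge_high = 0L, charge_low = -1L,
                               mean_pka = 4.1, n_values = 1L),
                path, "json")
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, "0 to -1", fixed = TRUE)
  expect_match(txt, "4.1", fixed = TRUE)

  # empty record set still yields a valid (empty) document
  empty <- scratch_file("empty.json")
  write_curated(tibble::tibble(structure_key = character(), smiles = character(),
                               charge_high = integer(), charge_low = integer(),
                               mean_pka = numeric(), n_values = integer()),
                empty, "json")
  expect_equal(nrow(read_curated(empty, "json")), 0)

  expect_error(write_curated(tibble::tibble(), path, "xlsx"))
})
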