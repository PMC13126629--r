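entry_row <- function(value, kind = "pKa", source = "A", temp = NA_real_,
                      cosolv = NA_real_, unq = FALSE, remark = NA_character_,
                      type = NA_character_, id = 1L) {
  tibble::tibble(entry_id = id, smiles = "CC(=O)O", structure_key = "k",
                 pka_value = value, constant_kind = kind, type_label = type,
                 temperature_c = temp, ionic_strength_m = NA_real_,
                 cosolvent_fraction = cosolv, cosolvent_unquantified = unq,
                 source_dataset = source, remark = remark)
}

test_that("pKb values convert by subtraction from the water constant", {
  got <- to_pka(dplyr::bind_rows(
    entry_row(0.0, "pKb", id = 1L),
    entry_row(4.75, "pKb", id = 2L),
    entry_row(7.4, "pKa", id = 3L),
    entry_row(5.0, "Kd", id = 4L)))
  expect_equal(got$entries$pka_value, c(14.0, 9.25, 7.4))
  expect_true(all(got$entries$constant_kind == "pKa"))
  expect_equal(got$rejects$reason, "unknown constant kind")

  # involution through the association convention: pKa -> pKb -> pKa
  x <- 6.31
  as_pkb <- 14.0 - x
  back <- to_pka(entry_row(as_pkb, "pKb"))
  expect_equal(back$entries$pka_value, x)
})

test_that("cosolvent and condition filters drop what the rules cover and keep the rest", {
  entries <- dplyr::bind_rows(
    entry_row(4, cosolv = 0.10, id = 1L),                     # above 5%
    entry_row(4, cosolv = 0.03, id = 2L),                     # within 5%
    entry_row(4, unq = TRUE, id = 3L),                        # unquantified
    entry_row(4, id = 4L),                                    # absent metadata
    entry_row(4, remark = "measured under extreme pressure", id = 5L))
  got <- metadata_filter(entries)
  expect_equal(got$entries$entry_id, c(2L, 4L))
  expect_setequal(got$rejects$reason,
                  c("cosolvent content above threshold",
                    "cosolvent content not quantified",
                    "nonconventional experimental conditions"))

  # sources outside the cosolvent rule's scope are exempt
  config <- curation_config(cosolvent_sources = "IUPAC")
  exempt <- metadata_filter(dplyr::bind_rows(
    entry_row(4, cosolv = 0.10, source = "A", id = 1L),
    entry_row(4, cosolv = 0.10, source = "IUPAC", id = 2L)), config)
  expect_equal(exempt$entries$entry_id, 1L)
})

test_that("transition assignment dispatches per strategy", {
  ladder <- macro_ladder("CC(=O)O", c(3.5, 9.2), charge_high = 1L)
  two <- assign_transitions(c(4.0, 9.0), ladder, "order_preserving")
  expect_equal(two$charge_high, c(1L, 0L))
  expect_equal(two$charge_low, c(0L, -1L))

  one <- assign_transitions(8.9, ladder, "closest")
  expect_equal(one$charge_high, 0L)

  expect_error(assign_transitions(c(1, 5, 9), ladder, "order_preserving"),
               class = "pkaladder_infeasible_error")
})

test_that("typed grouping matches group means when consistent and falls back when not", {
  ladder <- macro_ladder("x", c(3.0, 8.0), charge_high = 1L)
  ok <- assign_transitions(c(3.1, 3.3, 8.2), ladder, "typed_grouped",
                           type_labels = c("pKa1", "pKa1", "pKa2"))
  expect_false(attr(ok, "fallback"))
  expect_equal(ok$charge_high, c(1L, 1L, 0L))
  # same result as order-preserving matching on the group means
  means_match <- order_preserving_match(c(mean(c(3.1, 3.3)), 8.2), ladder$value)
  expect_equal(unique(ok$charge_high), ladder$charge_high[means_match$pairs$ladder_index])

  bad <- assign_transitions(c(3.0, 4.5), ladder, "typed_grouped",
                            type_labels = c("pKa1", "pKa1"))
  expect_true(attr(bad, "fallback"))
  expect_equal(bad$charge_high, c(1L, 1L))  # each matched to its closest rung
})

test_that("outlier rule drops molecules with any matched deviation strictly above 4", {
  expect_false(outlier_keep(c(0.3, 4.5)))
  expect_true(outlier_keep(0.0))
  expect_true(outlier_keep(4.0))
  expect_false(outlier_keep(-4.0001))
})

test_that("cross-source duplicates are counted at the minimum occurrence", {
  config <- curation_config()
  a <- deduplicate(list(A = c(4.50, 4.50), B = 4.50), config)
  expect_equal(nrow(a), 1)
  expect_equal(a$value, 4.50)

  b <- deduplicate(list(A = c(4.50, 4.50)), config)
  expect_equal(b$value, c(4.50, 4.50))

  c <- deduplicate(list(A = 4.50, B = 4.62), config)
  expect_setequal(c$value, c(4.50, 4.62))

  # comparison happens after rounding to 2 decimals
  d <- deduplicate(list(A = 4.501, B = 4.499), config)
  expect_equal(nrow(d), 1)
})

test_that("deduplication is idempotent", {
  set.seed(31)
  for (rep in 1:20) {
    df <- tibble::tibble(
      source = sample(LETTERS[1:3], 12, replace = TRUE),
      value = round(runif(12, 4, 5), 1))
    once <- deduplicate(df)
    twice <- deduplicate(once)
    expect_equal(twice, once)
  }
})

test_that("averaging respects the temperature window and reports empty transitions", {
  df <- tibble::tibble(charge_high = c(0L, 0L, 1L, 1L),
                       charge_low = c(-1L, -1L, 0L, 0L),
                       value = c(4.0, 4.2, 4.0, 6.0),
                       temperature_c = c(NA, NA, 25, 90))
  got <- average_transitions(df)
  expect_equal(got$averaged$mean_pka[got$averaged$charge_high == 0L], 4.1)
  expect_equal(got$averaged$mean_pka[got$averaged$charge_high == 1L], 4.0)

  all_out <- average_transitions(tibble::tibble(
    charge_high = 0L, charge_low = -1L, value = 5.0, temperature_c = 95))
  expect_equal(nrow(all_out$averaged), 0)
  expect_equal(nrow(all_out$omitted), 1)

  single <- average_transitions(tibble::tibble(
    charge_high = 0L, charge_low = -1L, value = 3.3, temperature_c = NA_real_))
  expect_equal(single$averaged$mean_pka, 3.3)
})

test_that("dispersion statistics match closed forms and an independent recomputation", {
  two <- dispersion_stats(tibble::tibble(
    structure_key = "k", charge_high = 0L, charge_low = -1L,
    value = c(4.0, 4.4)))
  expect_equal(two$per_transition$sd, 0.4 / sqrt(2), tolerance = 1e-12)
  expect_equal(two$per_transition$range, 0.4)

  flat <- dispersion_stats(tibble::tibble(
    structure_key = "k", charge_high = 0L, charge_low = -1L,
    value = c(5, 5, 5)))
  expect_equal(flat$per_transition$sd, 0)
  expect_equal(flat$per_transition$range, 0)

  set.seed(32)
  df <- tibble::tibble(
    structure_key = rep(c("a", "a", "b"), times = c(3, 2, 4)),
    charge_high = rep(c(0L, 1L, 0L), times = c(3, 2, 4)),
    charge_low = rep(c(-1L, 0L, -1L), times = c(3, 2, 4)),
    value = runif(9, 2, 12))
  got <- dispersion_stats(df)
  # spreadsheet-style oracle: split and recompute with nothing shared
  oracle <- t(sapply(split(df$value, paste(df$structure_key, df$charge_high)),
                     function(v) c(sd = sd(v), range = max(v) - min(v))))
  expect_equal(got$mean_sd, mean(oracle[, "sd"]))
  expect_equal(got$mean_range, mean(oracle[, "range"]))
})

test_that("the mean replicate SD agrees with a Monte-Carlo oracle at two replicates", {
  sigma <- 0.2
  sim <- generate_synthetic(synthetic_config(
    n_molecules = 3400, rungs = 3L, replicates = 2L, sigma_exp = sigma,
    dropout_p = 0, spurious_p = 0, sigma_pred = 0, seed = 33))
  df <- tibble::tibble(
    structure_key = paste(sim$entries$molecule_id, sim$entries$true_rung),
    charge_high = 0L, charge_low = -1L, value = sim$entries$pka_value)
  got <- dispersion_stats(df)
  expect_gte(nrow(got$per_transition), 10000)

  set.seed(34)  # direct oracle: sample SD of two sigma-scaled normals
  oracle <- mean(apply(matrix(rnorm(2 * 10000, sd = sigma), ncol = 2), 1, sd))
  expect_equal(got$mean_sd, oracle, tolerance = 0.03)
})

test_that("the curation pipeline conserves entries and brackets every mean", {
  sim <- generate_synthetic(synthetic_config(n_molecules = 150, seed = 35))
  entries <- sim$entries
  ladders <- sim$truth
  names(ladders)[names(ladders) == "true_pka"] <- "value"
  ladders$structure_key <- ladders$smiles  # synthetic stubs are unique already
  entries$structure_key <- entries$smiles
  res <- curate_entries(entries, ladders)

  # stage-level conservation: entered = kept + rejected, chained
  counts <- res$stage_counts
  rej_by_stage <- table(factor(res$rejects$stage, levels = counts$stage))
  expect_equal(counts$entered - counts$kept, as.integer(rej_by_stage))
  expect_equal(counts$entered[-1], counts$kept[-nrow(counts)])
  expect_equal(counts$entered[1], nrow(entries))

  # every averaged value lies within [min, max] of its contributors
  joined <- dplyr::inner_join(
    res$curated,
    dplyr::group_by(entries, .data$structure_key, .data$true_rung) |>
      dplyr::summarise(lo = min(.data$pka_value), hi = max(.data$pka_value),
                       .groups = "drop"),
    by = "structure_key", relationship = "many-to-many")
  by_row <- dplyr::group_by(joined, .data$structure_key, .data$charge_high) |>
    dplyr::summarise(ok = any(.data$mean_pka >= .data$lo - 1e-9 &
                                .data$mean_pka <= .data$hi + 1e-9),
                     .groups = "drop")
  expect_true(all(by_row$ok))

  # averaging is permutation-invariant
  shuffled <- entries[sample(nrow(entries)), ]
  res2 <- curate_entries(shuffled, ladders)
  ord <- function(df) df[order(df$structure_key, df$charge_high), ]
  expect_equal(ord(res2$curated), ord(res$curated))
})
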