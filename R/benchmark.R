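# Construction of the monoprotic / amphoteric / polyprotic benchmark sets
# from a curated collection: a fixed funnel of value-range, heavy-atom,
# fine-tune-overlap and prediction-sufficiency filters followed by
# classification. Every molecule ends up in exactly one set or in the
# exclusion log with a reason.

#' Value-range and molecule-size filter
#'
#' Keeps molecules whose every averaged pKa lies in `value_range`
#' (default `[0, 14]`, the aqueous window) and whose heavy-atom count lies
#' in `heavy_range` (default `[6, 50]`, excluding trivial fragments and
#' very large structures). Both bounds inclusive.
#'
#' @param records Curated tibble (one row per molecule/transition) with
#'   columns `structure_key`, `smiles`, `mean_pka`.
#' @param value_range,heavy_range Numeric length-2 inclusive bounds.
#' @return A list with `kept` (records of surviving molecules) and
#'   `excluded` (tibble `structure_key`, `reason`).
#' @export
range_filter <- function(records, value_range = c(0, 14),
                         heavy_range = c(6L, 50L)) {
  mols <- dplyr::summarise(dplyr::group_by(records, .data$structure_key),
                           smiles = .data$smiles[1],
                           ok_values = all(.data$mean_pka >= value_range[1] &
                                             .data$mean_pka <= value_range[2]),
                           .groups = "drop")
  heavy <- heavy_atom_count(mols$smiles, strict = FALSE)
  ok_heavy <- !is.na(heavy) & heavy >= heavy_range[1] & heavy <= heavy_range[2]
  reason <- rep(NA_character_, nrow(mols))
  reason[!mols$ok_values] <- "pKa value outside range"
  reason[is.na(reason) & !ok_heavy] <- "heavy atom count outside range"
  keep_keys <- mols$structure_key[is.na(reason)]
  list(kept = records[records$structure_key %in% keep_keys, ],
       excluded = tibble::tibble(structure_key = mols$structure_key[!is.na(reason)],
                                 reason = reason[!is.na(reason)]))
}

#' Fine-tune / popular-benchmark overlap filter
#'
#' Removes molecules whose stereochemistry-stripped structure key appears
#' in any exclusion set (e.g. the fine-tuning data of an open-source
#' predictor, or widely used benchmark collections whose leakage cannot be
#' ruled out). Stereochemistry is omitted in the comparison, so
#' stereoisomers of excluded molecules are excluded too.
#'
#' @param records Curated tibble.
#' @param exclusion_sets A list of character vectors, each either SMILES
#'   (converted via [canonical_key()]) or pre-computed structure keys
#'   (detected by the `"InChI="` prefix).
#' @return A list with `kept` and `excluded`.
#' @export
overlap_filter <- function(records, exclusion_sets = list()) {
  excl_keys <- character()
  for (set in exclusion_sets) {
    if (length(set) == 0) next
    is_key <- startsWith(set, "InChI=")
    keys <- c(set[is_key], if (any(!is_key)) canonical_key(set[!is_key], strict = FALSE))
    excl_keys <- union(excl_keys, keys[!is.na(keys)])
  }
  hit <- records$structure_key %in% excl_keys
  hit_keys <- unique(records$structure_key[hit])
  list(kept = records[!records$structure_key %in% hit_keys, ],
       excluded = tibble::tibble(structure_key = hit_keys,
                                 reason = "present in an exclusion set"))
}

#' Classify a molecule's averaged transitions
#'
#' Applies the benchmark group definitions: one averaged value at
#' transition `0 to -1` (acid) or `1 to 0` (base) is monoprotic; exactly
#' the two transitions `1 to 0` and `0 to -1` is amphoteric; more than one
#' averaged value otherwise is polyprotic. A molecule with a single
#' transition where both involved charge states are nonzero implies
#' experimentally undetected transitions and is excluded.
#'
#' @param charge_high,charge_low Integer vectors of the molecule's averaged
#'   transitions.
#' @return A string: `"monoprotic"`, `"amphoteric"`, `"polyprotic"` or
#'   an exclusion reason of the form `"excluded: ..."`.
#' @export
classify_molecule <- function(charge_high, charge_low) {
  stopifnot(length(charge_high) >= 1L, length(charge_high) == length(charge_low))
  n <- length(charge_high)
  if (n == 1L) {
    if ((charge_high == 0L && charge_low == -1L) ||
        (charge_high == 1L && charge_low == 0L)) {
      return("monoprotic")
    }
    if (charge_high != 0L && charge_low != 0L) {
      return("excluded: implied undetected transitions")
    }
    return("excluded: single transition outside monoprotic definitions")
  }
  if (n == 2L) {
    labs <- sort(transition_label(charge_high, charge_low))
    if (identical(labs, sort(c("1 to 0", "0 to -1")))) return("amphoteric")
  }
  "polyprotic"
}

#' Prediction-sufficiency filter
#'
#' A predictor's output for a molecule is sufficient when it supplies at
#' least as many predicted pKa values as there are experimental values. For
#' the monoprotic and amphoteric groups every listed predictor must be
#' sufficient; for the polyprotic group only macroscopic predictors are
#' considered (microscopic predictors are not evaluated there).
#'
#' @param records Curated tibble.
#' @param predictions Tibble with columns `structure_key`, `predictor`,
#'   `n_predicted` and `family` (`"macro"` or `"micro"`). A molecule absent
#'   from a predictor's rows counts as 0 predictions for it.
#' @return A list with `kept` and `excluded`.
#' @export
sufficiency_filter <- function(records, predictions) {
  mols <- dplyr::summarise(
    dplyr::group_by(records, .data$structure_key),
    n_exp = dplyr::n(),
    label = classify_molecule(.data$charge_high, .data$charge_low),
    .groups = "drop")
  predictors <- unique(predictions[, c("predictor", "family")])
  bad <- vapply(seq_len(nrow(mols)), function(i) {
    key <- mols$structure_key[i]
    relevant <- if (mols$label[i] == "polyprotic") {
      predictors$predictor[predictors$family == "macro"]
    } else {
      predictors$predictor
    }
    for (p in relevant) {
      got <- predictions$n_predicted[predictions$structure_key == key &
                                       predictions$predictor == p]
      if (length(got) == 0 || max(got) < mols$n_exp[i]) return(TRUE)
    }
    FALSE
  }, logical(1))
  bad_keys <- mols$structure_key[bad]
  list(kept = records[!records$structure_key %in% bad_keys, ],
       excluded = tibble::tibble(structure_key = bad_keys,
                                 reason = "insufficient prediction from a relevant predictor"))
}

#' Build the three benchmark sets
#'
#' Runs the full funnel — range/size filter, fine-tune overlap filter,
#' prediction sufficiency, classification — and partitions the survivors
#' into the monoprotic, amphoteric and polyprotic benchmark sets.
#' (Temperature filtering happens upstream, during averaging.)
#'
#' @param records Curated tibble from [curate_entries()].
#' @param exclusion_sets Passed to [overlap_filter()].
#' @param predictions Passed to [sufficiency_filter()]; `NULL` skips the
#'   sufficiency stage.
#' @param value_range,heavy_range Passed to [range_filter()].
#' @return A list with `sets` (named list of curated tibbles for
#'   `monoprotic`, `amphoteric`, `polyprotic`), `exclusions`
#'   (tibble `stage`, `structure_key`, `reason`) and `funnel`
#'   (per-stage molecule counts).
#' @export
build_benchmarks <- function(records, exclusion_sets = list(),
                             predictions = NULL,
                             value_range = c(0, 14), heavy_range = c(6L, 50L)) {
  n_mol <- function(df) length(unique(df$structure_key))
  funnel <- list()
  exclusions <- list()
  note <- function(stage, df, excl) {
    funnel[[length(funnel) + 1L]] <<- tibble::tibble(stage = stage, molecules = n_mol(df))
    if (nrow(excl) > 0) {
      excl$stage <- stage
      exclusions[[length(exclusions) + 1L]] <<- excl
    }
  }
  note("input", records, tibble::tibble(structure_key = character(), reason = character()))

  rf <- range_filter(records, value_range, heavy_range)
  note("range", rf$kept, rf$excluded)
  of <- overlap_filter(rf$kept, exclusion_sets)
  note("overlap", of$kept, of$excluded)
  kept <- of$kept
  if (!is.null(predictions)) {
    sf <- sufficiency_filter(kept, predictions)
    note("sufficiency", sf$kept, sf$excluded)
    kept <- sf$kept
  }

  labels <- dplyr::summarise(
    dplyr::group_by(kept, .data$structure_key),
    label = classify_molecule(.data$charge_high, .data$charge_low),
    .groups = "drop")
  class_excl <- labels[startsWith(labels$label, "excluded"), ]
  note("classify",
       kept[kept$structure_key %in% labels$structure_key[!startsWith(labels$label, "excluded")], ],
       tibble::tibble(structure_key = class_excl$structure_key,
                      reason = sub("^excluded: ", "", class_excl$label)))

  sets <- lapply(c(monoprotic = "monoprotic", amphoteric = "amphoteric",
                   polyprotic = "polyprotic"), function(lab) {
    keys <- labels$structure_key[labels$label == lab]
    kept[kept$structure_key %in% keys, ]
  })
  list(
    sets = sets,
    exclusions = if (length(exclusions) > 0) {
      dplyr::bind_rows(exclusions)[, c("stage", "structure_key", "reason")]
    } else {
      tibble::tibble(stage = character(), structure_key = character(),
                     reason = character())
    },
    funnel = dplyr::bind_rows(funnel)
  )
}
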