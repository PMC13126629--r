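# Multi-stage curation: raw multi-source entries -> per-molecule,
# per-transition averaged pKa values. Stage order: constant conversion ->
# metadata filters -> transition assignment -> outlier exclusion ->
# cross-source deduplication -> averaging. Every stage reports what it
# rejected and why; entries are never silently dropped.

#' Curation configuration
#'
#' Collects the thresholds used throughout the curation pipeline.
#'
#' @param pkw Water self-dissociation constant on the log10 scale; pKb
#'   values convert as `pka = pkw - pkb`. Default 14.0.
#' @param cosolvent_max Maximum tolerated cosolvent volume fraction.
#'   Default 0.05 (5 percent).
#' @param outlier_threshold Molecules with any matched experimental vs
#'   predicted deviation strictly greater than this (pKa units) are dropped
#'   within the affected source dataset. Default 4.0.
#' @param temp_window Celsius interval; entries with a known temperature
#'   outside it are excluded from averages. Default `c(15, 40)`.
#' @param dedup_decimals Values are compared after rounding to this many
#'   decimals when detecting cross-source duplicates. Default 2.
#' @param cosolvent_sources Character vector of source datasets the
#'   cosolvent rule applies to, or `NULL` (default) to apply it to every
#'   source. Entries without cosolvent metadata from rule-exempt sources are
#'   always kept.
#' @param nonconventional_pattern Regular expression matched against the
#'   `remark` field; matching entries are rejected as measured under
#'   nonconventional conditions (covalent hydration, excited states,
#'   extreme pressure, missing condition information).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(pkw = 14.0,
                            cosolvent_max = 0.05,
                            outlier_threshold = 4.0,
                            temp_window = c(15, 40),
                            dedup_decimals = 2L,
                            cosolvent_sources = NULL,
                            nonconventional_pattern = "covalent hydration|excited state|extreme pressure|no information|nonconventional") {
  stopifnot(pkw > 0, cosolvent_max > 0, outlier_threshold > 0,
            length(temp_window) == 2L, temp_window[1] < temp_window[2],
            dedup_decimals >= 0L)
  structure(list(pkw = pkw, cosolvent_max = cosolvent_max,
                 outlier_threshold = outlier_threshold,
                 temp_window = temp_window,
                 dedup_decimals = as.integer(dedup_decimals),
                 cosolvent_sources = cosolvent_sources,
                 nonconventional_pattern = nonconventional_pattern),
            class = "curation_config")
}

#' Convert entries to the pKa convention
#'
#' Proton-association constants (pKb) are converted to dissociation
#' constants by subtracting them from the water self-dissociation constant:
#' `pka = pkw - pkb` (default pkw = 14.0). pKa entries pass through
#' unchanged. Entries with any other constant kind are rejected.
#'
#' @param entries Entry tibble from [read_entries()].
#' @param config A [curation_config()].
#' @return A list with `entries` (all `constant_kind == "pKa"`) and
#'   `rejects` (tibble `entry_id`, `reason`).
#' @export
to_pka <- function(entries, config = curation_config()) {
  kind <- entries$constant_kind
  is_pka <- kind == "pKa"
  is_pkb <- kind == "pKb"
  bad <- !(is_pka | is_pkb) | is.na(kind)
  out <- entries[!bad, ]
  conv <- out$constant_kind == "pKb"
  out$pka_value[conv] <- config$pkw - out$pka_value[conv]
  out$constant_kind <- "pKa"
  list(
    entries = out,
    rejects = tibble::tibble(entry_id = entries$entry_id[bad],
                             reason = "unknown constant kind")
  )
}

#' Filter entries on measurement-condition metadata
#'
#' Removes entries measured with more than `cosolvent_max` cosolvent or
#' with unquantified cosolvent content (for the sources the rule applies
#' to), and entries whose remark indicates nonconventional experimental
#' settings. Entries with absent cosolvent metadata are kept: "unknown" is
#' not "out of range".
#'
#' @inheritParams to_pka
#' @return A list with `entries` and `rejects`.
#' @export
metadata_filter <- function(entries, config = curation_config()) {
  in_scope <- if (is.null(config$cosolvent_sources)) {
    rep(TRUE, nrow(entries))
  } else {
    entries$source_dataset %in% config$cosolvent_sources
  }
  reason <- rep(NA_character_, nrow(entries))
  over <- in_scope & !is.na(entries$cosolvent_fraction) &
    entries$cosolvent_fraction > config$cosolvent_max
  unq <- in_scope & entries$cosolvent_unquantified
  reason[over] <- "cosolvent content above threshold"
  reason[is.na(reason) & unq] <- "cosolvent content not quantified"
  nonconv <- is.na(reason) & !is.na(entries$remark) &
    grepl(config$nonconventional_pattern, entries$remark, ignore.case = TRUE)
  reason[nonconv] <- "nonconventional experimental conditions"
  keep <- is.na(reason)
  list(entries = entries[keep, ],
       rejects = tibble::tibble(entry_id = entries$entry_id[!keep],
                                reason = reason[!keep]))
}

#' Assign charge-state transitions to one molecule's entries
#'
#' Matches the experimental values of a single molecule (within one source
#' dataset) against a predicted reference ladder and annotates each entry
#' with the charge-state transition of its matched rung.
#'
#' Strategies: `"order_preserving"` assumes distinct values belong to
#' distinct transitions and runs [order_preserving_match()];
#' `"closest"` matches every value independently to its nearest rung;
#' `"typed_grouped"` trusts type labels (`pKa1`, `pKa2`, ...) when they pass
#' [typed_group_check()], matching the group means order-preservingly and
#' propagating each group's transition to its members, and falls back to
#' closest-value matching per entry when the check fails.
#'
#' @param values Numeric experimental pKa values of one molecule.
#' @param ladder Reference ladder tibble from [macro_ladder()] (columns
#'   `charge_high`, `charge_low`, `value`, ascending).
#' @param strategy One of `"order_preserving"`, `"closest"`,
#'   `"typed_grouped"`.
#' @param type_labels Character vector parallel to `values`; required for
#'   `"typed_grouped"`.
#' @return A tibble parallel to `values` with columns `charge_high`,
#'   `charge_low`, `matched_value` and `deviation` (predicted −
#'   experimental), plus an attribute `fallback` indicating whether the
#'   typed-group check failed.
#' @export
assign_transitions <- function(values, ladder,
                               strategy = c("order_preserving", "closest", "typed_grouped"),
                               type_labels = NULL) {
  strategy <- rlang::arg_match(strategy)
  stopifnot(length(values) >= 1L)
  lad_vals <- ladder$value
  result <- tibble::tibble(
    charge_high = rep(NA_integer_, length(values)),
    charge_low = rep(NA_integer_, length(values)),
    matched_value = rep(NA_real_, length(values)),
    deviation = rep(NA_real_, length(values))
  )
  fill <- function(res, idx, rung) {
    res$charge_high[idx] <- ladder$charge_high[rung]
    res$charge_low[idx] <- ladder$charge_low[rung]
    res$matched_value[idx] <- ladder$value[rung]
    res$deviation[idx] <- ladder$value[rung] - values[idx]
    res
  }
  fallback <- FALSE
  if (strategy == "closest" || length(values) == 1L && strategy != "typed_grouped") {
    for (i in seq_along(values)) {
      a <- closest_match(values[i], lad_vals)
      result <- fill(result, i, a$pairs$ladder_index[1])
    }
  } else if (strategy == "order_preserving") {
    dedup_vals <- sort(unique(values))
    if (length(lad_vals) < length(dedup_vals)) {
      infeasible("ladder insufficiently enumerated for the distinct experimental values")
    }
    a <- order_preserving_match(dedup_vals, lad_vals)
    for (i in seq_along(values)) {
      pos <- match(values[i], dedup_vals)
      rung <- a$pairs$ladder_index[a$pairs$exp_index == pos]
      result <- fill(result, i, rung)
    }
  } else {
    if (is.null(type_labels) || length(type_labels) != length(values)) {
      rlang::abort("typed_grouped strategy requires type_labels",
                   class = "pkaladder_usage_error")
    }
    groups <- split(values, type_labels)
    check <- typed_group_check(groups)
    if (check$pass && length(lad_vals) >= length(groups)) {
      means <- vapply(groups, mean, numeric(1))
      ord <- order(means)
      a <- order_preserving_match(means[ord], lad_vals)
      for (g in seq_along(ord)) {
        lab <- names(groups)[ord[g]]
        rung <- a$pairs$ladder_index[a$pairs$exp_index == g]
        result <- fill(result, which(type_labels == lab), rung)
      }
    } else {
      fallback <- TRUE
      for (i in seq_along(values)) {
        a <- closest_match(values[i], lad_vals)
        result <- fill(result, i, a$pairs$ladder_index[1])
      }
    }
  }
  attr(result, "fallback") <- fallback
  result
}

#' Decide whether a matched molecule is an outlier
#'
#' A molecule (within one source dataset) is dropped when at least one
#' matched experimental vs predicted pair deviates by strictly more than
#' the configured threshold — such values are likely misannotated or
#' erroneous.
#'
#' @param deviations Numeric matched deviations of one molecule.
#' @inheritParams to_pka
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
outlier_keep <- function(deviations, config = curation_config()) {
  all(abs(deviations) <= config$outlier_threshold)
}

#' Cross-source deduplication of per-transition values
#'
#' Several sources may propagate the same measurement. For one molecule and
#' one charge-state transition, a value (compared after rounding to
#' `dedup_decimals`) that appears in two or more source datasets is counted
#' only as many times as its minimum occurrence count in any of those
#' sources; values confined to a single source keep their count as-is. Rows
#' are retained from the minimum-count source so the operation is
#' idempotent.
#'
#' @param values_by_source Tibble with columns `source` and `value` (all
#'   rows one molecule, one transition), or a named list of numeric
#'   vectors.
#' @inheritParams to_pka
#' @return A tibble of the surviving rows with at least the columns
#'   `source` and `value`; any additional input columns are preserved.
#' @export
deduplicate <- function(values_by_source, config = curation_config()) {
  df <- if (is.data.frame(values_by_source)) {
    tibble::as_tibble(values_by_source)
  } else {
    tibble::tibble(
      source = rep(names(values_by_source), lengths(values_by_source)),
      value = unlist(values_by_source, use.names = FALSE)
    )
  }
  if (nrow(df) == 0L) return(df)
  df$.rounded <- round(df$value, config$dedup_decimals)
  kept <- lapply(split(df, df$.rounded), function(grp) {
    counts <- table(grp$source)
    if (length(counts) >= 2L) {
      keep_n <- min(counts)
      src <- sort(names(counts)[counts == keep_n])[1]
      grp[grp$source == src, ][seq_len(keep_n), ]
    } else {
      grp
    }
  })
  out <- dplyr::bind_rows(kept)
  out$.rounded <- NULL
  tibble::as_tibble(out[order(out$source, out$value), ])
}

#' Average per-transition values within the temperature window
#'
#' Arithmetic mean of the surviving values for each charge-state
#' transition. Entries with a known measurement temperature outside
#' `temp_window` are excluded from the mean; entries with unknown
#' temperature are included. A transition whose every value was
#' temperature-excluded is omitted from the averaged map and reported.
#'
#' @param df Tibble with columns `charge_high`, `charge_low`, `value` and
#'   optionally `temperature_c` (all rows one molecule, deduplication
#'   already applied).
#' @inheritParams to_pka
#' @return A list with `averaged` (tibble `charge_high`, `charge_low`,
#'   `mean_pka`, `n_values`) and `omitted` (tibble of transitions whose
#'   values were all excluded).
#' @export
average_transitions <- function(df, config = curation_config()) {
  if (!"temperature_c" %in% names(df)) df$temperature_c <- NA_real_
  df$.in_window <- is.na(df$temperature_c) |
    (df$temperature_c >= config$temp_window[1] &
       df$temperature_c <= config$temp_window[2])
  by_tr <- dplyr::group_by(df, .data$charge_high, .data$charge_low)
  summ <- dplyr::summarise(
    by_tr,
    mean_pka = if (any(.data$.in_window)) mean(.data$value[.data$.in_window]) else NA_real_,
    n_values = sum(.data$.in_window),
    .groups = "drop"
  )
  omitted <- summ[summ$n_values == 0L, c("charge_high", "charge_low")]
  averaged <- summ[summ$n_values > 0L, ]
  list(averaged = averaged[order(averaged$mean_pka), ], omitted = omitted)
}

#' Replicate dispersion statistics
#'
#' For every molecule/transition with at least two experimental values,
#' computes (i) the sample standard deviation and (ii) the largest pairwise
#' difference (max − min), and summarizes both by their means over
#' transitions. These quantify replicate disagreement across sources and
#' methods.
#'
#' @param df Tibble with columns `structure_key`, `charge_high`,
#'   `charge_low`, `value`.
#' @return A list with `per_transition` (tibble adding `n`, `sd`, `range`)
#'   and scalars `mean_sd`, `mean_range`.
#' @export
dispersion_stats <- function(df) {
  by_tr <- dplyr::group_by(df, .data$structure_key, .data$charge_high,
                           .data$charge_low)
  per <- dplyr::summarise(by_tr, n = dplyr::n(),
                          sd = stats::sd(.data$value),
                          range = max(.data$value) - min(.data$value),
                          .groups = "drop")
  per <- per[per$n >= 2L, ]
  list(per_transition = per,
       mean_sd = mean(per$sd),
       mean_range = mean(per$range))
}

#' Run the full curation pipeline
#'
#' Applies, in order: pKb conversion, metadata filtering, per-source
#' transition assignment against the reference ladders, outlier exclusion,
#' cross-source deduplication and per-transition averaging. Bookkeeping is
#' conserved at every stage: each input entry is either carried forward or
#' appears in the reject report with a machine-readable stage and reason.
#'
#' @param entries Entry tibble from [read_entries()].
#' @param ladders Reference ladders: tibble with columns `structure_key`
#'   (or `structure` carrying SMILES), `charge_high`, `charge_low`,
#'   `value`, one ladder per molecule over the enumerated charge window.
#' @param strategy Assignment strategy passed to [assign_transitions()];
#'   either a single string or a named character vector keyed by source
#'   dataset.
#' @inheritParams to_pka
#' @return A list with components `curated` (tibble `structure_key`,
#'   `smiles`, `charge_high`, `charge_low`, `mean_pka`, `n_values`),
#'   `assigned` (per-entry transitions before averaging), `rejects`
#'   (tibble `stage`, `entry_id`, `reason`) and `stage_counts` (entries
#'   entering/kept per stage).
#' @export
curate_entries <- function(entries, ladders, strategy = "order_preserving",
                           config = curation_config()) {
  rejects <- list()
  counts <- list()
  note_stage <- function(stage, n_in, n_kept, rej) {
    counts[[stage]] <<- tibble::tibble(stage = stage, entered = n_in, kept = n_kept)
    if (nrow(rej) > 0) {
      rejects[[length(rejects) + 1L]] <<-
        tibble::tibble(stage = stage, entry_id = rej$entry_id, reason = rej$reason)
    }
  }
  if (!"structure_key" %in% names(ladders)) {
    ladders$structure_key <- canonical_key(ladders$structure)
  }

  # 1. constant conversion
  n_in <- nrow(entries)
  conv <- to_pka(entries, config)
  note_stage("conversion", n_in, nrow(conv$entries), conv$rejects)
  cur <- conv$entries

  # 2. metadata filters
  met <- metadata_filter(cur, config)
  note_stage("metadata", nrow(cur), nrow(met$entries), met$rejects)
  cur <- met$entries

  # 3. transition assignment, per molecule within each source dataset
  no_ladder <- !(cur$structure_key %in% ladders$structure_key)
  note_stage("ladder_lookup", nrow(cur), sum(!no_ladder),
             tibble::tibble(entry_id = cur$entry_id[no_ladder],
                            reason = "no reference ladder"))
  cur <- cur[!no_ladder, ]

  pick_strategy <- function(src) {
    if (length(strategy) == 1L && is.null(names(strategy))) return(strategy)
    if (!is.null(names(strategy)) && src %in% names(strategy)) return(strategy[[src]])
    if (!is.null(names(strategy)) && "default" %in% names(strategy)) return(strategy[["default"]])
    "order_preserving"
  }

  groups <- split(cur, list(cur$structure_key, cur$source_dataset), drop = TRUE)
  assigned_rows <- list()
  assign_rejects <- list()
  for (grp in groups) {
    lad <- ladders[ladders$structure_key == grp$structure_key[1], ]
    lad <- lad[order(lad$value), ]
    strat <- pick_strategy(grp$source_dataset[1])
    res <- tryCatch(
      assign_transitions(grp$pka_value, lad, strategy = strat,
                         type_labels = grp$type_label),
      pkaladder_infeasible_error = function(e) NULL
    )
    if (is.null(res)) {
      assign_rejects[[length(assign_rejects) + 1L]] <- tibble::tibble(
        entry_id = grp$entry_id, reason = "ladder insufficiently enumerated")
      next
    }
    grp$charge_high <- res$charge_high
    grp$charge_low <- res$charge_low
    grp$matched_value <- res$matched_value
    grp$deviation <- res$deviation
    if (!outlier_keep(res$deviation, config)) {
      assign_rejects[[length(assign_rejects) + 1L]] <- tibble::tibble(
        entry_id = grp$entry_id,
        reason = sprintf("matched deviation above %.1f in source dataset",
                         config$outlier_threshold))
      next
    }
    assigned_rows[[length(assigned_rows) + 1L]] <- grp
  }
  assigned <- if (length(assigned_rows) > 0) dplyr::bind_rows(assigned_rows) else cur[0, ]
  arej <- if (length(assign_rejects) > 0) dplyr::bind_rows(assign_rejects) else
    tibble::tibble(entry_id = integer(), reason = character())
  note_stage("assignment_outlier", nrow(cur), nrow(assigned), arej)

  # 4. deduplication + 5. averaging, per molecule/transition
  curated_rows <- list()
  dedup_kept <- 0L
  dedup_rej <- list()
  omitted_rows <- list()
  for (key in unique(assigned$structure_key)) {
    mol <- assigned[assigned$structure_key == key, ]
    mol_kept <- list()
    for (lab in unique(transition_label(mol$charge_high, mol$charge_low))) {
      tr <- parse_transition_label(lab)
      sub <- mol[mol$charge_high == tr$charge_high, ]
      surv <- deduplicate(
        tibble::tibble(source = sub$source_dataset, value = sub$pka_value,
                       entry_id = sub$entry_id,
                       temperature_c = sub$temperature_c),
        config)
      # deduplicate() keeps whole rows; recover dropped entry ids
      kept_ids <- surv$entry_id
      dropped <- setdiff(sub$entry_id, kept_ids)
      if (length(dropped) > 0) {
        dedup_rej[[length(dedup_rej) + 1L]] <- tibble::tibble(
          entry_id = dropped, reason = "cross-source duplicate")
      }
      surv$charge_high <- tr$charge_high
      surv$charge_low <- tr$charge_low
      mol_kept[[length(mol_kept) + 1L]] <- surv
    }
    mol_surv <- dplyr::bind_rows(mol_kept)
    dedup_kept <- dedup_kept + nrow(mol_surv)
    avg <- average_transitions(mol_surv, config)
    if (nrow(avg$omitted) > 0) {
      om <- avg$omitted
      om$structure_key <- key
      omitted_rows[[length(omitted_rows) + 1L]] <- om
    }
    if (nrow(avg$averaged) > 0) {
      out <- avg$averaged
      out$structure_key <- key
      out$smiles <- mol$smiles[1]
      curated_rows[[length(curated_rows) + 1L]] <- out
    }
  }
  drej <- if (length(dedup_rej) > 0) dplyr::bind_rows(dedup_rej) else
    tibble::tibble(entry_id = integer(), reason = character())
  note_stage("deduplication", nrow(assigned), dedup_kept, drej)

  curated <- if (length(curated_rows) > 0) {
    dplyr::bind_rows(curated_rows)[, c("structure_key", "smiles", "charge_high",
                                       "charge_low", "mean_pka", "n_values")]
  } else {
    tibble::tibble(structure_key = character(), smiles = character(),
                   charge_high = integer(), charge_low = integer(),
                   mean_pka = numeric(), n_values = integer())
  }
  list(
    curated = curated,
    assigned = assigned,
    rejects = if (length(rejects) > 0) dplyr::bind_rows(rejects) else
      tibble::tibble(stage = character(), entry_id = integer(), reason = character()),
    stage_counts = dplyr::bind_rows(counts),
    omitted_transitions = if (length(omitted_rows) > 0) dplyr::bind_rows(omitted_rows) else
      tibble::tibble(charge_high = integer(), charge_low = integer(),
                     structure_key = character())
  )
}
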