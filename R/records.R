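#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

# Column layout of an entry table. Mandatory columns must be present in any
# input; the rest are metadata that the curation filters consult when
# available ("unknown" is represented as NA, never as a sentinel number).
entry_mandatory_cols <- c("smiles", "pka_value", "constant_kind", "source_dataset")
entry_optional_cols <- c("type_label", "temperature_c", "ionic_strength_m",
                         "cosolvent_fraction", "remark")

#' Read a table of experimental dissociation-constant entries
#'
#' Parses a CSV/TSV file (or an already-loaded data frame) into the entry
#' tibble the curation pipeline consumes. Each row becomes one entry; rows
#' whose structure cannot be parsed by the cheminformatics toolkit or whose
#' value is not a finite number are collected into a reject report rather
#' than silently dropped.
#'
#' The expected columns are `smiles`, `pka_value`, `constant_kind`
#' (`"pKa"` or `"pKb"`) and `source_dataset`, plus the optional metadata
#' columns `type_label`, `temperature_c`, `ionic_strength_m`,
#' `cosolvent_fraction` (a fraction in `[0, 1]`, or the literal text
#' `"unquantified"`) and `remark`.
#'
#' @param source Path to a delimited text file, or a data frame.
#' @return A list with components
#'   \describe{
#'     \item{entries}{tibble of accepted entries, one per row, with an
#'       `entry_id` and the stereo-stripped `structure_key` added}
#'     \item{rejects}{tibble of rejected rows with columns `row` and
#'       `reason`}
#'   }
#' @export
read_entries <- function(source) {
  raw <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    delim <- if (grepl("\\.tsv$", source, ignore.case = TRUE)) "\t" else ","
    readr::read_delim(source, delim = delim, col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE)
  }
  missing <- setdiff(entry_mandatory_cols, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("entry table is missing mandatory column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "pkaladder_format_error")
  }
  for (col in entry_optional_cols) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }

  n <- nrow(raw)
  smiles <- as.character(raw$smiles)
  value <- suppressWarnings(as.numeric(raw$pka_value))
  cosolv_raw <- raw$cosolvent_fraction
  cosolv_chr <- if (is.character(cosolv_raw)) trimws(cosolv_raw) else as.character(cosolv_raw)
  unquantified <- !is.na(cosolv_chr) & tolower(cosolv_chr) == "unquantified"
  cosolv_num <- suppressWarnings(as.numeric(ifelse(unquantified, NA, cosolv_chr)))

  desc <- chem_descriptors(smiles)
  reason <- rep(NA_character_, n)
  reason[!desc$ok] <- "unparseable structure"
  reason[is.na(reason) & (is.na(value) | !is.finite(value))] <- "unparseable numeric value"
  bad_cosolv <- is.na(reason) & !is.na(cosolv_num) & (cosolv_num < 0 | cosolv_num > 1)
  reason[bad_cosolv] <- "cosolvent fraction outside [0, 1]"

  keep <- is.na(reason)
  entries <- tibble::tibble(
    entry_id = seq_len(n),
    smiles = smiles,
    structure_key = desc$inchi,
    pka_value = value,
    constant_kind = as.character(raw$constant_kind),
    type_label = as.character(raw$type_label),
    temperature_c = suppressWarnings(as.numeric(raw$temperature_c)),
    ionic_strength_m = suppressWarnings(as.numeric(raw$ionic_strength_m)),
    cosolvent_fraction = cosolv_num,
    cosolvent_unquantified = unquantified,
    source_dataset = as.character(raw$source_dataset),
    remark = as.character(raw$remark)
  )[keep, ]
  rejects <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  list(entries = entries, rejects = rejects)
}

#' Charge-state transition labels
#'
#' A charge-state transition is an ordered pair of integer net charges
#' `(q, q - 1)` connected by loss of one proton; exports render it as
#' `"<charge_high> to <charge_low>"`, e.g. `"0 to -1"`.
#'
#' @param charge_high,charge_low Integer net charges of the more and less
#'   protonated states.
#' @return Character vector of labels.
#' @export
transition_label <- function(charge_high, charge_low = charge_high - 1L) {
  stopifnot(all(charge_low == charge_high - 1L))
  paste(as.integer(charge_high), "to", as.integer(charge_low))
}

#' @rdname transition_label
#' @param label Labels produced by `transition_label()`.
#' @return For `parse_transition_label()`, a tibble with columns
#'   `charge_high` and `charge_low`.
#' @export
parse_transition_label <- function(label) {
  parts <- strsplit(label, " to ", fixed = TRUE)
  high <- as.integer(vapply(parts, `[[`, character(1), 1))
  low <- as.integer(vapply(parts, `[[`, character(1), 2))
  if (any(is.na(high) | is.na(low)) || any(low != high - 1L)) {
    rlang::abort("malformed transition label", class = "pkaladder_format_error")
  }
  tibble::tibble(charge_high = high, charge_low = low)
}

# Validate a single transition against the enumerated charge window.
validate_transition <- function(charge_high, charge_low, window = c(-6L, 6L)) {
  if (any(charge_low != charge_high - 1L)) {
    rlang::abort("charge_low must equal charge_high - 1",
                 class = "pkaladder_invariant_error")
  }
  if (any(charge_high > window[2] | charge_low < window[1])) {
    rlang::abort(sprintf("charges outside the enumerated window [%d, %d]",
                         window[1], window[2]),
                 class = "pkaladder_invariant_error")
  }
  invisible(TRUE)
}

#' Construct a macroscopic pKa ladder
#'
#' A ladder is the ascending sequence of a molecule's macroscopic pKa
#' values, each bound to a charge-state transition with strictly decreasing
#' net charge. A *complete* ladder chains: the low charge of one rung is the
#' high charge of the next.
#'
#' @param structure Structure text (SMILES) of the molecule.
#' @param values Ascending numeric macro-pKa values.
#' @param charge_high Integer vector of high charges per rung, or a single
#'   integer giving the top (most protonated, first rung) charge of a
#'   complete ladder.
#' @param source Name of the predictor or reference that produced the ladder.
#' @param complete Whether consecutive rungs must chain.
#' @param charge_window Allowed net-charge window, default `c(-6, 6)`.
#' @return A tibble with columns `structure`, `charge_high`, `charge_low`,
#'   `value`, `source`, ordered by ascending value.
#' @export
macro_ladder <- function(structure, values, charge_high, source = "reference",
                         complete = TRUE, charge_window = c(-6L, 6L)) {
  n <- length(values)
  stopifnot(n >= 1)
  if (length(charge_high) == 1L && n > 1L) {
    charge_high <- seq(as.integer(charge_high), by = -1L, length.out = n)
  }
  charge_high <- as.integer(charge_high)
  charge_low <- charge_high - 1L
  if (is.unsorted(values, strictly = TRUE)) {
    rlang::abort("ladder values must be strictly ascending",
                 class = "pkaladder_invariant_error")
  }
  if (any(diff(charge_high) >= 0)) {
    rlang::abort("ladder charges must be strictly decreasing",
                 class = "pkaladder_invariant_error")
  }
  if (complete && n > 1L && any(charge_low[-n] != charge_high[-1L])) {
    rlang::abort("complete ladder rungs must chain (charge_low[i] == charge_high[i+1])",
                 class = "pkaladder_invariant_error")
  }
  validate_transition(charge_high, charge_low, charge_window)
  tibble::tibble(structure = structure, charge_high = charge_high,
                 charge_low = charge_low, value = as.numeric(values),
                 source = source)
}

#' Write and read curated per-molecule results
#'
#' Serializes a curated table (one row per molecule and charge-state
#' transition, with the averaged pKa) to CSV, JSON or a SMILES list.
#' Averaged values are exported at 2 decimal places — the precision at which
#' pKa data are reported — while full precision is retained in memory.
#' Reading the CSV or JSON back reproduces the averaged values to 2
#' decimals.
#'
#' @param records Curated tibble with columns `structure_key`, `smiles`,
#'   `charge_high`, `charge_low`, `mean_pka` and optionally `n_values`.
#' @param path Output file path.
#' @param format One of `"csv"`, `"json"`, `"smiles"`.
#' @return `path`, invisibly.
#' @export
write_curated <- function(records, path, format = c("csv", "json", "smiles")) {
  format <- rlang::arg_match(format)
  records <- tibble::as_tibble(records)
  if (!"n_values" %in% names(records)) records$n_values <- NA_integer_
  if (format == "csv") {
    out <- tibble::tibble(
      structure_key = records$structure_key,
      smiles = records$smiles,
      transition = transition_label(records$charge_high, records$charge_low),
      mean_pka = round(records$mean_pka, 2),
      n_values = records$n_values
    )
    readr::write_csv(out, path, progress = FALSE)
  } else if (format == "json") {
    split_rows <- split(records, records$structure_key)
    docs <- lapply(split_rows, function(df) {
      list(
        structure_key = df$structure_key[1],
        smiles = df$smiles[1],
        transitions = lapply(seq_len(nrow(df)), function(i) {
          list(transition = transition_label(df$charge_high[i], df$charge_low[i]),
               mean_pka = round(df$mean_pka[i], 2),
               n_values = df$n_values[i])
        })
      )
    })
    jsonlite::write_json(unname(docs), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    writeLines(unique(records$smiles), path)
  }
  invisible(path)
}

#' @rdname write_curated
#' @export
read_curated <- function(path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      structure_key = "c", smiles = "c", transition = "c",
      mean_pka = "d", n_values = "i"
    ), progress = FALSE, show_col_types = FALSE)
    trans <- parse_transition_label(raw$transition)
    tibble::tibble(structure_key = raw$structure_key, smiles = raw$smiles,
                   charge_high = trans$charge_high, charge_low = trans$charge_low,
                   mean_pka = raw$mean_pka, n_values = raw$n_values)
  } else {
    docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    purrr::map_dfr(docs, function(doc) {
      purrr::map_dfr(doc$transitions, function(tr) {
        trans <- parse_transition_label(tr$transition)
        tibble::tibble(structure_key = doc$structure_key, smiles = doc$smiles,
                       charge_high = trans$charge_high,
                       charge_low = trans$charge_low,
                       mean_pka = as.numeric(tr$mean_pka),
                       n_values = if (is.null(tr$n_values)) NA_integer_ else as.integer(tr$n_values))
      })
    })
  }
}
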