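# Bridge to the RDKit cheminformatics toolkit. All structure-level
# primitives (InChI keys, heavy-atom counts, Morgan fingerprints, SMARTS
# matching) are computed by a single batched subprocess call per request;
# results are cached for the session so repeated lookups of the same
# structure are free.

.pkaladder_cache <- new.env(parent = emptyenv())

chem_tool_path <- function() {
  path <- system.file("python", "chem_tools.py", package = "pkaladder")
  if (!nzchar(path)) {
    stop("internal error: chem_tools.py not found in the installed package",
         call. = FALSE)
  }
  path
}

#' Low-level batched call into the RDKit backend
#'
#' @param smiles Character vector of SMILES strings.
#' @param want Subset of `c("inchi", "heavy", "fp")`.
#' @param smarts Optional list of `list(name =, pattern =)` SMARTS queries.
#' @param fp_radius,fp_bits Circular fingerprint parameters.
#' @return A list with one record per structure; unparseable structures
#'   yield `list(ok = FALSE)`.
#' @noRd
run_chem_tool <- function(smiles, want = character(), smarts = NULL,
                          fp_radius = 4L, fp_bits = 2048L) {
  req <- list(
    smiles = as.list(as.character(smiles)),
    want = as.list(want),
    fp_radius = fp_radius,
    fp_bits = fp_bits
  )
  if (!is.null(smarts)) req$smarts <- smarts
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, null = "null")
  out <- tryCatch(
    suppressWarnings(system2("python", shQuote(chem_tool_path()),
                             input = payload, stdout = TRUE, stderr = TRUE)),
    error = function(e) {
      stop("failed to run the python/RDKit backend: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  status <- attr(out, "status")
  if (!is.null(status) && status == 2L) {
    rlang::abort(paste("invalid substructure pattern library:",
                       paste(out, collapse = " ")),
                 class = "pkaladder_config_error")
  }
  if (!is.null(status) && status != 0L) {
    stop("RDKit backend failed (exit ", status, "): ",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# Cached InChI + heavy-atom lookup. Returns a tibble aligned with `smiles`:
# columns smiles, ok, inchi, heavy_atoms.
chem_descriptors <- function(smiles) {
  smiles <- as.character(smiles)
  if (is.null(.pkaladder_cache$desc)) .pkaladder_cache$desc <- new.env(parent = emptyenv())
  cache <- .pkaladder_cache$desc
  uniq <- unique(smiles[!is.na(smiles) & nzchar(smiles)])
  missing <- uniq[!vapply(uniq, function(s) !is.null(cache[[s]]), logical(1))]
  if (length(missing) > 0) {
    recs <- run_chem_tool(missing, want = c("inchi", "heavy"))
    for (i in seq_along(missing)) {
      rec <- recs[[i]]
      cache[[missing[i]]] <- if (isTRUE(rec$ok)) {
        list(ok = TRUE, inchi = rec$inchi, heavy_atoms = as.integer(rec$heavy_atoms))
      } else {
        list(ok = FALSE, inchi = NA_character_, heavy_atoms = NA_integer_)
      }
    }
  }
  rows <- lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(list(ok = FALSE, inchi = NA_character_, heavy_atoms = NA_integer_))
    }
    cache[[s]]
  })
  tibble::tibble(
    smiles = smiles,
    ok = vapply(rows, `[[`, logical(1), "ok"),
    inchi = vapply(rows, `[[`, character(1), "inchi"),
    heavy_atoms = vapply(rows, `[[`, integer(1), "heavy_atoms")
  )
}

#' Canonical stereochemistry-free structure key
#'
#' Computes a standard InChI for each structure after removing all
#' stereochemistry descriptors, so that stereoisomers and different
#' atom-ordered drawings of the same molecule share one key. Keys are the
#' basis for cross-dataset deduplication and fine-tune overlap removal.
#'
#' @param structure Character vector of SMILES strings.
#' @param strict If `TRUE` (default), an unparseable structure is an error;
#'   if `FALSE`, it yields `NA`.
#' @return Character vector of InChI keys (same length as `structure`).
#' @examples
#' \dontrun{
#' canonical_key("CCO") == canonical_key("OCC")
#' }
#' @export
canonical_key <- function(structure, strict = TRUE) {
  desc <- chem_descriptors(structure)
  if (strict && any(!desc$ok)) {
    bad <- structure[!desc$ok]
    rlang::abort(
      paste0("unparseable structure(s): ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "pkaladder_structure_error"
    )
  }
  ifelse(desc$ok, desc$inchi, NA_character_)
}

#' Heavy-atom counts for a set of structures
#'
#' @inheritParams canonical_key
#' @return Integer vector; `NA` for unparseable structures when
#'   `strict = FALSE`.
#' @export
heavy_atom_count <- function(structure, strict = TRUE) {
  desc <- chem_descriptors(structure)
  if (strict && any(!desc$ok)) {
    rlang::abort("unparseable structure", class = "pkaladder_structure_error")
  }
  desc$heavy_atoms
}
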