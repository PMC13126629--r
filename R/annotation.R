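# Structure-level descriptors: circular fingerprints and Tanimoto
# similarity summaries, titratable-group annotation by substructure
# search, and macro-state speciation as a function of pH.

#' Morgan fingerprints
#'
#' Circular (Morgan) fingerprints of radius 4 folded to 2048 bits,
#' computed by the cheminformatics toolkit. Returned as sorted integer
#' vectors of on-bit positions (0-based), cached per session.
#'
#' @param structure Character vector of SMILES.
#' @param radius,n_bits Fingerprint parameters.
#' @return A list of integer vectors, one per structure.
#' @export
fingerprint <- function(structure, radius = 4L, n_bits = 2048L) {
  key_of <- function(s) paste(s, radius, n_bits, sep = "\r")
  if (is.null(.pkaladder_cache$fp)) .pkaladder_cache$fp <- new.env(parent = emptyenv())
  cache <- .pkaladder_cache$fp
  uniq <- unique(structure)
  missing <- uniq[!vapply(uniq, function(s) !is.null(cache[[key_of(s)]]), logical(1))]
  if (length(missing) > 0) {
    recs <- run_chem_tool(missing, want = "fp", fp_radius = radius, fp_bits = n_bits)
    for (i in seq_along(missing)) {
      rec <- recs[[i]]
      if (!isTRUE(rec$ok)) {
        rlang::abort(paste("unparseable structure:", missing[i]),
                     class = "pkaladder_structure_error")
      }
      cache[[key_of(missing[i])]] <- sort(as.integer(unlist(rec$fp_bits)))
    }
  }
  lapply(structure, function(s) cache[[key_of(s)]])
}

#' Tanimoto similarity of two bit fingerprints
#'
#' Intersection over union of the on-bit sets; 1 for identical
#' fingerprints, 0 for disjoint ones.
#'
#' @param fp_a,fp_b Integer vectors of on-bit positions.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) == 0 && length(fp_b) == 0) return(1)
  inter <- length(intersect(fp_a, fp_b))
  inter / (length(fp_a) + length(fp_b) - inter)
}

# All-pairs Tanimoto between two fingerprint lists (rows = a, cols = b).
tanimoto_matrix <- function(fps_a, fps_b) {
  outer(seq_along(fps_a), seq_along(fps_b),
        Vectorize(function(i, j) tanimoto(fps_a[[i]], fps_b[[j]])))
}

#' Cross-set similarity
#'
#' Mean, over the molecules of the smaller set, of each molecule's maximum
#' Tanimoto similarity to any molecule of the partner set. When the sets
#' have equal size the first argument is iterated over.
#'
#' @param set_a,set_b Character vectors of SMILES (non-empty).
#' @return A number in `[0, 1]`.
#' @export
set_similarity <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    rlang::abort("both sets must be non-empty", class = "pkaladder_usage_error")
  }
  if (length(set_b) < length(set_a)) {
    tmp <- set_a; set_a <- set_b; set_b <- tmp
  }
  sims <- tanimoto_matrix(fingerprint(set_a), fingerprint(set_b))
  mean(apply(sims, 1, max))
}

#' Self-similarity of a molecule set
#'
#' Mean over the set's molecules of the maximum Tanimoto similarity to any
#' *other* member; a measure of internal redundancy.
#'
#' @param set Character vector of at least two SMILES.
#' @return A number in `[0, 1]`.
#' @export
self_similarity <- function(set) {
  if (length(set) < 2) {
    rlang::abort("self-similarity needs at least two molecules",
                 class = "pkaladder_usage_error")
  }
  sims <- tanimoto_matrix(fingerprint(set), fingerprint(set))
  diag(sims) <- -Inf
  mean(apply(sims, 1, max))
}

#' Load a titratable-group pattern library
#'
#' The library is a tab-separated text file with columns `name`, `pattern`
#' (SMARTS) and `tag` (`acidic` or `basic`). The default shipped library
#' covers carboxylic acids, phenols, sulfonamides, thiols, 1,3-dicarbonyl
#' carbon acids, tetrazoles, aliphatic amines, basic aromatic nitrogens and
#' amidines/guanidines; it is deliberately editable because no single
#' SMARTS set captures every convention.
#'
#' @param path Path to a library file; default is the shipped library.
#' @return A tibble with columns `name`, `pattern`, `tag`.
#' @export
load_pattern_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "titratable_groups.tsv", package = "pkaladder")
  }
  lib <- readr::read_tsv(path, col_types = "ccc", progress = FALSE,
                         show_col_types = FALSE)
  if (!all(c("name", "pattern", "tag") %in% names(lib)) ||
      !all(lib$tag %in% c("acidic", "basic"))) {
    rlang::abort("pattern library must have columns name/pattern/tag with tags acidic|basic",
                 class = "pkaladder_config_error")
  }
  lib
}

#' Titratable-group annotation
#'
#' Counts substructure matches of each library pattern in each molecule and
#' labels the molecule `"acidic"`, `"basic"`, `"both"` or `"other"` from
#' the tags of the matched categories (`"other"` = no conventional
#' titratable group matched).
#'
#' @param structure Character vector of SMILES.
#' @param library A pattern library from [load_pattern_library()].
#' @return A tibble with one row per structure: `smiles`, one count column
#'   per category, and `label`.
#' @export
titratable_groups <- function(structure, library = load_pattern_library()) {
  smarts <- lapply(seq_len(nrow(library)), function(i) {
    list(name = library$name[i], pattern = library$pattern[i])
  })
  recs <- run_chem_tool(structure, smarts = smarts)
  counts <- matrix(0L, nrow = length(structure), ncol = nrow(library),
                   dimnames = list(NULL, library$name))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    if (!isTRUE(rec$ok)) {
      rlang::abort(paste("unparseable structure:", structure[i]),
                   class = "pkaladder_structure_error")
    }
    counts[i, ] <- as.integer(unlist(rec$matches[library$name]))
  }
  has_acid <- rowSums(counts[, library$tag == "acidic", drop = FALSE]) > 0
  has_base <- rowSums(counts[, library$tag == "basic", drop = FALSE]) > 0
  label <- dplyr::case_when(
    has_acid & has_base ~ "both",
    has_acid ~ "acidic",
    has_base ~ "basic",
    TRUE ~ "other"
  )
  out <- tibble::as_tibble(as.data.frame(counts))
  out <- dplyr::bind_cols(tibble::tibble(smiles = structure), out)
  out$label <- label
  out
}

#' Macroscopic charge-state populations versus pH
#'
#' Equilibrium fractions of the macro charge states of a molecule with the
#' given ascending macro-pKa ladder at a given pH. Relative to the most
#' protonated state (weight 1), each deprotonation across the rung with
#' constant `pKa_i` multiplies the weight by `10^(pH - pKa_i)`
#' (Henderson–Hasselbalch); fractions are normalized to sum to 1. Computed
#' in log space for numerical stability.
#'
#' @param ladder Ascending numeric macro-pKa values (`n` rungs give
#'   `n + 1` states).
#' @param pH A single finite pH value.
#' @param charge_high Optional integer charge of the most protonated state;
#'   used to name the result.
#' @return Numeric vector of `length(ladder) + 1` fractions summing to 1,
#'   ordered from most to least protonated.
#' @export
macrostate_populations <- function(ladder, pH, charge_high = NULL) {
  stopifnot(is.finite(pH), length(ladder) >= 1L)
  if (is.unsorted(ladder, strictly = TRUE)) {
    rlang::abort("ladder values must be strictly ascending",
                 class = "pkaladder_invariant_error")
  }
  log_w <- c(0, cumsum(pH - ladder))
  w <- 10^(log_w - max(log_w))
  frac <- w / sum(w)
  if (!is.null(charge_high)) {
    names(frac) <- as.character(seq(as.integer(charge_high), by = -1L,
                                    length.out = length(frac)))
  }
  frac
}
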