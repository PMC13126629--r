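# Seeded generator of synthetic molecules, true macro-pKa ladders, noisy
# experimental replicates and imperfect predictor ladders. It emulates the
# statistical structure the curation and matching stages assume — ascending
# ladders with a minimum spacing, replicate scatter, experimentally
# undetected transitions (gaps) and predictor noise with occasional
# spurious rungs — without modelling any structure-activity relationship.

#' Synthetic-data configuration
#'
#' @param n_molecules Number of molecules to generate.
#' @param rungs Integer vector of possible true rung counts per molecule
#'   (sampled uniformly). Default `1:5`.
#' @param min_spacing Minimum gap between adjacent true pKa values (pKa
#'   units). Default 1.0.
#' @param value_range Interval the true values are drawn from. Default
#'   `c(0, 14)`.
#' @param sigma_exp Gaussian noise scale of experimental replicates, in pKa
#'   units. Default 0.2, matching typical cross-source replicate scatter.
#' @param replicates Integer vector of possible replicate counts per
#'   detected transition (sampled uniformly). Default `1:4`.
#' @param dropout_p Probability that a true transition goes experimentally
#'   undetected (a "gap"). Default 0.1.
#' @param sigma_pred Gaussian noise scale of the predictor's values.
#'   Default 0.5.
#' @param spurious_p Probability that the predictor ladder gains one extra
#'   (spurious) rung. Default 0.1.
#' @param seed Integer seed; the full output is reproducible per seed, and
#'   molecule `i` is generated from a counter-derived substream so it does
#'   not depend on `n_molecules`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 100L, rungs = 1:5,
                             min_spacing = 1.0, value_range = c(0, 14),
                             sigma_exp = 0.2, replicates = 1:4,
                             dropout_p = 0.1, sigma_pred = 0.5,
                             spurious_p = 0.1, seed = 1L) {
  stopifnot(n_molecules >= 1, all(rungs >= 1), min_spacing > 0,
            length(value_range) == 2L, value_range[1] < value_range[2],
            sigma_exp >= 0, sigma_pred >= 0,
            dropout_p >= 0, dropout_p <= 1, spurious_p >= 0, spurious_p <= 1,
            all(replicates >= 1))
  if ((max(rungs) - 1) * min_spacing > diff(value_range)) {
    rlang::abort(sprintf(
      "infeasible: %d rungs with spacing %.2f cannot fit in [%g, %g]",
      max(rungs), min_spacing, value_range[1], value_range[2]),
      class = "pkaladder_config_error")
  }
  structure(list(n_molecules = as.integer(n_molecules), rungs = as.integer(rungs),
                 min_spacing = min_spacing, value_range = value_range,
                 sigma_exp = sigma_exp, replicates = as.integer(replicates),
                 dropout_p = dropout_p, sigma_pred = sigma_pred,
                 spurious_p = spurious_p, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Deterministic synthetic structure
#'
#' Maps an index to a unique, parseable small-molecule SMILES with 6–50
#' heavy atoms: a carboxylic-acid head plus a linear heteroatom tail whose
#' C/N/O sequence encodes the index in base 3. Distinct indices give
#' distinct constitutional isomers, hence distinct structure keys.
#'
#' @param index Non-negative integer vector.
#' @return Character vector of SMILES.
#' @export
structure_stub <- function(index) {
  vapply(as.integer(index), function(i) {
    stopifnot(i >= 0)
    width <- max(8L, as.integer(ceiling(log(i + 2) / log(3))))
    digits <- integer(width)
    x <- i
    for (p in seq_len(width)) {
      digits[p] <- x %% 3L
      x <- x %/% 3L
    }
    paste0("OC(=O)C", paste(c("C", "N", "O")[digits + 1L], collapse = ""))
  }, character(1))
}

# Counter-derived per-molecule seed, independent of n_molecules and well
# below 2^31.
molecule_seed <- function(seed, i) {
  as.integer((as.numeric(seed %% 100000L) * 20011 + as.numeric(i) * 7919) %% 2147483647)
}

draw_spaced_values <- function(n, range, spacing) {
  repeat {
    v <- sort(stats::runif(n, range[1], range[2]))
    if (n == 1L || min(diff(v)) >= spacing) return(v)
  }
}

#' Generate a synthetic study
#'
#' Produces, per molecule: a true macro-pKa ladder (ascending values with
#' spacing at least `min_spacing`, strictly descending chained charges),
#' noisy experimental replicate entries with transitions dropped at
#' `dropout_p`, and a predictor ladder with Gaussian noise `sigma_pred`
#' plus an occasional spurious rung. The ground-truth assignment (which
#' entry and which predicted rung came from which true transition) is
#' recorded. Byte-identical output per seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with tibbles `truth` (`molecule_id`, `smiles`, `rung`,
#'   `charge_high`, `charge_low`, `true_pka`), `entries` (experimental
#'   entry schema plus `molecule_id` and `true_rung`), `predicted`
#'   (`molecule_id`, `smiles`, `predictor`, `position`, `charge_high`,
#'   `charge_low`, `predicted_pka`, `true_rung` — `NA` for spurious rungs)
#'   and the `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  truth <- vector("list", config$n_molecules)
  entries <- vector("list", config$n_molecules)
  predicted <- vector("list", config$n_molecules)
  next_entry_id <- 1L

  for (i in seq_len(config$n_molecules)) {
    set.seed(molecule_seed(config$seed, i))
    smi <- structure_stub(i - 1L)
    n_rungs <- if (length(config$rungs) == 1L) config$rungs else sample(config$rungs, 1L)
    values <- draw_spaced_values(n_rungs, config$value_range, config$min_spacing)
    q_top <- sample(0:min(n_rungs, 2L), 1L)
    charges_high <- seq(q_top, by = -1L, length.out = n_rungs)
    truth[[i]] <- tibble::tibble(
      molecule_id = i, smiles = smi, rung = seq_len(n_rungs),
      charge_high = charges_high, charge_low = charges_high - 1L,
      true_pka = values)

    detected <- which(stats::runif(n_rungs) >= config$dropout_p)
    if (length(detected) > 0) {
      n_rep <- if (length(config$replicates) == 1L) {
        rep(config$replicates, length(detected))
      } else {
        sample(config$replicates, length(detected), replace = TRUE)
      }
      rung_of <- rep(detected, n_rep)
      vals <- values[rung_of] + stats::rnorm(length(rung_of), 0, config$sigma_exp)
      ent <- tibble::tibble(
        molecule_id = i, smiles = smi, pka_value = vals,
        constant_kind = "pKa", type_label = NA_character_,
        temperature_c = 25, ionic_strength_m = NA_real_,
        cosolvent_fraction = NA_real_, cosolvent_unquantified = FALSE,
        source_dataset = "synthetic", remark = NA_character_,
        true_rung = rung_of)
      ent$entry_id <- seq(next_entry_id, length.out = nrow(ent))
      next_entry_id <- next_entry_id + nrow(ent)
      entries[[i]] <- ent
    }

    pred_vals <- values + stats::rnorm(n_rungs, 0, config$sigma_pred)
    pred_rung <- seq_len(n_rungs)
    if (stats::runif(1) < config$spurious_p) {
      pred_vals <- c(pred_vals, stats::runif(1, config$value_range[1], config$value_range[2]))
      pred_rung <- c(pred_rung, NA_integer_)
    }
    ord <- order(pred_vals)
    pred_vals <- pred_vals[ord]
    pred_rung <- pred_rung[ord]
    # anchor charges so the first true rung keeps its true transition
    first_true <- which(!is.na(pred_rung))[1]
    q_anchor <- charges_high[pred_rung[first_true]] + (first_true - 1L)
    ch <- seq(q_anchor, by = -1L, length.out = length(pred_vals))
    predicted[[i]] <- tibble::tibble(
      molecule_id = i, smiles = smi, predictor = "synthetic_predictor",
      position = seq_along(pred_vals), charge_high = ch, charge_low = ch - 1L,
      predicted_pka = pred_vals, true_rung = pred_rung)
  }

  list(truth = dplyr::bind_rows(truth),
       entries = dplyr::bind_rows(entries),
       predicted = dplyr::bind_rows(predicted),
       config = config)
}

#' Score assignment recovery on synthetic data
#'
#' For every molecule with at least one detected transition, averages the
#' replicates of each observed transition, matches the resulting ascending
#' experimental values onto the predictor ladder with the requested
#' algorithm, and checks whether every observed transition was assigned to
#' the predictor rung generated from the same true transition.
#'
#' @param sim Output of [generate_synthetic()].
#' @param mode `"order_preserving"` or `"window"`.
#' @return A tibble with one row per scored molecule: `molecule_id`,
#'   `n_observed` and `correct`.
#' @export
recover_assignments <- function(sim, mode = c("order_preserving", "window")) {
  mode <- rlang::arg_match(mode)
  match_fun <- if (mode == "order_preserving") order_preserving_match else window_match
  ent_by_mol <- split(sim$entries, sim$entries$molecule_id)
  lad_by_mol <- split(sim$predicted, sim$predicted$molecule_id)
  out <- list()
  for (id in names(ent_by_mol)) {
    ent <- ent_by_mol[[id]]
    means <- vapply(split(ent$pka_value, ent$true_rung), mean, numeric(1))
    obs <- tibble::tibble(true_rung = as.integer(names(means)), value = unname(means))
    obs <- obs[order(obs$value), ]
    lad <- lad_by_mol[[id]]
    lad <- lad[order(lad$predicted_pka), ]
    if (nrow(lad) < nrow(obs)) next
    a <- match_fun(obs$value, lad$predicted_pka)
    matched_rung <- lad$true_rung[a$pairs$ladder_index]
    correct <- !anyNA(matched_rung) && all(matched_rung == obs$true_rung)
    out[[length(out) + 1L]] <- tibble::tibble(
      molecule_id = as.integer(id), n_observed = nrow(obs), correct = correct)
  }
  dplyr::bind_rows(out)
}
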