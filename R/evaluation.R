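# Scoring of predictor output ladders against the benchmark sets, and the
# ANOVA + five-test post-hoc majority vote used to decide which predictor
# pairs differ significantly in absolute error.

#' Match one molecule's predictions for evaluation
#'
#' Dispatches on the benchmark class: monoprotic molecules use
#' [closest_match()] (one value), amphoteric molecules use
#' [pairwise_match()] (two values, linear assignment), polyprotic molecules
#' use [order_preserving_match()]. Returns signed deviations with the
#' convention predicted − experimental. An absent or under-enumerated
#' ladder is an exception: the molecule is recorded, no deviations are
#' emitted.
#'
#' @param exp_values The molecule's averaged experimental pKa values.
#' @param ladder Numeric vector of the predictor's macro-pKa values.
#' @param set_label One of `"monoprotic"`, `"amphoteric"`, `"polyprotic"`.
#' @return Numeric vector of signed deviations, or `NULL` when the
#'   prediction is insufficient (exception).
#' @export
match_for_evaluation <- function(exp_values, ladder,
                                 set_label = c("monoprotic", "amphoteric", "polyprotic")) {
  set_label <- rlang::arg_match(set_label)
  n <- length(exp_values)
  if (length(ladder) < n || length(ladder) == 0) return(NULL)
  a <- switch(set_label,
    monoprotic = closest_match(exp_values[1], ladder),
    amphoteric = pairwise_match(exp_values, ladder),
    polyprotic = order_preserving_match(exp_values, ladder)
  )
  a$pairs$deviation
}

#' Summarize matched deviations
#'
#' Computes the mean absolute error, the root mean squared error and a
#' histogram of absolute errors over left-closed, right-open bins (the
#' final bin is open-ended).
#'
#' @param deviations Signed deviations (predicted − experimental).
#' @param bin_edges Ascending finite bin edges; absolute errors are counted
#'   in `[e_i, e_{i+1})` with a final `[e_last, Inf)` bin.
#' @param predictor,set_label Names carried into the result.
#' @return A list of class `evaluation_result` with fields `predictor`,
#'   `set_label`, `n`, `mae`, `rmse`, `bins` (named counts) and the raw
#'   `deviations`.
#' @export
summarize_errors <- function(deviations, bin_edges = c(0, 0.5, 1, 2, 3),
                             predictor = NA_character_,
                             set_label = NA_character_) {
  if (length(deviations) == 0) {
    rlang::abort(sprintf("no matched deviations for predictor '%s' on set '%s'",
                         predictor, set_label),
                 class = "pkaladder_usage_error")
  }
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE), all(is.finite(bin_edges)))
  abs_err <- abs(deviations)
  idx <- findInterval(abs_err, bin_edges)
  # errors below the first edge (possible when bin_edges[1] > 0) fall in
  # an implicit leading bin; with the default edges idx >= 1 always.
  labels <- c(
    if (bin_edges[1] > 0) sprintf("[0, %g)", bin_edges[1]),
    sprintf("[%g, %g)", utils::head(bin_edges, -1), utils::tail(bin_edges, -1)),
    sprintf("[%g, Inf)", bin_edges[length(bin_edges)])
  )
  offset <- if (bin_edges[1] > 0) 1L else 0L
  counts <- tabulate(idx + offset, nbins = length(labels))
  names(counts) <- labels
  structure(list(
    predictor = predictor, set_label = set_label,
    n = length(deviations),
    mae = mean(abs_err),
    rmse = sqrt(mean(deviations^2)),
    bins = counts,
    deviations = deviations
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s on %s: n = %d, MAE = %.3f, RMSE = %.3f\n",
              x$predictor, x$set_label, x$n, x$mae, x$rmse))
  print(x$bins)
  invisible(x)
}

#' Evaluate predictor ladders against benchmark sets
#'
#' For every predictor and benchmark set, matches each molecule's averaged
#' experimental values to the predictor's ladder (per
#' [match_for_evaluation()]), collects signed deviations, and summarizes
#' MAE/RMSE/bins plus the exception rate — the fraction of the set's
#' molecules for which the predictor produced no or too few values.
#'
#' @param sets Named list of curated tibbles (`monoprotic`, `amphoteric`,
#'   `polyprotic`), as produced by [build_benchmarks()].
#' @param predictions Tibble of predictor ladders with columns
#'   `structure_key` (or `smiles`), `charge_high`, `charge_low`,
#'   `predicted_pka`, `predictor`.
#' @param bin_edges Passed to [summarize_errors()].
#' @return A list with `results` (list of `evaluation_result`), `summary`
#'   (tibble: predictor, set, n, mae, rmse, exception_rate) and
#'   `exceptions` (tibble of unprocessed molecules).
#' @export
evaluate_predictors <- function(sets, predictions, bin_edges = c(0, 0.5, 1, 2, 3)) {
  if (!"structure_key" %in% names(predictions)) {
    predictions$structure_key <- canonical_key(predictions$smiles)
  }
  results <- list()
  exceptions <- list()
  summary_rows <- list()
  for (pred in unique(predictions$predictor)) {
    pred_rows <- predictions[predictions$predictor == pred, ]
    for (set_label in names(sets)) {
      set_df <- sets[[set_label]]
      keys <- unique(set_df$structure_key)
      if (length(keys) == 0) next
      devs <- list()
      n_exc <- 0L
      for (key in keys) {
        exp_values <- sort(set_df$mean_pka[set_df$structure_key == key])
        ladder <- sort(pred_rows$predicted_pka[pred_rows$structure_key == key])
        d <- match_for_evaluation(exp_values, ladder, set_label)
        if (is.null(d)) {
          n_exc <- n_exc + 1L
          exceptions[[length(exceptions) + 1L]] <- tibble::tibble(
            predictor = pred, set_label = set_label, structure_key = key)
        } else {
          devs[[length(devs) + 1L]] <- d
        }
      }
      if (length(devs) == 0) next
      res <- summarize_errors(unlist(devs), bin_edges, predictor = pred,
                              set_label = set_label)
      res$exception_rate <- n_exc / length(keys)
      results[[paste(pred, set_label, sep = ".")]] <- res
      summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
        predictor = pred, set_label = set_label, n = res$n,
        mae = res$mae, rmse = res$rmse, exception_rate = res$exception_rate)
    }
  }
  list(
    results = results,
    summary = if (length(summary_rows) > 0) dplyr::bind_rows(summary_rows) else
      tibble::tibble(predictor = character(), set_label = character(),
                     n = integer(), mae = numeric(), rmse = numeric(),
                     exception_rate = numeric()),
    exceptions = if (length(exceptions) > 0) dplyr::bind_rows(exceptions) else
      tibble::tibble(predictor = character(), set_label = character(),
                     structure_key = character())
  )
}

#' Exception rate of a predictor over a molecule universe
#'
#' Fraction of molecules the predictor cannot process: no ladder at all, or
#' fewer predicted values than experimental values.
#'
#' @param n_exp Named integer vector: experimental value count per
#'   structure key (the universe).
#' @param n_pred Named integer vector: predicted value count per structure
#'   key; missing names count as zero predictions.
#' @return A fraction in `[0, 1]`.
#' @export
exception_rate <- function(n_exp, n_pred) {
  stopifnot(length(n_exp) >= 1L, !is.null(names(n_exp)))
  got <- n_pred[names(n_exp)]
  got[is.na(got)] <- 0L
  mean(got < n_exp)
}

# ---- post-hoc machinery -------------------------------------------------

# Pooled one-way ANOVA pieces shared by the Scheffé and Tukey tests.
pooled_anova <- function(samples) {
  k <- length(samples)
  ns <- lengths(samples)
  means <- vapply(samples, mean, numeric(1))
  big_n <- sum(ns)
  mse <- sum(vapply(samples, function(x) sum((x - mean(x))^2), numeric(1))) /
    (big_n - k)
  list(k = k, ns = ns, means = means, big_n = big_n, mse = mse,
       df_err = big_n - k)
}

scheffe_p <- function(pa, i, j) {
  diff2 <- (pa$means[i] - pa$means[j])^2
  f <- diff2 / (pa$mse * (1 / pa$ns[i] + 1 / pa$ns[j])) / (pa$k - 1)
  stats::pf(f, pa$k - 1, pa$df_err, lower.tail = FALSE)
}

tukey_range_p <- function(pa, i, j) {
  se <- sqrt(pa$mse / 2 * (1 / pa$ns[i] + 1 / pa$ns[j]))
  q <- abs(pa$means[i] - pa$means[j]) / se
  stats::ptukey(q, pa$k, pa$df_err, lower.tail = FALSE)
}

# Tamhane's T2: Welch t statistic per pair with Sidak-corrected p-values.
tamhane_t2_p <- function(samples, i, j, m) {
  w <- stats::t.test(samples[[i]], samples[[j]], var.equal = FALSE)
  min(1, 1 - (1 - w$p.value)^m)
}

#' Compare predictors by ANOVA with a post-hoc majority vote
#'
#' Tests whether predictors share a common mean absolute error by one-way
#' ANOVA at level `alpha`. Upon rejection, five parametric post-hoc tests
#' run on every predictor pair: Scheffé's test, Tamhane's T2 test, the
#' pairwise Student's t-test with Bonferroni–Holm correction, Tukey's range
#' test, and Tukey's honestly significant difference test. A pair is
#' declared significantly different when at least three of the five tests
#' report p below `alpha`.
#'
#' @param errors_by_predictor Named list of absolute-error vectors, one per
#'   predictor (each of length at least 2), pooled across the benchmark
#'   sets the predictor family was evaluated on.
#' @param alpha Significance level, default 0.05.
#' @return A list of class `significance_report` with `anova_p`,
#'   `pairwise` (tibble with the five p-values per pair, `n_significant`
#'   and the majority `significant` verdict; empty when the ANOVA does not
#'   reject) and `alpha`.
#' @export
compare_predictors <- function(errors_by_predictor, alpha = 0.05) {
  k <- length(errors_by_predictor)
  if (k < 2L || is.null(names(errors_by_predictor))) {
    rlang::abort("need a named list of at least two predictors",
                 class = "pkaladder_usage_error")
  }
  if (any(lengths(errors_by_predictor) < 2L)) {
    rlang::abort("each predictor needs at least two error samples",
                 class = "pkaladder_usage_error")
  }
  x <- unlist(errors_by_predictor, use.names = FALSE)
  g <- factor(rep(names(errors_by_predictor), lengths(errors_by_predictor)))
  anova_p <- stats::oneway.test(x ~ g, var.equal = TRUE)$p.value

  empty <- tibble::tibble(
    predictor_a = character(), predictor_b = character(),
    scheffe = numeric(), tamhane_t2 = numeric(), t_holm = numeric(),
    tukey_range = numeric(), tukey_hsd = numeric(),
    n_significant = integer(), significant = logical())
  if (is.na(anova_p) || anova_p >= alpha) {
    return(structure(list(anova_p = anova_p, pairwise = empty, alpha = alpha),
                     class = "significance_report"))
  }

  samples <- errors_by_predictor
  pa <- pooled_anova(samples)
  pair_idx <- utils::combn(k, 2L)
  m <- ncol(pair_idx)

  hsd <- stats::TukeyHSD(stats::aov(x ~ g))$g
  hsd_key <- rownames(hsd)

  raw_t <- vapply(seq_len(m), function(c) {
    i <- pair_idx[1, c]; j <- pair_idx[2, c]
    stats::t.test(samples[[i]], samples[[j]], var.equal = TRUE)$p.value
  }, numeric(1))
  t_holm <- stats::p.adjust(raw_t, method = "holm")

  rows <- lapply(seq_len(m), function(c) {
    i <- pair_idx[1, c]; j <- pair_idx[2, c]
    a <- names(samples)[i]; b <- names(samples)[j]
    key <- if (paste(b, a, sep = "-") %in% hsd_key) paste(b, a, sep = "-") else paste(a, b, sep = "-")
    p5 <- c(
      scheffe = unname(scheffe_p(pa, i, j)),
      tamhane_t2 = unname(tamhane_t2_p(samples, i, j, m)),
      t_holm = unname(t_holm[c]),
      tukey_range = unname(tukey_range_p(pa, i, j)),
      tukey_hsd = unname(hsd[key, "p adj"])
    )
    nsig <- sum(p5 < alpha)
    tibble::tibble(predictor_a = a, predictor_b = b,
                   scheffe = p5[["scheffe"]], tamhane_t2 = p5[["tamhane_t2"]],
                   t_holm = p5[["t_holm"]], tukey_range = p5[["tukey_range"]],
                   tukey_hsd = p5[["tukey_hsd"]],
                   n_significant = nsig, significant = nsig >= 3L)
  })
  structure(list(anova_p = anova_p, pairwise = dplyr::bind_rows(rows),
                 alpha = alpha),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("<significance_report> one-way ANOVA p = %.3g (alpha = %g)\n",
              x$anova_p, x$alpha))
  if (nrow(x$pairwise) > 0) print(x$pairwise) else
    cat("ANOVA did not reject; no post-hoc comparisons run\n")
  invisible(x)
}
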