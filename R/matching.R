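# Assignment of experimental macroscopic pKa values to predicted
# macro-pKa ladders. The central algorithm is the order-preserving,
# L1-minimal matching: a strictly increasing injection of the N ascending
# experimental values into the M >= N ascending predicted values that
# minimizes the sum of absolute deviations, allowing unassigned predicted
# rungs ("gaps") anywhere — including interior positions — to account for
# experimentally undetected transitions.

# Floating costs within this tolerance are treated as tied; ties resolve to
# the smallest ladder indices so backtraces are platform-independent.
.cost_tol <- 1e-9

new_assignment <- function(exp_index, ladder_index, exp_values, ladder_values,
                           mode, n_ladder) {
  pairs <- tibble::tibble(
    exp_index = as.integer(exp_index),
    ladder_index = as.integer(ladder_index),
    exp_value = exp_values[exp_index],
    ladder_value = ladder_values[ladder_index]
  )
  pairs$deviation <- pairs$ladder_value - pairs$exp_value
  out <- list(
    pairs = pairs,
    total_cost = sum(abs(pairs$deviation)),
    mode = mode,
    gaps = setdiff(seq_len(n_ladder), pairs$ladder_index)
  )
  class(out) <- "pka_assignment"
  out
}

#' @export
print.pka_assignment <- function(x, ...) {
  cat("<pka_assignment> mode =", x$mode,
      " total cost =", format(x$total_cost), "\n")
  print(x$pairs)
  if (length(x$gaps) > 0) cat("unassigned ladder rungs:",
                              paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

check_sorted <- function(x, what) {
  if (is.unsorted(x)) {
    rlang::abort(paste(what, "values must be sorted ascending"),
                 class = "pkaladder_usage_error")
  }
  invisible(x)
}

infeasible <- function(msg) {
  rlang::abort(msg, class = "pkaladder_infeasible_error")
}

#' Order-preserving minimal-deviation matching
#'
#' Finds the strictly increasing injection of the `N` ascending
#' experimental values into the `M >= N` ascending ladder values that
#' minimizes the total absolute deviation `sum |e_i - p_k|`. Crossing
#' assignments are forbidden; unassigned ladder rungs (gaps) are permitted
#' anywhere, modelling experimentally undetected transitions. Computed by
#' dynamic programming over `C[i, j] = min(C[i, j-1], C[i-1, j-1] +
#' |e_i - p_j|)`; among cost ties the backtrace prefers the smallest ladder
#' indices.
#'
#' @param exp Numeric vector of experimental pKa values (sorted internally
#'   if needed; pairs are reported against ascending order).
#' @param ladder Numeric vector of predicted macro-pKa values.
#' @return A `pka_assignment`: a list with `pairs` (tibble of
#'   `exp_index`, `ladder_index`, values and signed `deviation` =
#'   predicted − experimental), `total_cost`, `mode` and `gaps`.
#' @seealso [window_match()], [closest_match()], [pairwise_match()]
#' @export
order_preserving_match <- function(exp, ladder) {
  exp <- sort(as.numeric(exp))
  ladder <- sort(as.numeric(ladder))
  n <- length(exp)
  m <- length(ladder)
  if (n < 1) rlang::abort("at least one experimental value is required",
                          class = "pkaladder_usage_error")
  if (m < n) {
    infeasible(sprintf(
      "ladder has %d rungs for %d experimental values; the predictor has likely failed to enumerate the relevant ionization states",
      m, n))
  }
  # C[i+1, j+1] = min cost of matching the first i experimental values
  # into the first j ladder values.
  cost <- matrix(Inf, n + 1L, m + 1L)
  cost[1L, ] <- 0
  for (i in seq_len(n)) {
    for (j in i:m) {
      pair <- cost[i, j] + abs(exp[i] - ladder[j])
      skip <- cost[i + 1L, j]
      cost[i + 1L, j + 1L] <- min(pair, skip)
    }
  }
  # Backtrace; skipping ladder rung j whenever it does not raise the cost
  # pushes every assignment to the smallest available indices.
  exp_idx <- integer(n)
  lad_idx <- integer(n)
  i <- n
  j <- m
  while (i >= 1L) {
    if (j > i && cost[i + 1L, j] - cost[i + 1L, j + 1L] < .cost_tol) {
      j <- j - 1L
    } else {
      exp_idx[i] <- i
      lad_idx[i] <- j
      i <- i - 1L
      j <- j - 1L
    }
  }
  new_assignment(exp_idx, lad_idx, exp, ladder, "order_preserving", m)
}

#' Sliding-window matching
#'
#' Alternative to [order_preserving_match()] under the assumption that the
#' experiment captured *all* transitions in the measured pH window: the
#' `N` experimental values are aligned against every length-`N` consecutive
#' segment of the ladder and the minimum-cost segment wins (ties to the
#' smallest start index).
#'
#' @inheritParams order_preserving_match
#' @return A `pka_assignment` with mode `"window"`.
#' @export
window_match <- function(exp, ladder) {
  exp <- sort(as.numeric(exp))
  ladder <- sort(as.numeric(ladder))
  n <- length(exp)
  m <- length(ladder)
  if (n < 1) rlang::abort("at least one experimental value is required",
                          class = "pkaladder_usage_error")
  if (m < n) infeasible("ladder shorter than the experimental sequence")
  best_start <- 1L
  best_cost <- Inf
  for (s in seq_len(m - n + 1L)) {
    cost <- sum(abs(exp - ladder[s:(s + n - 1L)]))
    if (cost < best_cost - .cost_tol) {
      best_cost <- cost
      best_start <- s
    }
  }
  new_assignment(seq_len(n), best_start:(best_start + n - 1L), exp, ladder,
                 "window", m)
}

#' Closest-value matching for a single experimental value
#'
#' The maximally permissive strategy used when nothing links multiple
#' reported values to distinct transitions: the experimental value is paired
#' with the predicted value of minimal absolute difference (ties to the
#' lower ladder index, i.e. the lower pKa).
#'
#' @param exp_value A single experimental pKa value.
#' @param ladder Numeric vector of predicted macro-pKa values (non-empty).
#' @return A `pka_assignment` with mode `"closest"` and one pair.
#' @export
closest_match <- function(exp_value, ladder) {
  stopifnot(length(exp_value) == 1L)
  ladder <- sort(as.numeric(ladder))
  if (length(ladder) < 1L) infeasible("empty ladder")
  d <- abs(ladder - exp_value)
  k <- which(d <= min(d) + .cost_tol)[1L]
  new_assignment(1L, k, exp_value, ladder, "closest", length(ladder))
}

#' Two-value linear assignment
#'
#' For amphoteric molecules (two experimental values) the two predictions
#' minimizing the total absolute deviation are selected by exhaustive linear
#' assignment over all ordered pairings of distinct ladder rungs. On sorted
#' inputs the optimum provably coincides with [order_preserving_match()]
#' (an L1 exchange argument removes any crossing without raising the cost);
#' ties are broken to the order-preserving pairing with the smallest
#' indices.
#'
#' @param exp_pair Two experimental pKa values.
#' @param ladder Numeric vector of at least two predicted values.
#' @return A `pka_assignment` with mode `"pairwise"`.
#' @export
pairwise_match <- function(exp_pair, ladder) {
  stopifnot(length(exp_pair) == 2L)
  exp_pair <- sort(as.numeric(exp_pair))
  ladder <- sort(as.numeric(ladder))
  m <- length(ladder)
  if (m < 2L) infeasible("ladder must contain at least two rungs")
  # Non-crossing pairings first so that cost ties resolve to the
  # order-preserving assignment with the smallest ladder indices.
  combos <- expand.grid(j = seq_len(m), k = seq_len(m))
  combos <- combos[combos$j != combos$k, ]
  combos <- combos[order(combos$j >= combos$k, combos$j, combos$k), ]
  best <- NULL
  best_cost <- Inf
  for (r in seq_len(nrow(combos))) {
    j <- combos$j[r]
    k <- combos$k[r]
    cost <- abs(exp_pair[1] - ladder[j]) + abs(exp_pair[2] - ladder[k])
    if (cost < best_cost - .cost_tol) {
      best_cost <- cost
      best <- c(j, k)
    }
  }
  ord <- order(best)
  new_assignment(ord, best[ord], exp_pair, ladder, "pairwise", m)
}

#' Consistency check for typed pKa groups
#'
#' Entries carrying type labels (e.g. `"pKa1"`, `"pKa2"`) are grouped by
#' label; the labelling is considered consistent when no two values within
#' one group differ by more than 1.0 pKa unit and no two values from
#' different groups differ by less than 0.5. Inconsistent labelling means
#' the type tags cannot be trusted to separate transitions, and callers fall
#' back to closest-value matching.
#'
#' @param groups Named list mapping type label to a numeric vector of
#'   values (each non-empty).
#' @param within_max Maximum allowed within-group absolute difference.
#' @param between_min Minimum required between-group absolute difference.
#' @return A list with `pass` (logical) and `violations` (tibble with
#'   columns `kind`, `group_a`, `group_b`, `value_a`, `value_b`, `diff`).
#' @export
typed_group_check <- function(groups, within_max = 1.0, between_min = 0.5) {
  stopifnot(length(groups) >= 1L, all(lengths(groups) >= 1L))
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    rlang::abort("groups must be named by type label",
                 class = "pkaladder_usage_error")
  }
  viol <- list()
  labs <- names(groups)
  for (a in seq_along(groups)) {
    va <- groups[[a]]
    if (length(va) > 1L) {
      pr <- utils::combn(length(va), 2L)
      d <- abs(va[pr[1, ]] - va[pr[2, ]])
      hit <- which(d > within_max)
      for (h in hit) {
        viol[[length(viol) + 1L]] <- tibble::tibble(
          kind = "within", group_a = labs[a], group_b = labs[a],
          value_a = va[pr[1, h]], value_b = va[pr[2, h]], diff = d[h])
      }
    }
    if (a < length(groups)) {
      for (b in (a + 1L):length(groups)) {
        vb <- groups[[b]]
        grid <- expand.grid(x = va, y = vb)
        d <- abs(grid$x - grid$y)
        hit <- which(d < between_min)
        for (h in hit) {
          viol[[length(viol) + 1L]] <- tibble::tibble(
            kind = "between", group_a = labs[a], group_b = labs[b],
            value_a = grid$x[h], value_b = grid$y[h], diff = d[h])
        }
      }
    }
  }
  violations <- if (length(viol) > 0) dplyr::bind_rows(viol) else
    tibble::tibble(kind = character(), group_a = character(),
                   group_b = character(), value_a = numeric(),
                   value_b = numeric(), diff = numeric())
  list(pass = nrow(violations) == 0L, violations = violations)
}
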