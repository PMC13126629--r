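---
title: "Curating and benchmarking macroscopic pKa data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and benchmarking macroscopic pKa data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkaladder)
```

## The model

A titration measures a molecule's macroscopic dissociation constants: an
ascending sequence of pKa values, each corresponding to the loss of one
proton between net-charge states `(q, q−1)`. The measurement itself does
not say which states are involved. Structure-based predictors do annotate
their values with transitions, so aligning an experimental sequence with a
predicted *ladder* — the ascending macro-pKa values bound to strictly
decreasing charges — transfers the annotation onto the experiment.

Formally, with `N` ascending experimental values and an `M ≥ N`-rung
ladder, the assignment is a strictly increasing injection of experimental
indices into ladder indices minimizing `sum |e_i − p_k(i)|`. Two modelling
assumptions are encoded:

* **Order preservation.** Transitions progress monotonically with pH, so
  crossings are chemically inconsistent and forbidden.
* **Gaps are allowed anywhere.** An experiment may simply miss a
  transition (weak spectroscopic signal, limited pH window), so unassigned
  ladder rungs are legal, including interior ones. This is the agnostic
  default; it implicitly assumes undetected transitions are more common
  than very large predictor errors.

If one instead assumes the experiment observed *every* transition in the
window, the matched rungs must be consecutive and the problem reduces to a
sliding-window alignment (`window_match()`). When nothing ties multiple
reported values to distinct transitions, the permissive fallback is
closest-value matching per value (`closest_match()`); for exactly two
values, exhaustive linear assignment (`pairwise_match()`) is used, which
on sorted inputs provably coincides with the order-preserving optimum (an
L1 exchange argument: uncrossing two matched pairs never increases the
cost) — an equality the test suite asserts on a thousand random instances.

The dynamic program is the textbook recurrence
`C[i][j] = min(C[i][j−1], C[i−1][j−1] + |e_i − p_j|)` in `O(NM)`; the test
suite checks it against exhaustive enumeration over all strictly
increasing injections for a thousand seeded instances.

## Numerical choices

* Costs are compared with an absolute tolerance of `1e-9`; differences
  below it count as ties. Ties resolve everywhere toward the smallest
  ladder index (the lowest pKa), making backtraces platform-independent.
* Inputs are sorted ascending internally; pairs are reported against the
  sorted order.
* `M < N` is an infeasibility error, not a silent truncation: a predictor
  offering fewer transitions than were observed has failed to enumerate
  the relevant ionization states, and the caller decides (the curation
  pipeline flags the molecule; the evaluator records an exception).
* Speciation (`macrostate_populations()`) accumulates
  `log10`-weights and shifts by the maximum before exponentiating, so
  ladders spanning the full 0–14 range cannot overflow; fractions
  renormalize to 1 within `1e-12`.

## The curation pipeline

`curate_entries()` applies, in order: constant conversion, metadata
filters, per-source transition assignment, outlier exclusion,
cross-source deduplication and per-transition averaging. The order
matters: deduplication must follow assignment (duplicates are defined
within a transition) and precede averaging. Each stage emits a
machine-readable reject report, and conservation — entries in = kept +
rejected — is asserted at every stage by the tests.

The thresholds, all collected in `curation_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `pkw` | 14.0 | log10 | water self-dissociation constant; `pKa = pKw − pKb` |
| `cosolvent_max` | 0.05 | volume fraction | above ~5% cosolvent the aqueous constant shifts materially |
| `outlier_threshold` | 4.0 | pKa units | a matched experimental-vs-predicted gap above 4 is far outside both replicate scatter and typical predictor error, so the record is likely misannotated; the comparison is strict (`> 4`), exactly 4.0 is kept |
| `temp_window` | [15, 40] | °C | near-ambient measurements; entries with a *known* temperature outside are excluded from averages, unknown temperatures are kept (unknown is not out-of-range) |
| `dedup_decimals` | 2 | decimals | published pKa values are near-universally 2-decimal, so "the same numeric value" is compared after rounding to 2 |

Cross-source deduplication treats a value appearing (after rounding) in
two or more source datasets as one measurement propagated between
collections: it is kept only as many times as its minimum occurrence count
in any of those sources, while single-source values keep their counts.
The implementation retains the surviving rows of the minimum-count source
(ties to the first source in sorted order), which makes the operation
idempotent — re-running it on its own output changes nothing.

Typed entries (`pKa1`, `pKa2`, …) get a consistency check before their
labels are trusted: the labelling fails if any two values within a group
differ by more than 1.0 or any two values across groups differ by less
than 0.5. On failure the pipeline falls back to closest-value matching per
entry. The failure path is a genuine design choice — the alternative of
excluding such molecules outright discards usable single values, and
closest matching is already the standard treatment for unlabeled data, so
the fallback is the less destructive option.

## Benchmark sets

`build_benchmarks()` runs the funnel: value range `[0, 14]` and heavy-atom
count `[6, 50]` (both inclusive), removal of molecules whose stereo-free
InChI appears in any exclusion set (fine-tuning data of trainable
predictors, popular benchmark collections), a sufficiency filter (each
relevant predictor must offer at least as many values as there are
experimental ones; for polyprotic molecules only macroscopic predictors
count), and classification:

* *monoprotic* — one averaged value at `0 to -1` (acid) or `1 to 0` (base);
* *amphoteric* — exactly the pair `1 to 0` and `0 to -1`;
* *polyprotic* — more than one averaged value, not amphoteric.

A molecule with a single transition between two nonzero charges implies
undetected transitions and is excluded with that reason; since `0 to -1`
and `1 to 0` are the only adjacent-charge pairs involving zero, every
single-transition molecule is either monoprotic or carries that exclusion.
The three sets are pairwise disjoint, and every input molecule lands in
exactly one set or in the exclusion log.

## Evaluation statistics

Deviations use the convention *predicted − experimental* (fixed so bias
has a sign). Matching at evaluation time mirrors the class structure:
closest for monoprotic, linear assignment for amphoteric, order-preserving
for polyprotic. Summaries are MAE, RMSE (so MAE ≤ RMSE always, by
Jensen), histograms over left-closed right-open bins with default edges
0, 0.5, 1, 2, 3, ∞, and the exception rate — the fraction of a set's
molecules with no or too few predictions.

Predictor comparison pools each predictor's absolute errors across the
sets its family was evaluated on and runs a classic equal-variance one-way
ANOVA at α = 0.05. Upon rejection, five parametric post-hoc tests run per
pair — Scheffé, Tamhane T2 (Welch t with Šidák correction), pairwise
Student's t with Bonferroni–Holm, the studentized-range test, and Tukey's
HSD — and a pair is declared different when at least three of five agree.
The range test and HSD are closely related by construction; keeping both
mirrors the five-test roster this voting scheme is defined over. Scheffé,
Tamhane T2 and the range test are computed directly from their closed
forms on top of `stats::pf`/`stats::ptukey`; the tests cross-check the
hand-written range test against `stats::TukeyHSD`.

## The synthetic generator

`generate_synthetic()` emulates the statistical structure the pipeline
assumes: true ladders with 1–5 rungs drawn uniformly in `[0, 14]` under a
minimum spacing of 1.0 (rejection sampling; the uniform spread is a
deliberate simplification of the broad empirical pKa distribution), a
most-protonated charge drawn from `{0, …, min(rungs, 2)}` so all three
benchmark classes occur, replicate measurements with Gaussian noise, and a
predictor ladder with its own noise plus occasional spurious rungs.
Defaults, chosen once as realistic study conditions: `sigma_exp = 0.2`
(the typical cross-source replicate standard deviation of curated pKa
collections), 1–4 replicates per transition, `sigma_pred = 0.5` (mid-range
of practical predictor RMSEs), `dropout_p = 0.1` and `spurious_p = 0.1`
(undetected and over-enumerated transitions are real but minority events).

Randomness is organized as counter-derived per-molecule substreams, so
molecule `i` is identical whether 10 or 10,000 molecules are generated —
fixtures stay stable across test subsets — and the whole output is
byte-identical per seed.

What the generator does *not* emulate: any relationship between structure
and pKa (structures are deterministic stubs whose only guarantees are
parseability, uniqueness and a 6–50 heavy-atom count), correlated errors
between predictors, non-Gaussian heavy-tailed replicate scatter, or
systematic predictor bias. Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated noise
model, not predictor performance on real chemistry.

Gaussian noise was chosen deliberately because it gives closed-form
targets: with noise scale σ and correct assignment, MAE → σ·√(2/π) and
RMSE → σ, which the tests assert within 5% at 5,000 matched values; the
mean two-replicate sample standard deviation is checked against a direct
Monte-Carlo oracle within 3% at 10,000 transitions. Problem sizes in the
test suite (1,000 instances for oracle equivalence, 1,000 molecules for
recovery, 500 per arm for the significance checks, 20 repetitions for the
vote rates) are the package's chosen trade-off between statistical
resolution and a test suite that stays fast enough to run on every change.

## Structure handling

All structure-level primitives are delegated to the RDKit toolkit through
a batched helper process: stereochemistry-stripped standard InChI as the
molecule key (so stereoisomers and redrawn molecules collapse, matching
how overlap between datasets is assessed), heavy-atom counts, Morgan
fingerprints of radius 4 folded to 2048 bits with Tanimoto similarity, and
SMARTS substructure search for titratable-group annotation. The
titratable-group pattern library ships as an editable TSV
(`inst/extdata/titratable_groups.tsv`) because no published SMARTS set is
canonical for these categories; the defaults cover carboxylic acids,
phenols, sulfonamides, thiols, 1,3-dicarbonyl carbon acids, tetrazoles,
aliphatic amines, basic aromatic nitrogens and amidines/guanidines. Set
similarity iterates the smaller set and averages each molecule's best
Tanimoto into the partner set; self-similarity excludes the molecule
itself.

## Known limitations

* Molecules whose SMILES the toolkit cannot parse are reported, never
  repaired; aromaticity problems that require manual fixes are out of
  scope.
* The "complete observation" regime in which several experimental values
  may map onto one predicted transition is documented but not implemented;
  none of the shipped strategies needs it.
* Micro-pKa ↔ macro-pKa interconversion and microstate enumeration are out
  of scope: the package operates entirely at the macroscopic level.
* The speciation helper works from macro-pKa ladders only and says nothing
  about microspecies populations within a charge state.
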