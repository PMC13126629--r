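# pkaladder

Tools for turning heterogeneous experimental acid-dissociation data into
per-molecule, per-charge-state-transition reference pKa values, and for
benchmarking pKa predictors against the result.

## The problem

A titration experiment yields a molecule's *macroscopic* pKa values — an
ascending sequence of apparent constants — but not the identity of the
protonation states behind each transition. Aggregated literature
collections make this worse: the same molecule appears in several sources
with replicate values, missing metadata, mixed pKa/pKb conventions, and no
indication of which reported value belongs to which charge-state
transition. `pkaladder` annotates each experimental value with a
charge-state transition `(q, q−1)` by aligning the experimental sequence
with a predicted macro-pKa *ladder*, then curates, averages and benchmarks
on top of that annotation.

## The core algorithm

Given `N` ascending experimental values `e_1 < … < e_N` and `M ≥ N`
ascending predicted values `p_1 < … < p_M`, the assignment is the strictly
increasing injection `k(1) < … < k(N)` minimizing the total absolute
deviation

    sum_i | e_i − p_k(i) |

Order preservation forbids "crossing" assignments (the monotone
progression of transitions with pH must be respected), while unassigned
predicted rungs — *gaps* — are allowed anywhere, modelling experimentally
undetected transitions. The optimum is found by dynamic programming over

    C[i][j] = min( C[i][j−1],  C[i−1][j−1] + |e_i − p_j| )

with ties broken toward the smallest ladder indices. Three companions
cover the other data regimes: `window_match()` (all transitions assumed
observed: best length-`N` consecutive segment), `closest_match()` (a single
unlabeled value), and `pairwise_match()` (two values by exhaustive linear
assignment, provably equal to the order-preserving optimum on sorted
inputs).

Around the matcher sit the curation pipeline (pKb → pKa conversion via
`pKa = pKw − pKb`, cosolvent/condition filters, a strict `> 4` matched-
deviation outlier rule, cross-source deduplication at minimum occurrence
counts, temperature-windowed per-transition averaging), the benchmark
builder (monoprotic / amphoteric / polyprotic sets), the evaluator
(MAE/RMSE, binned absolute errors, exception rates, one-way ANOVA with a
five-test post-hoc majority vote) and structure annotation (stereo-free
InChI keys, Morgan radius-4/2048-bit fingerprints and Tanimoto similarity,
titratable-group labelling, Henderson–Hasselbalch macro-state speciation).
A seeded synthetic-data generator emulates the whole statistical setting
so every stage is testable without external databases.

## Worked example

```r
library(pkaladder)

# Two experimental values against a three-rung predicted ladder: the middle
# rung is left as a gap (an undetected transition).
order_preserving_match(c(4.0, 9.0), c(3.5, 7.0, 9.2))
#> <pka_assignment> mode = order_preserving  total cost = 0.7
#>   exp_index ladder_index exp_value ladder_value deviation
#> 1         1            1         4          3.5    -0.5
#> 2         2            3         9          9.2     0.200
#> unassigned ladder rungs: 2
```

A miniature curation run — three entries from two sources for one
amphoteric molecule, one of them reported as a pKb:

```r
lad <- macro_ladder("OC(=O)c1ccccc1N", c(2.1, 4.8), charge_high = 1L)
lad$structure_key <- "anthranilic"
entries <- tibble::tibble(
  entry_id = 1:3, smiles = "OC(=O)c1ccccc1N", structure_key = "anthranilic",
  pka_value = c(2.05, 4.95, 9.2), constant_kind = c("pKa", "pKa", "pKb"),
  type_label = NA, temperature_c = c(25, 25, NA), ionic_strength_m = NA_real_,
  cosolvent_fraction = NA_real_, cosolvent_unquantified = FALSE,
  source_dataset = c("A", "A", "B"), remark = NA_character_)

curate_entries(entries, lad)$curated
#>   structure_key smiles          charge_high charge_low mean_pka n_values
#> 1 anthranilic   OC(=O)c1ccccc1N           1          0     2.05        1
#> 2 anthranilic   OC(=O)c1ccccc1N           0         -1     4.88        2
```

The pKb entry converts to `14.0 − 9.2 = 4.8`, lands on the `0 to -1`
transition next to the 4.95 measurement, and the two average to 4.88. The
resulting ladder speciates as expected at physiological pH:

```r
macrostate_populations(c(2.1, 4.8), pH = 7, charge_high = 1L)
#>            1            0           -1
#> 7.893477e-08 6.270012e-03 9.937299e-01
```

A command-line interface wraps the same functions:

```sh
pkaladder simulate --out-dir sim --seed 7 --n-molecules 100
pkaladder curate --entries sim/entries.csv --ladders sim/ladders.csv --out-dir curated
pkaladder build-benchmarks --curated curated/curated.csv --out-dir bench
pkaladder evaluate --sets-dir bench --predictions sim/predictions.csv --out-dir eval
```

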