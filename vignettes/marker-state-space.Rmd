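---
title: "Marker state space panels: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker state space panels: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mss)
```

## The model

A marker-state panel is a triple: an ordered set of $n$ markers, one
threshold per marker, and a *state rule set* mapping each of the $2^n$
binary states to case or control. A sample's state is obtained by
binarizing each marker value against its threshold (strictly above
$\mapsto 1$), reading the bits with the first marker as most significant,
and numbering states $1 \dots 2^n$; classification is a table lookup. The
model's only structural assumption is that class membership is a function
of the *pattern* of high/low values — it imposes no ordering, additivity
or distributional assumption across markers, which is what lets it
represent patient subclasses with completely divergent marker profiles
(a subclass elevated in markers 1 and 3 and one elevated in all three can
both be case states while their "average" pattern is not).

Rules are learned by per-state majority vote of the training samples
occupying the state. Majority voting is optimal for training accuracy:
with states fixed, accuracy decomposes over states, and each state's
contribution is maximized by picking its more frequent class (the test
suite verifies this against all $2^{2^n}$ assignments for $n = 2$). Two
cases are not determined by the vote and are resolved by documented,
configurable rules:

* **Ties** (equal counts) go to control. Calling a tied state negative
  favors specificity, the conservative choice for a diagnostic follow-up
  setting; `tie = "case"` flips it.
* **Unoccupied states** take the majority class of the occupied states at
  minimum Hamming distance, ties again to control. This generalizes the
  natural manual judgement — an empty state is read by its similarity to
  neighboring states — into a deterministic, testable rule. The
  `source` column of every rule table records which rule produced each
  assignment (`majority`, `tie_rule`, `unoccupied_rule`).

## Search

Panel discovery is exhaustive by design. Candidate thresholds for each
marker are consecutive integer multiples of a step (default 0.2, in log10
fluorescence units) spanning the marker's observed range: a marker ranging
1.25–3.25 at step 0.5 is scanned at 1, 1.5, 2, 2.5, 3, 3.5. Anchoring the
grid at step multiples rather than at the data minimum keeps grids
comparable across markers and makes the scan invariant to shifting a
marker by a step multiple; thresholds are carried internally as integer
multiples, so no floating-point accumulation can perturb the grid.
Per-marker ranges are the default; a `range = "global"` flag scans a fixed
common range (e.g. the full 1–4.82 transformed scale) instead.

`full_train()` visits every combination of `panel_size` markers and the
full Cartesian product of their grids — no pruning, since correctness of
the exhaustive search is the point and the cost is explicit:
$\binom{m}{n} \prod_j T_j$ rule evaluations, each $O(N)$ in the sample
count. The inner loop is a small C++ kernel (per-marker binarizations are
precomputed once per grid column; states are updated incrementally along
the threshold odometer), which keeps a 13-marker, 200-sample,
step-0.2 search around a second on one CPU. Panels meeting both cutoffs
are retained in full; the best setting overall is additionally tracked by
correct calls, ties broken toward higher specificity and then the
lexicographically earliest grid point, so results are bit-identical
regardless of evaluation order.

Retention cutoffs are study-specific and have no natural default; the
package ships `min_sensitivity = min_specificity = 0.8` as a moderate
screening level and the examples pass explicit values.

## Cross-validation and panel selection

`make_splits()` divides samples into $k = 10$ groups of as-equal-as-possible
size (a mandatory seed makes plans reproducible; stratification is
optional and off by default, matching plain random division). For each
split, every retained panel is retrained on the other nine tenths at its
own thresholds; if it still meets the cutoffs there, its completed rules
are applied to the held-out tenth and the accuracy recorded, otherwise the
cell is missing (`N/A` in the final report). Per-panel averages are taken
over non-missing splits only — a panel absent from a split contributes
nothing, rather than a zero that would conflate absence with failure.

Selection then rewards *robustness*: the panel list is trimmed to settings
reaching the best or second-best **distinct** accuracy level in at least
one split (distinct levels, because coarse grids produce heavy ties that
would make "top two rows" ill-defined); trimmed settings are grouped by
unordered marker combination; and combinations are ranked by the number of
distinct threshold settings present (insensitivity to threshold placement)
with mean held-out accuracy as the tie-breaker. The winner is finalized by
re-scanning its threshold product on all samples (best accuracy, ties →
higher specificity → lexicographically earlier thresholds).

A single headline cross-validation accuracy is also reported, defined
operationally as: in each split, take the panel with the best
training-portion accuracy (same tie-breaks) and apply it to the held-out
split; average the ten held-out accuracies. Other aggregations are
defensible — the per-split-best definition is the one consistent with
reporting a single accuracy without per-split sensitivity/specificity —
and reports label it as such. `cv_run(headline = FALSE)` skips the extra
per-split scans when only panel selection is needed.

## Preprocessing

The intended inputs are quantified antibody-array intensities. The chain
is: median local-background subtraction (`net_signal()`, performed
upstream by scanner software but provided for completeness), clipping to a
positive floor of 10 raw units, geometric-mean averaging of within-array
replicates, removal of markers where fewer than 10% of samples reach twice
the buffer-only negative-control signal (the fold comparison inclusive,
the 10% boundary strict — a marker passing in exactly 10% of samples is
kept), and a log10 transform. The floor of 10 is the one value that maps
the 16-bit scale 0–65535 onto exactly 1–4.82 and simultaneously resolves
zero and negative net signals; because the geometric mean of floored raw
values equals the arithmetic mean of floored logs, averaging before or
after the transform is equivalent (tested). Whether the 1–4.82 range in
the motivating data reflects clipping or merely the observed range is not
decidable from the outside; the floor is therefore a configurable
argument, not a constant.

## The synthetic generator

`simulate_markers()` emulates the data-generating picture the model
assumes: log-normal raw intensities (Gaussian on the log10 scale), a case
population drawn from a mixture of subclass states over the planted panel
markers, a control population drawn from mostly-low states, decoy markers
with no class signal, and optional label flips. Defaults — 100 + 100
samples, 13 markers with 3 planted, effect size $\Delta = 1.0$ log10 unit,
noise sd 0.25, case mix $111\!:\!0.45$, $101\!:\!0.30$, $110\!:\!0.15$,
$011\!:\!0.10$, control mix $000\!:\!0.60$, $010\!:\!0.30$,
$100\!:\!0.10$ — reproduce the occupancy pattern typical of a
CA 19-9-anchored pancreatic-cancer panel, where most cases sit in the
all-high and first-and-third-high states and most controls in the all-low
state. The ground truth (markers, separating thresholds at
$\mathrm{baseline} + \Delta/2$, per-sample subclass states) is returned
alongside for parameter-recovery experiments.

What the generator does *not* emulate: antibody cross-reactivity,
correlated noise between assays sharing a capture or detection antibody,
batch and plate effects, and heavy-tailed outliers. Passing the recovery
and null-control tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not performance on real
cohort data.

## Numerical choices and degenerate inputs

* Equality at a threshold maps to 0; the choice is isolated in
  `binarize_value()` and is immaterial whenever no datum sits exactly on a
  grid multiple.
* Grid endpoints use a $10^{-9}$ relative guard so values lying exactly on
  a step multiple do not gain a spurious extra threshold.
* Metrics are kept as exact ratios of integer confusion counts; rounding
  to one-decimal percentages happens only in the report writers, so
  report files round-trip at the printed precision (±0.05 points) while
  in-memory comparisons are exact.
* A split whose training portion lacks a class is flagged degenerate, its
  cells reported missing, with a warning.
* Boolean minimization is exact (prime implicants by iterated single-bit
  merging, then essential implicants plus exhaustive minimum cover) —
  affordable because panels are small ($n \le 6$); each class is covered
  independently and the round trip back to the state partition is tested
  exhaustively for $n \le 4$.

## Problem sizes used in the test suite

Unit and property tests run on instances of 10–60 samples and 2–6 markers
with coarse grids; the scan-versus-oracle comparison uses 50 random
instances of up to 5 markers and 20 samples; parameter recovery uses 20
replicate studies at the generator defaults (200 samples, 13 markers,
step 0.2); the null-effect control pools three 100-sample studies. These
sizes give each statistical check enough resolution while keeping the
default suite under a couple of minutes on one CPU.

## Known limitations

* **Threshold recovery at fine steps is noisy.** Finalization returns the
  empirical accuracy argmax; at 200 samples with noise sd 0.25 the
  accuracy landscape within ±2 grid steps (step 0.2) of the true
  threshold differs by only one or two samples, so the finalized
  threshold occasionally lands 1.5 steps from the population optimum even
  though the marker combination itself is recovered essentially always.
  Brute-force checks confirm those settings genuinely maximize training
  accuracy — the spread is sampling noise, not a search defect. Larger
  cohorts or coarser steps tighten it.
* Exhaustive search scales as $\binom{m}{n}$ times the grid product;
  panels beyond $n \approx 4$ or marker sets in the thousands need
  search-space reduction, which is out of scope here.
* Samples with missing marker values cannot be classified (a state
  requires every bit) and must be imputed or excluded upstream.
* Binary states only; two-threshold three-level encodings are a possible
  extension, not implemented.
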