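---
title: "Mining climate–yield association rules by agro-ecological zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining climate–yield association rules by agro-ecological zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrorules)
library(dplyr)
```

## The procedure and its assumptions

The package answers a descriptive question: in a given agro-ecological
zone, which combinations of climate *categories* co-occur with high crop
yield? The unit of analysis is the station-month. The procedure is:

1. **Aggregate.** Daily station records are averaged to monthly means, one
   record per (zone, year, month). Annual yield is spread uniformly over the
   year (monthly yield = annual / 12): with no within-year yield signal,
   any seasonal shape would be an invention, so the flat disaggregation is
   the only defensible choice.
2. **Filter redundant predictors.** Pearson correlations are computed on
   the pooled (all-zone) monthly records; from every predictor pair with
   |r| above 0.8 one member is dropped. Minimum and maximum humidity are
   strongly collinear in this kind of data, so `Umin` is typically removed,
   leaving six predictors plus yield.
3. **Discretize.** Per zone and attribute, values at or below mean − sd are
   `low`, at or above mean + sd are `high`, and `medium` in between (open
   interval). Under approximate normality this makes `low` and `high`
   ≈ 16 % tails and `medium` ≈ 68 % of months.
4. **Mine.** Each station-month becomes a transaction of
   `attribute=category` items. Frequent itemsets are mined per zone with
   FP-Growth; rules toward the single consequent `Yield=high` are scored by
   support, confidence and lift; rules with ≥ 3 antecedents, confidence
   ≥ 0.8 and lift ≥ 1 are ranked and the top five reported.

The key assumptions are that monthly means are the right temporal grain,
that the mean ± sd bands are meaningful summaries per zone (they are
recomputed per zone precisely because the zones differ in level and
spread), and that co-occurrence — not causality — is the claim a rule
makes.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_support` | 0.2 | fraction of a zone's months | ≈ 63 of 312 months; low enough to see tail categories, high enough to keep the itemset lattice small |
| `min_confidence` | 0.8 | conditional frequency | rules should be near-deterministic to be agronomic advice |
| `min_lift` | 1 | ratio | excludes rules no better than the consequent's base rate |
| `min_antecedents` | 3 | items | single- and two-condition rules are dominated by their refinements and rarely actionable |
| `top_k` | 5 | rules/zone | a readable report |
| `correlation_threshold` | 0.8 | \|r\| | conventional collinearity cutoff |

Support is converted to an absolute count by `ceiling(min_support * N)`:
the conservative reading under which every reported fractional support
genuinely satisfies the floor. Mining is per zone with N = that zone's
transaction count, matching the per-zone rule tables the analysis is meant
to produce; pooled mining would mix zone-specific thresholds.

## What the synthetic generator emulates — and what it does not

No station data ship with the package. `benin_thresholds()` carries the
published per-zone cutpoints; since cutpoints are mean ± sd, the zone
profile (mean = midpoint, sd = half-width) is recoverable exactly, and
`generate_monthly_records()` draws each attribute independently from a
normal with those moments, truncated to physical ranges (RR, Sun, ET,
yield ≥ 0; humidities in [0, 100]).

Truncation alone would shift the realized mean and shrink the sd — for the
Sudanian yield profile (mean 441.3, sd 248.7, floor at 0) by roughly 8 %
of sd — so the parent parameters are *moment-matched*: a two-parameter
numerical solve makes the truncated distribution itself carry the
profile's mean and sd. This is what lets threshold-recovery tests compare
computed cutpoints to the generating ones with a plain 3-standard-error
band, with no truncation-bias bookkeeping. When matching is impossible the
generator warns and falls back to naive parameters.

`Umin` is generated as `0.9 · Umax + N(0, 2 %)` (clamped to [0, Umax]) by
default, deliberately recreating the humidity collinearity so the
correlation filter has real work to do.

The generator does **not** emulate: seasonality or autocorrelation (months
are i.i.d., while real Benin climate has a strong annual cycle), spatial
structure beyond the zone label, dependence between attributes (other than
`Umin` and planted rules), or within-year yield variation. A green
planted-rule test therefore establishes that the pipeline's counting,
discretization and mining are exact — not that the generator's months look
like real weather.

`plant_rule()` injects a known rule by rewriting values inside category
bands: with n records, the full itemset is placed in exactly
⌈support · n⌉ records; the antecedent alone in m = the integer count that
brings k/m closest to the target confidence (an error is raised if no m
gets within 1/n — confidences are only representable on the grid k/m);
and the first antecedent attribute is knocked out of its category in all
remaining records so the counts are *exact*, not approximate. Note that
planting rewrites marginals: if `Umax` is part of a planted rule, the
`Umin`–`Umax` correlation of the affected records is weakened, and callers
who rely on the collinearity (as the acceptance script does) should
re-derive `Umin` afterwards.

## Numerical and boundary choices

* **Cutpoint semantics.** `low` is ≤, `high` is ≥, `medium` is open on
  both sides — forced by the interval notation of the published tables.
  For a degenerate zero-width table (`low_cut == high_cut`, e.g. a
  constant attribute) the ≤ test wins: the value is `low`. Arbitrary but
  fixed and tested.
* **Standard deviation** uses the n − 1 denominator (sample sd).
* **Item order in the FP-tree**: frequency descending, ties by ascending
  label — deterministic trees across platforms. Itemsets keep exact
  integer counts throughout; fractional support is computed once at the
  boundary.
* **Rule relevance order**: confidence, then lift, then support,
  descending, ties by antecedent label. With a fixed consequent, lift is a
  monotone function of confidence, so the order is effectively
  (confidence, support); the full key keeps ranking total and
  deterministic for any consequent.
* **Correlation filter drop order**: the variable in more above-threshold
  pairs is dropped first; ties fall back to the fixed keep-priority
  Tmin > Tmax > Umax > Umin > RR > Sun > ET. |r| (not signed r) is
  compared, and the matrix is recomputed after each drop. Zero-variance
  attributes produce undefined correlations and are retained with a
  warning rather than guessed at.
* **Degenerate inputs**: empty transaction sets, a support floor above N,
  missing (zone, year) yields, zones with a single record, and NaN values
  at discretization all raise typed, early errors; a month with no usable
  daily values is dropped with a warning.

## Design choices that were genuinely open

* **Thresholds for mining planted data.** `run_pipeline()` recomputes
  mean ± sd thresholds from its input by default, but accepts a fixed
  threshold table. Exact recovery of a planted rule requires mining with
  the same table the rule was planted under — recomputed thresholds shift
  once values have been rewritten. The default serves real data; the
  argument serves calibration studies.
* **Minimum-humidity thresholds.** The published tables cover seven
  attributes (`Umin` was dropped before thresholding), so the packaged
  table cannot discretize `Umin`; `to_transactions()` therefore defaults
  to the attributes its threshold table covers, and errors loudly if asked
  for one it cannot.
* **Consequent scope.** Only single-item consequents are generated; the
  pipeline's question has a fixed consequent (`Yield=high`) and the
  general multi-consequent enumeration would be dead code.
* **Confidence-1 rule sets.** If every reported rule had confidence 1
  *and* lift exactly 1, the metric identities would force
  support(`Yield=high`) = 1 — every month high-yield — which a mean ± sd
  discretization cannot produce over a whole zone. The package computes
  lift strictly by its definition and reports whatever it is (planted
  confidence-1 rules here get lift ≈ 2–3, the reciprocal of the high-yield
  base rate); it does not attempt to reproduce rule tables in which both
  metrics equal 1 simultaneously.

## Known limitations

Rules are descriptive co-occurrence statements on discretized monthly
means; they carry no causal weight and no uncertainty quantification.
The three-level discretization wastes within-band variation and makes the
`low`/`high` tails scarce (≈ 16 % of months), so with the 0.2 support
floor a tail category can appear in a reported rule only if it is
over-represented — in synthetic data, only where planted. The miner is
pure R, entirely adequate for hundreds of transactions over ~21 items but
not intended for market-basket-scale databases.
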