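# agrorules

Association-rule mining between monthly climate conditions and crop yield,
for agro-meteorological analyses in which a region is split into
agro-ecological zones (here: the Sudanian, Sudano-Guinean and Guinean zones
of Benin, observed through one synoptic station each). The package is aimed
at agricultural-informatics users who want to ask: *which combinations of
climate categories co-occur with high yield?* — and get back auditable
rules rather than a black-box fit.

## What it computes

Station records (daily or monthly) of minimum/maximum temperature (`Tmin`,
`Tmax`, °C), minimum/maximum relative humidity (`Umin`, `Umax`, %), rainfall
(`RR`, mm), sunshine (`Sun`, h) and evapotranspiration (`ET`, mm) are
aggregated to station-months and joined with the monthly yield (annual
yield / 12, kg/ha). Redundant predictors are removed with a pooled Pearson
correlation filter (|r| > 0.8 drops one member of the pair; with the usual
humidity collinearity this removes `Umin`). Per zone, each attribute *v* is
discretized by its mean ± standard deviation into

* `low`: v ≤ mean − sd
* `medium`: mean − sd < v < mean + sd
* `high`: v ≥ mean + sd

so every station-month becomes a transaction of items such as `ET=low` or
`Yield=high`. Frequent itemsets are mined per zone with a from-scratch
**FP-Growth** implementation (two-pass FP-tree construction, recursive
conditional-tree mining, single-path shortcut), and rules X ⇒ Y toward the
high-yield item are scored with

* support(X ⇒ Y) = freq(X ∪ Y) / N
* confidence(X ⇒ Y) = freq(X ∪ Y) / freq(X)
* lift(X ⇒ Y) = confidence / support(Y)

The reference configuration keeps rules with at least three antecedents,
support ≥ 0.2, confidence ≥ 0.8 and lift ≥ 1, and reports the five most
relevant per zone (confidence, then lift, then support, ties by label).

A levelwise Apriori enumerator (`enumerate_bruteforce()`) ships alongside
the miner purely as an independent oracle; the test suite checks exact
agreement of itemsets and counts on hundreds of random databases.

Because the original station data are not redistributable, the package
includes a synthetic generator: zone profiles are reconstructed from the
published threshold tables (`benin_thresholds()`, mean = midpoint,
sd = half-width), values are drawn from moment-matched truncated normals,
and known rules can be *planted* at exact support/confidence
(`plant_rule()`) for end-to-end recovery testing.

## Worked example

Simulate 26 years of monthly records for the three zones, plant the
Sudanian high-yield rule at support 0.25 / confidence 1, and run the
default pipeline:

```r
library(agrorules)

th      <- benin_thresholds()
profile <- profile_from_thresholds(th)
records <- generate_monthly_records(profile, 1995, 2020, seed = 11)

sudanian <- plant_rule(dplyr::filter(records, zone == "Sudanian"),
                       antecedent = c("ET=low", "Tmin=medium", "Umax=high"),
                       consequent = "Yield=high",
                       target_support = 0.25, target_confidence = 1,
                       thresholds = th, seed = 5)
records <- dplyr::bind_rows(sudanian,
                            dplyr::filter(records, zone != "Sudanian"))

run <- run_pipeline(records, thresholds = th)
tidy(run)
#> # A tibble: 1 × 7
#>   zone     antecedents                  consequent n_antecedents support confidence  lift
#> 1 Sudanian ET=low;Tmin=medium;Umax=high Yield=high             3    0.25          1  2.81
glance(run)
#> # A tibble: 3 × 5
#>   zone           n_transactions n_frequent_itemsets n_rules n_selected
#> 1 Sudanian                  312                  95      13          1
#> 2 Sudano-Guinean            312                  97       0          0
#> 3 Guinean                   312                  95       0          0
```

The planted rule comes back with support exactly 78/312 = 0.25 and
confidence 1: the 78 station-months whose evapotranspiration is low
(≤ 3.009 mm), minimum temperature medium (19.024–25.120 °C) and maximum
humidity high (≥ 94.264 %) are all high-yield months. Its lift of 2.81
says high yield is 2.81× more frequent under those conditions than
marginally. The unplanted zones select no rule: under independent
attributes `Yield=high` has probability ≈ 0.16, below the 0.2 support
floor — which is exactly why recovering a planted rule is informative.

`autoplot(run)` draws support vs. confidence of all scored rules by zone;
`plot_thresholds(th)` shows the per-zone medium bands. A thin CLI wrapper
lives at `inst/cli/agrorules.R` (`simulate`, `thresholds`, `run`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the whole pipeline from scratch against the installed package:
it rebuilds the three zone profiles from the packaged threshold tables,
simulates 1995–2020 monthly records, plants each zone's headline
high-yield rule (supports 0.250 / 0.416 / 0.457, confidence 1), runs the
correlation filter, discretization, FP-Growth and rule selection at the
reference settings, prints the per-zone summaries and selected rules, and
writes the JSON report to `--out`.
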