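# surgflow

Task-flow analysis of hierarchically annotated surgical activity.

Surgical tasks decompose into **maneuvers** (segments that accomplish a task
landmark — suture throw `ST`, grasp-pull-run `GPR`, two-loop knot `TLK`,
one-loop knot `OLK`, inter-maneuver segment `IMS`) which in turn decompose
into **gestures** (atomic actions such as driving or rotating the needle,
looping suture around the needle driver). Given per-trial annotation tables
— gesture events with error flags, maneuver spans with incomplete flags, and
skill assessments (self-reported experience plus a six-item OSATS global
rating score) — surgflow quantifies how task flow differs between skill
groups. It is aimed at surgical-education researchers comparing expert and
novice performance on robot-assisted bench-top tasks.

## What it computes

* **Segment counts** per trial (maneuvers, incomplete maneuvers, IMS,
  gestures, error gestures, gestures within each maneuver, named gestures
  within maneuvers), with skill-group means and 95% percentile bootstrap
  intervals (1000 trial-level resamples), and an interval-non-overlap
  significance rule.
* **Transition structure**: first-order transition matrices per skill group
  at the maneuver level and within maneuvers; per-state **Hellinger
  distance** between groups,
  H(p,q) = (1/√2)·√Σᵢ(√pᵢ−√qᵢ)², with bootstrap intervals; the
  **conditional entropy** H = −Σₓ m(x) Σᵧ P(y|x)·log P(y|x) of each group's
  flow and the expert-minus-novice difference; Graphviz DOT state-flow
  exports with edge thickness proportional to transition fractions.
* **Inter-annotator reliability**: Levenshtein distance between paired
  label sequences normalised per 10 reference labels, and frame-level
  Cohen's kappa per robot-arm gesture category.
* **Skill classification**: experience-based, and three GRS-based schemes
  (total thresholds <14 / >22; two item-level rules).
* **Synthetic data**: a skill-conditioned semi-Markov generator with known
  ground truth, calibrated so expected expert/novice totals are
  26.3 vs 31.3 gestures and 1.00 vs 2.84 error gestures per trial, for
  validating every stage without access to the original data.

## Worked example

```r
library(surgflow)

gen <- generate_dataset(seed = 1)   # 18 surgeons, 135 trials (study shape)
ds  <- gen$dataset

group_mean_bi(ds, "total_gestures", "experience", n_boot = 1000, seed = 2)
#>           metric  group   n     mean   bi_low  bi_high n_boot seed
#> 1 total_gestures expert  30 26.03333 22.60000 29.36667   1000    3
#> 2 total_gestures novice 105 29.56190 26.92333 32.58310   1000    4

groups <- split_by_skill(ds, "experience")
compare_flows(groups$expert, groups$novice, "maneuver",
              n_boot = 1000, seed = 3, include_virtual = TRUE)
#>   state  hellinger     bi_low   bi_high n_undefined convention
#> 1   GPR 0.23370801 0.15217643 0.3486528           0 normalized
#> 2   IMS 0.04612576 0.04195283 0.2408886           0 normalized
#> 3   OLK 0.40118938 0.33806758 0.4538782           0 normalized
#> 4    ST 0.21105345 0.13420379 0.3031610           0 normalized
#> 5   TLK 0.25979837 0.18519172 0.3198992           0 normalized

ed <- entropy_difference(groups$expert, groups$novice, "maneuver",
                         n_boot = 1000, seed = 4)
#> difference -0.396 bits (95% BI -0.587 to -0.256)
```

The expert group uses fewer gestures (26.0 vs 29.6 on this draw; each mean
lies outside the other group's interval, so the difference is flagged
significant), its flow differs most where novices chain one-loop knots
(`OLK`), and its negative entropy difference says expert task flow is the
more predictable one.

`run_full_report(ds, "out/")` writes all tables (CSV), DOT state-flow
graphs and a provenance manifest in one call. A thin command-line front end
with `simulate`, `validate`, `describe`, `reliability`, `transitions` and
`report` subcommands lives at `inst/cli/surgflow.R`.

Real annotation data in the deposited three-table dialect (gestures,
maneuvers, skill assessments; tab-delimited) are loaded with
`read_dataset_dir()` and flow through the identical pipeline.

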