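---
title: "Methods: quantifying surgical task flow from hierarchical annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying surgical task flow from hierarchical annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgflow)
```

## The data model

surgflow analyses trials of a bench-top suturing and knot-tying task
(a single suture throw followed by a 2–1 surgeon's knot, performed on a
tele-operated surgical robot and videoed at 30 fps) that have been annotated
with a two-level vocabulary:

* **Maneuvers** are circumscribed segments that accomplish a task landmark.
  Seven raw labels — suture throw (`ST`), grasp-pull-run (`GPR`), two-loop
  knot and one-loop knot with a left/right-arm variant each
  (`TLK_L`/`TLK_R`, `OLK_L`/`OLK_R`), and the inter-maneuver segment
  (`IMS`) — collapse onto five analysis labels.
* **Gestures** are atomic segments nested inside maneuvers, drawn from a
  30-label vocabulary of which nine are named (`DN`, `GN`, `RN`, `PN`, `AD`,
  `LS`, `GT`, `PT`, `TK`); the remaining labels are configurable
  placeholders, so no analysis depends on their identity. Each gesture
  carries an error flag, each maneuver an incomplete flag.

The deposited table dialects carry no timestamps: row order within a trial
defines temporal order. Frame spans, where present (generator output,
frame-level annotation), are 0-based and half-open `[start, end)` — a
convention chosen so adjacent segments compose without ±1 bookkeeping.

Each trial also has a skill record: a self-reported experience class
(attending surgeons with robotic practices = expert, trainees = novice) and
a global rating score (GRS) built from six OSATS items scored 1–5 (the
"use of assistants" item does not apply to the task). Three GRS-based
classifications are implemented; the item-level rules (`grs2`, `grs3`)
require item scores and refuse totals-only data rather than guessing. In
the `grs2` expert rule, "more than 3 on at least four items and at least 3
on the remaining two" is generalised to *every* item outside the >3 set
being at least 3, so tuples with five or six items above 3 are classified
expert rather than left undefined.

## Statistics

**Counts.** The descriptive panel per trial: total/incomplete maneuvers,
IMS count, total/error gestures, gestures within each collapsed maneuver,
and named-gesture counts per maneuver. Group summaries are means over
trials with 95% percentile bootstrap intervals (1000 resamples), resampling
*trials* with replacement: each repetition by a surgeon is treated as an
independent data point, which mirrors how the study data were analysed and
is a known limitation (surgeon-level clustering is ignored). Two groups are
declared different when a group mean falls outside the other group's
interval. The wording of that rule is ambiguous in one direction; the
default (`"either"`: one exclusion suffices) and the stricter `"both"` are
both available and the report states which directions fired.

**Bootstrap.** One shared engine performs all resampling: trials are put in
a canonical order (sorted by trial id) so results do not depend on file row
order, indices are drawn with `sample.int` from a seeded RNG stream, and
intervals are percentile intervals with linear interpolation between order
statistics (`quantile` type 7). Replicates on which a statistic is
undefined (for example, a transition row empty after resampling) are
dropped and counted; when more than half are undefined the interval is
flagged unreliable rather than silently reported. BCa or studentised
intervals are deliberately out of scope.

**Transitions.** Task flow is modelled as a first-order Markov chain over
the collapsed maneuvers (or over gestures within one maneuver type).
Adjacent pairs are counted within each sequence only — never across trial
or maneuver-instance boundaries — and consecutive identical labels count as
genuine self-transitions (novices, for instance, chain one-loop knots
directly). Virtual `START`/`END` states are available but excluded from the
comparison statistics by default, matching plots that show task states
only. Rows with no outgoing transitions are zero rows, flagged rather than
smoothed; additive smoothing is available but defaults to 0. For states
that usually terminate the task (an expert's one-loop knot exits directly
most of the time), the in-task-only row can be empty in a finite sample;
including the virtual `END` state (`include_virtual = TRUE`) makes every
outgoing distribution well-defined by counting exits, and the end-to-end
report and acceptance script use that variant for the maneuver-level
Hellinger comparison.

**Hellinger distance.** Outgoing-transition rows of two skill groups are
compared per state by
\(H(p,q) = \tfrac{1}{\sqrt 2}\bigl(\sum_i (\sqrt{p_i} - \sqrt{q_i})^2\bigr)^{1/2}\),
bounded in [0, 1] (the default, "normalized" convention); the
unnormalized variant without the \(1/\sqrt2\) factor (range \([0,\sqrt2]\))
is also implemented because published values for this kind of analysis are
not always consistent with a single convention — interval bounds above
\(\sqrt2\) appear in the literature and cannot be reproduced under either
definition, so the convention used is always recorded in the output.
Intervals come from rebuilding both groups' models on each bootstrap
replicate.

**Conditional entropy.**
\(H = -\sum_x m(x) \sum_y P(y\mid x)\log P(y\mid x)\) with \(m\) the
empirical distribution of transition sources and \(0\log 0 = 0\): zero for
fully predictable flow, \(\log |S|\) for uniform rows under a uniform
marginal. The logarithm base is a parameter (default 2, bits) because
published entropy differences for such analyses rarely state the base; the
expert-minus-novice difference can be computed under both.

**Reliability.** Sequence agreement between two annotators is the
Levenshtein distance (standard dynamic program, unit costs), normalised per
10 labels of a designated reference annotation — the denominator is
configurable and reported because "per 10 labels in a trial" does not name
it; per-trial normalised distances are averaged unweighted and
bootstrapped like every other statistic. Frame-level agreement is Cohen's
kappa computed separately per robot-arm category (a frame can carry labels
from several categories), over the category's labels plus an explicit
background label for unannotated frames; kappas are reported pooled across
trials and per trial.

## The synthetic generator

Because the study's annotation files cannot be redistributed, the package
ships a generator whose defaults emulate the study conditions: 4 expert and
14 novice surgeons with 8 and 7 trials alternating (135 trials — the study
count, which 18 does not divide evenly). Maneuver sequences come from
skill-specific absorbing Markov chains; gestures within each maneuver from
per-maneuver chains built around a canonical gesture path (`GN→DN→RN→PN`
for the suture throw, `LS→GT→PT→TK` for both knots) with skill-dependent
adjustment-insertion and step-repeat probabilities; errors and incomplete
flags are Bernoulli; durations are i.i.d. log-normal frame counts
(meanlog \(\log 40\), sdlog 0.35 at 30 fps, i.e. ≈1.3 s typical) tiling
each maneuver span; GRS items are rejection-sampled to be consistent with
the trial's class under all three GRS definitions at once, so one dataset
exercises every scheme.

The chains are *phase-progressive* — detours through IMS are short and
mostly move the task forward — because a free IMS hub would produce
near-geometric trial lengths with unrealistically heavy tails. Two
structural contrasts are built in: the expert chain has no direct
`TLK→OLK` or `OLK→OLK` edges (those transitions are a novice signature),
and novice chains repeat and backtrack with small probabilities.
Calibration is analytic, not simulated: expected maneuver visits are
\(s^\top (I-Q)^{-1}\) for the chain's transient part, expected gestures per
instance likewise, and the insertion/repeat rates were set so the expected
total gestures per trial are 26.31 (expert) and 31.30 (novice); error
probabilities are then targets/expectation (1.00 and 2.84 expected error
gestures) by construction. `expected_profile_stats()` exposes these
closed forms, and the test suite checks the generator against them.

The generator does **not** model surgeon-level random effects, session
structure, learning over weeks, realistic duration dependence, or the full
30-gesture vocabulary in use — passing recovery tests therefore shows the
pipeline is correct on data satisfying its own assumptions, not that real
annotation data meet them. The annotator-corruption model (independent
per-position substitutions/insertions/deletions plus boundary jitter) is
plumbing to exercise the reliability metrics, with edit rates chosen to
produce disagreement of the order seen between trained annotators
(a few edits per 10 gesture labels).

## Numerical and design choices

* Degenerate inputs: empty tables parse to empty records; a trial present
  only in the skill table is retained with empty sequences and flagged as a
  warning; orphan or out-of-range maneuver references are validation
  errors, and the report refuses datasets with validation errors rather
  than repairing them.
* Kappa with a single shared constant label has chance agreement 1; it is
  defined as 1 when the tracks are identical and flagged undefined
  otherwise.
* A single bootstrap replicate (or a constant statistic) yields a
  degenerate interval, flagged.
* DOT export orders nodes and edges lexicographically and formats numbers
  with fixed precision, so output is byte-stable; edge pen-width is
  proportional to the source row's transition fraction and a minimum edge
  fraction filters rare edges from plots.
* Problem sizes used by the test suite — e.g. 500 sequences for transition
  recovery, 100 trials per group for the group contrast, 1000 simulations
  for bootstrap coverage — are chosen as the smallest sizes at which the
  Monte-Carlo tolerances quoted in the tests are meaningful.

## Worked example

```{r example, eval = FALSE}
gen <- generate_dataset(seed = 1)          # 135 trials, 18 surgeons
ds  <- gen$dataset

group_mean_bi(ds, "total_gestures", "experience", n_boot = 1000, seed = 2)

groups <- split_by_skill(ds, "experience")
compare_flows(groups$expert, groups$novice, "maneuver",
              n_boot = 1000, seed = 3)
entropy_difference(groups$expert, groups$novice, "maneuver",
                   n_boot = 1000, seed = 4)
```

The same computations, plus reliability on a corrupted second annotation
and DOT state-flow exports, are produced end to end by `run_full_report()`
and by `scripts/acceptance.R` at the repository root.

## Known limitations

Trials are treated as independent (no surgeon clustering in the bootstrap);
the interval-non-overlap rule is conservative relative to a formal test and
carries no multiplicity control, matching the descriptive spirit of the
analysis; gesture-level comparisons use only the named gesture subset by
default; and reproduction of numbers computed on the original deposited
annotation files requires those files, which the package reads
(`read_dataset_dir()`) but cannot ship.
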