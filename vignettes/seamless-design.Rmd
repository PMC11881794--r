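---
title: "The seamless diagnostic accuracy design: model, decisions, and simulation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The seamless diagnostic accuracy design: model, decisions, and simulation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamlessDx)
```

## The statistical model

A single index test is compared with a reference standard that defines the
target condition. Every analysis reduces to two independent binomial
proportions: among the $n_{case}$ subjects with the condition, the number
of true positives is $Binomial(n_{case}, se)$; among the $n_{ctrl}$
subjects without it, the number of true negatives is
$Binomial(n_{ctrl}, sp)$. Sensitivity and specificity are co-primary:
confirmation requires rejecting *both* one-sided nulls $se \le se_0$ and
$sp \le sp_0$, which the intersection–union principle achieves without any
multiplicity adjustment. Operationally, each endpoint is rejected when the
lower limit of its two-sided $(1-\alpha)$ Wilson score interval is
strictly above the minimum value. With $\alpha = 0.05$ each endpoint test
is one-sided at 2.5%, and because the two binomials are independent, the
nominal level of the global test is $0.025^2 = 0.000625$
(`nominal_global_level(0.025)`).

The Wilson interval is used throughout, plainly (no continuity
correction): it behaves well near the boundaries of the unit interval,
where diagnostic accuracy values live. Alternative intervals
(Wald, Clopper–Pearson) are deliberately not offered.

## The two-stage procedure

The seamless design recruits population-based from the start.

1. **Stage I.** After a fraction $s$ (the *stopping time*) of the intended
   final sample size $N$ has been recruited, external cases are *added*
   (e.g. from retrospective sources) until cases and controls are balanced
   1:1. This interim analysis population is close to a classical
   case–control study, but its controls are already representative.
2. **Interim decision.** The study continues only if both interim point
   estimates are strictly above their futility boundaries
   $(f_{se}, f_{sp})$; otherwise it stops for futility. There is no
   stopping for success — added cases make overoptimistic estimates
   likely, so an early "success" claim would be unreliable.
3. **Stage II.** Recruitment continues to $N$. The added cases are
   removed, the stage-I population subjects are kept, and the final
   analysis is the ordinary population-based confirmatory analysis
   described above.

Because stopping is futility-only, the final test needs no level
adjustment. What the double use of the stage-I population data *can* do is
bias the final estimates conditionally on continuation — trials that
survive the interim hurdle tend to have had lucky stage-I draws. The
simulation machinery in this package exists to quantify exactly that.

### Composition arithmetic

`interim_composition(p, N, s)` computes the planned interim population:
$n_1 = \mathrm{round}(sN)$ recruited subjects, $\mathrm{round}(p\,n_1)$
expected cases, the remainder controls, and added cases by subtraction.
Rounding is **half-up**, applied first to $n_1$ and then to the expected
case count; this order reproduces the planning table for all combinations
of $p \in \{0.1, 0.2, 0.3\}$, $N \in \{167, 250, 333, 500, 1000\}$ and
$s \in \{0.1, 0.2, 0.3\}$, including the non-integer products, and makes
the balance `pop_cases + added_cases = controls` an exact identity.

`composition_for_target_interim_total(p, T)` supports the alternative
parameterization where the interim analysis population itself is fixed at
$T$ subjects split 1:1. Here the added-case requirement
$T/2 \cdot (1-2p)/(1-p)$ is rounded half-up *last*, which again preserves
exact balance (at $p = 0.1$, $T = 100$: 44 added cases). Rounding the
population stream size first instead would break balance by one subject
for half-integer cases.

At the trial itself the added-case requirement is recomputed from the
*realized* stage-I split (`observed_added_cases(cases, controls)`), not
from the planned prevalence.

Designs with prevalence above 0.5 would add controls instead of cases.
The package does not implement that mirror image; the composition
functions refuse such inputs explicitly rather than silently swapping
roles.

## Tunable parameters

| Parameter | Meaning | Default / typical | Why |
|---|---|---|---|
| `final_n` (N) | final-analysis sample size | chosen externally | determined by the usual single-proportion precision arguments, e.g. $N = 500$ at $p = 0.2$ yields 100 cases and SE $\approx \sqrt{0.9 \cdot 0.1/100} = 0.03$ for $se = 0.9$ |
| `stopping_time` (s) | stage-I fraction | 0.1–0.3 | large enough for interim precision, small enough to limit waste on futile tests; `validate_design()` warns outside this range |
| `f_se`, `f_sp` | futility boundaries | ~10 points below the minimum values | low boundaries risk continuing futile tests; high ones risk stopping adequate tests |
| `se0`, `sp0` | minimum acceptable values | design-specific | the confirmatory hypotheses |
| `ci_level` | two-sided CI level | 0.95 | gives one-sided 2.5% endpoint tests and a 0.000625 global level |
| `margin_mode` | case/control margins | `"fixed"` | see below |

**Tie rule.** Continuation requires estimates *strictly above* the
boundaries, and rejection requires CI lower limits *strictly above* the
minimum values; equality stops and does not reject. Ties are therefore
resolved conservatively for confirmation and in favour of stopping at the
interim. This convention is fixed, not configurable, so that two analyses
of the same design can never disagree.

## The simulation engine

`run_trials()` draws whole trials as binomial counts, not per-subject
streams: stage-I population true positives, added-case true positives and
control true negatives, then stage-II true positives and true negatives —
always in that fixed order, for *every* replicate, whether or not it
stops. Two consequences:

* re-running with the same seed but different futility boundaries shares
  every underlying count, so paired comparisons (seamless vs the
  cohort-only comparator in `cohort_only_power()`) isolate the stopping
  rule's effect with no Monte Carlo noise between arms, and seamless power
  is pairwise $\le$ cohort-only power by construction;
* the stage-I population counts are *carried unchanged* into the final
  counts (data reuse) and the added-case counts are discarded, mirroring
  the design's accounting exactly.

**Margin modes.** With `margin_mode = "fixed"` (default) the case/control
margins are the deterministic planned compositions; this matches how the
scenario grid's sample sizes were chosen (to put about 100 or 50 cases in
the final analysis) and makes the exact enumeration oracle available.
With `"binomial"` the stage-I case count is drawn
$Binomial(n_1, p)$ and the added-case requirement recomputed from the
realized split, emulating a trial that rebalances on observed data; the
stage-II case count is likewise binomial. Which regime an actual
simulation study of this design used is not derivable from its summary
figures, so both are provided and the default is the one consistent with
the deterministic planning table.

**Added-case sensitivity.** Enriched cases may be easier to detect; the
truth object carries an additive shift `delta_add` for their sensitivity,
clamped at 1 (`min(se_true + delta_add, 1)`) — the only probability-valid
choice when, e.g., $se = 0.95$ and the shift is $0.1$.

**Degenerate interim estimates.** Under binomial margins a realized margin
can be empty (probability $\le p^{n_1}$, about $10^{-17}$ over the grid),
making an interim estimate `NaN`; the engine then stops, the conservative
reading of "not strictly above".

**The enumeration oracle.** For fixed margins,
`exact_stopping_probability()` computes $P(\text{stop})$ exactly: the
interim true-positive count is the convolution of the two case binomials,
the true-negative count a single binomial, and both strict comparisons are
evaluated on the same `count / margin` floating-point scale the simulation
uses, so oracle and engine can never disagree through rounding. The test
suite holds the Monte Carlo stopping frequency inside the central 99.7%
band of the binomial distribution implied by the oracle.

## The scenario study

`build_grid()` crosses $N \in \{333, 500, 1000\}$, $s \in \{0.1,0.2,0.3\}$,
$p \in \{0.1,0.2,0.3\}$, true sensitivity and specificity in
$\{0.65, 0.75, 0.85, 0.95\}$, the boundary-minus-truth distance
$\Delta \in \{-0.3, -0.25, \dots, 0.1\}$ (the same distance for both
endpoints, so $f_{se} = se + \Delta$, $f_{sp} = sp + \Delta$) and the
added-case shift $\delta_{add} \in \{0, 0.1\}$ — 7776 scenarios in a
deterministic order (earlier factors vary fastest). Note that
$\Delta = 0.1$ with truth 0.95 puts a boundary above 1: such trials always
stop, which is intended, and is why the design constructor accepts
boundaries outside $[0, 1)$.

Per scenario, `run_scenario()` computes:

* **stopping frequency** — stopped runs over all runs;
* **conditional relative bias** — mean estimation error over non-stopped
  runs, divided by $1 - \text{truth}$, times 100 (the same absolute bias
  is more harmful near 1);
* **conditional / unconditional coverage** — the unconditional convention
  counts stopped runs as covering, so
  $\text{uncond} = \text{stop} + (1-\text{stop})\cdot\text{cond}$ holds as
  an exact identity (tested exactly, not approximately);
* **power** over all 25 pairs of hypothetical minimum values from
  $\{0.55, 0.65, 0.75, 0.85, 0.95\}$, stopped runs counted as
  non-rejections;
* **type I error** — the power entry at the pair equal to the true
  values, defined only when the truth lies on that grid.

**Seeding.** `run_grid()` draws one seed per scenario from the master seed
up front, so results are independent of execution order and bit-for-bit
reproducible.

**Reporting filters.** Conditional measures are unstable when almost every
run stops. `summarize_across_designs()` omits designs with fewer completed
final analyses than a threshold stated at 40000 replicates (40 for bias,
200 for conditional coverage) and scaled proportionally (ceiling) to the
actual replicate count. Percentiles use linear interpolation between order
statistics (R's default type 7). Bias and coverage summaries **pool** the
sensitivity and specificity values of each design before taking
percentiles; pooling is one of two defensible readings of endpoint-level
summaries (the other is per-endpoint percentiles) and is recorded in the
results metadata sidecar.

## What the generator does and does not emulate

The generator reproduces the probabilistic skeleton of a seamless trial:
binomial test results given true accuracies, case enrichment and its
removal, the futility rule, and the data reuse between analyses. It does
*not* emulate imperfect reference standards, verification bias,
covariate-dependent accuracy, delayed reference results, partial
enrichment pools (the composition functions merely warn when a declared
pool is too small), or sample-size reassessment. Passing tests therefore
demonstrate that the *design's arithmetic and inference machinery* behave
as claimed under the stated binomial model — not that any real trial's
data meet that model.

## Numerical and testing choices

* **Problem sizes.** The package's own summary checks run the grid slices
  that drive each claim at 2000 replicates per design for stopping
  frequencies (432 designs per slice) and 5000 for the bias percentile
  (288 designs); at these sizes the median stopping frequency at
  $\Delta = 0$ is stable to a few tenths of a point across seeds. The
  full 7776 × 40000 study is reachable with the same functions
  (`run_grid(build_grid(), reps = 40000, ...)`).
* **Wilson coverage oscillation.** The exact coverage of the Wilson
  interval oscillates in $(n, p)$; at $n = 100$, $p = 0.85$, for example,
  it is 0.933. Tests of the no-stopping reduction therefore compare Monte
  Carlo coverage against the *enumerated* exact coverage at the
  scenario's margins, and the blanket "at least 94.5%" check is placed at
  a truth where the enumerated coverage is genuinely above nominal —
  conservatism is a property of $(n, p)$, not of the design.
* **Monte Carlo bands.** Agreement checks against the enumeration oracle
  use exact binomial quantile bands (the 3-sigma analogue), computed on
  the complement scale when the stopping probability is near 1, where
  `qbinom` loses accuracy.

## Known limitations

* Single index test only: no comparative two-test designs, no ROC/AUC
  endpoints, no weighted composites (e.g. a Youden-index futility rule).
* Case enrichment only (prevalence < 0.5); the add-controls mirror image
  is not implemented.
* No formal final-analysis sample-size derivation; `se_of_proportion()`
  supports the back-of-envelope argument only.
* The engine accepts unequal futility distances for the two endpoints,
  but the bundled grid only covers the equal-distance case.
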