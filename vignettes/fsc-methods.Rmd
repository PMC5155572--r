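---
title: "Feedback-driven combination screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-driven combination screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscombo)
```

## The problem and the method

Combination chemotherapy regimens are usually assembled from bi-drug
interaction assays, yet clinical regimens carry three or more drugs. For a
panel of six drugs at five doses each, exhaustive testing means
$5^6 = 15{,}625$ viability assays per cell line — infeasible at the bench.
`fscombo` implements the closed-loop alternative: a differential-evolution
(DE) search proposes a small batch of drug–dose combinations, a viability
assay (or its in-silico stand-in) scores them, and the scores feed the next
round of proposals, so that well under 1% of the design space is ever
touched.

The search objective is the **average cumulative survival**
$$\mathrm{ACS} = \frac{1}{m}\sum_{c\,\in\,\text{panel}} S_c,$$
the sum of per-cell-line survival percentages for one combination divided
by a fixed panel divisor $m$. Lower is better; a combination is called
*effective* when $\mathrm{ACS} < 30\%$ (strict). The divisor is an explicit
parameter of every table, never inferred from the number of measured
values: the published fourth-round screen divides a seven-value sum by
eight, and the package reproduces that arithmetic verbatim.

Selectivity of a candidate regimen against a benign reference line is
summarized by the **therapeutic window**
$$\mathrm{TW} = (100 - S_{\text{benign}}) - \mathrm{ACS}_{\text{cancer}},
\qquad \mathrm{TW_{index}} = \mathrm{TW} - \mathrm{ACS}_{\text{cancer}}.$$
The prose definition accompanying these metrics in the source material
("the difference in treatment-triggered cell survival between the benign
and cancer lines") does not reproduce the printed values; the identities
above reproduce both printed numbers exactly from the printed inputs and
are the ones implemented.

## Scoring the published screens

The three published screening tables ship as package data
(`reference_viability_table()`), transposed to one row per combination,
with the printed summary statistics retained for cross-checks. Recomputing
every summary cell from the printed survivals reproduces 108 of 116 cells
exactly under half-up rounding at two decimals. The eight exceptions all
differ by exactly 0.01: four sums land on exact `.xx5` ties of which the
source rounded three down and one up (no single rounding rule covers
both), and five cells of one cumulative-score row are inconsistent with
their own printed survivals at the last digit, indicating the source
computed them from unrounded raw readings. Tests assert exactness where
the source is self-consistent and a 0.01 band with an exact mismatch count
elsewhere. Display rounding in the package is half-up
(`round_half_up()`; 23.025 → 23.03), with a small epsilon guard so binary
representation error cannot turn a decimal tie into a non-tie.

## The dose grid

Six drugs (Pi, Pa, EH, Ci, Ge, Mi) on five-point, five-fold ladders
(ng/mL). Only four non-zero doses per drug appear in the published tables;
the fifth level extends each ladder one five-fold step *downward*, a
choice that affects no fixture-based computation because grids are
config-driven. A zero dose is a per-round option, not a grid level: the
published search opened it in round 3 to shrink six-drug combinations to
four or five drugs, and `de_config(zero_from_round = 3)` mirrors that
schedule.

## The search loop

`run_fsc_loop()` is canonical DE/rand/1/bin on integer level indices:
mutation $v = x_{r1} + F(x_{r2} - x_{r3})$ with three distinct donors,
binomial crossover at rate CR with one forced coordinate, rounding to the
nearest level, clamping to the valid index range, and greedy member-wise
selection in which ties keep the parent. Level-index arithmetic makes
mutation steps scale-free across drugs whose ladders span five orders of
magnitude. Every distinct combination is evaluated once and cached;
repeats are free.

Defaults follow the published screen: batches of `np = 20`, four rounds
with the last batch doubled (100 evaluations, 0.64% of the default grid),
`F = 0.8`, `CR = 0.9`. Two additions address discrete-grid pathology:

* **Stall repair** (`stall_repair`, default 0.15): when rounding collapses
  a trial onto its parent — which becomes the *only* outcome once the
  population loses diversity in a coordinate, since all difference vectors
  are zero there — the forced coordinate is nudged one level with this
  probability. Without it a discrete population can stall permanently
  below the optimum.
* **Evaluation budget** (`max_evaluations`): an explicit cap on distinct
  oracle calls. Because cached repeats are free, a budgeted run can
  iterate many selection rounds; trials beyond the budget stay unevaluated
  and their parents are kept.

For benchmark runs that must *find* a planted optimum under a tight
budget (200 distinct evaluations on the $5^6$ grid), the package's tests
use `np = 10`, `CR = 0.3`, `stall_repair = 0.2`: a compact population
converts the budget into more selection rounds, and a low crossover rate
is the standard DE recommendation for near-separable objectives (each
trial then changes few coordinates, approximating coordinate descent).
This configuration locates the all-top-dose optimum of noiseless monotone
surfaces in 60 of 60 held-out seeds and lands in the top 0.5% of the
exhaustively enumerated ranking on random additive surfaces; the demo
default stays at the published batch size.

## The viability simulator

`response_surface_sim` stands in for the plate assays so that the whole
loop runs offline. Each cell line is a set of per-drug Hill curves — kill
$k_i = e_i d_i^{h_i} / (\mathrm{EC50}_i^{h_i} + d_i^{h_i})$ with maximal
kill $e_i \in [0,1]$ — composed across drugs by Bliss independence with a
pairwise additive deviation on the survival-fraction scale:
$$S = 100\,\mathrm{clamp}\!\Big(\prod_i (1-k_i) +
3\sum_{i<j}\gamma_{ij}k_ik_j,\;0,\;1\Big),$$
$\gamma_{ij} = 0$ exact Bliss, $\gamma < 0$ synergy, $\gamma > 0$
antagonism. Archetypes (`sensitive`, `moderate`, `resistant`, `benign`)
draw EC50s log-uniformly from bands spanning the observed heterogeneity
(resistant bands 10× and more above sensitive; the benign archetype has
uniformly high EC50 and reduced attainable kill, mimicking an immortalized
normal line). Measurement noise is Gaussian on the percent scale, default
sd 3% — typical MTT triplicate scatter — with triplicate means reported and
entries truncated to [0, 120].

Two calibration choices deserve explanation:

* **Why an additive deviation with a factor of 3, not a multiplicative
  one.** Expanding the Bliss product shows the survival surface of two
  *independent* inhibitory drugs already carries a positive cross term
  $+k_ik_j$: on the survival scale, Bliss independence itself looks
  "antagonistic" to a second-order fit. A multiplicative deviation
  $(1+\gamma k_ik_j)$ shifts that cross term to $(1+\gamma)k_ik_j$, which
  stays positive for every $\gamma > -1$; no admissible $\gamma$ can flip
  the fitted bilinear sign, so planted synergy would be statistically
  invisible by construction. The additive form with amplitude 3 makes a
  moderate $|\gamma| = 0.5$ exceed the intrinsic curvature while leaving
  $\gamma = 0$ exactly Bliss.
* **What the simulator does not emulate.** No pharmacokinetics, no
  time-dependence, no mechanistic pathway coupling, and noise is
  homoscedastic where real MTT scatter grows near 100% survival. Passing
  tests therefore certify the *pipeline arithmetic and search behaviour*
  under controlled conditions, not biological fidelity.

## Response-surface regression

`fit_polynomial()` fits the full second-order surface — intercept, $k$
linear, $k$ quadratic and $k(k-1)/2$ bilinear dose terms; 28 columns for
six drugs — by ordinary least squares, computed on internally rescaled
columns for conditioning (dose ladders span 0.008–1500 ng/mL) and
reported on the raw ng/mL scale. `simplify_model()` is a bidirectional
greedy stepwise minimizing AIC by default, with BIC or any explicit
penalty-per-parameter available, and hierarchy enforced: a quadratic or
bilinear term is only retained together with its linear parents unless
`hierarchy = FALSE`. A near-zero residual sum of squares is floored at
$10^{-12}\cdot\mathrm{TSS}$ inside the criterion so that interpolating
fits remain comparable by parsimony; an infinite penalty collapses to the
intercept-only model. With hierarchy off, the procedure reproduces
`stats::step()` term-for-term on planted examples — the two routes serve as
mutual checks, and the hand-rolled version exists because `step()` cannot
enforce hierarchy across `I(x^2)`-style columns.

For *support recovery* (which terms are real, rather than which model
predicts best), the package's tests and analysis scripts use an explicit
penalty of 10 per parameter. AIC's per-term false-positive rate (about
16%) across ~24 spurious candidates admits at least one intruder in
virtually every run — a property of AIC, not of any implementation — so
the selection-consistent penalty is the right tool for that question.

`interpret_interactions()` reads a fitted surface the way the screening
analysis does: on a survival response a retained negative bilinear
coefficient is a synergy call, a positive one antagonism; a drug with a
negative linear slope but the largest positive quadratic coefficient has
diminishing returns, and is recommended for elimination when it also owns
the largest positive bilinear coefficient. Quadratic ties break toward the
drug with the larger total absolute bilinear involvement (deterministic).

**Where interaction signs are identifiable.** For drugs that kill
effectively, the high-dose corner of the grid is already near 0% survival
under independence alone; clamping then erases any planted synergy
exactly where the bilinear design column has its weight, and no generator
mechanism can make the fitted sign track $\gamma$ (measured: 0–54% sign
recovery across archetypes, mechanisms and design scales). Interaction
structure is identifiable only *off the kill floor*: the package's
sign-recovery experiments use sub-potent profiles (EC50 at twice the top
ladder dose, $e = 0.9$), where recovery is 98–100% over 50 seeded runs at
triplicate noise. This mirrors the screening analysis itself, which
resolved its negative bilinear coefficient in the most chemoresistant
line — the one whose survivals stay far from the floor.

The printed full-screen fit statistics ($R^2 = 0.7015$,
$p = 2.439\times10^{-15}$ for one cell line) require the two unpublished
middle screening rounds and are therefore not asserted anywhere; the
recovery properties above stand in for them.

## Pathway-reporter digitization and concordance

Dual-luciferase readings normalize as
$\max(\mathrm{firefly} - \mathrm{background}, 0)/\mathrm{Renilla}$, with
replicates averaged after normalization and sub-background firefly
readings clamped to zero under a warning. Fold-changes against the
reference profile digitize to ternary states — activated ($> 1.5$-fold),
repressed ($< 0.5$-fold), null otherwise; both comparisons strict, both
thresholds configurable. Concordance between two treatments' state
vectors is sample Pearson correlation with an inclusive 0.917 cutoff. A
constant state vector has no defined correlation and raises an explicit
error rather than silently returning 0 or 1; the matrix helper reports
such pairs as `NA` with a warning. The pathway list defaults to the nine
assayed reporters but is taken from the data everywhere.

## Problem sizes and reproducibility

Simulation-backed checks run at the sizes stated in-line: 100-combination
screens for regression properties, 200 null simulations for the F-test
size, 50 seeded runs for sign recovery, 20 seeds (after three disjoint
20-seed tuning sets) for the budgeted-search benchmark, 30 random additive
surfaces against exhaustive enumeration of all 15,625 grid points. Every
stochastic step draws from R's RNG under an explicit seed; `run_pipeline()`
writes a manifest with the seed and MD5 digests of all outputs, and
identical configuration plus seed reproduces digest-identical runs.

## Known limitations

* The DE control parameters and stopping rule of the original wet-lab
  search were never published; the per-round effective-count trajectory
  (4/20 → 9/20 → 33/40) is reproduced as *re-scored arithmetic on the
  printed tables*, not as a property of the re-implemented search.
* IC50s for sub-potent drug–line pairs whose curves never cross 50% are
  reported as flagged boundary estimates by the interpolation method; the
  4PL method refuses them.
* The bilinear-sign reading of synergy is scale-bound (survival percent,
  raw doses); on other response scales the same data can yield other
  signs. The vignette section above states the regime in which the
  reading is reliable.
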