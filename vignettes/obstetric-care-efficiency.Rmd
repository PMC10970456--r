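---
title: "Benchmarking obstetric-care efficiency in a fragmented health system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking obstetric-care efficiency in a fragmented health system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deacare)
```

## The problem

Latin-American public health systems are typically *fragmented*: several
disconnected institutions each serve a fixed population segment (formal-sector
workers, government employees, the armed forces, the uninsured), plan their
resources independently, and rarely share capacity. Mexico's obstetric-care
system is the package's reference case: six federal institutions (SS, IMSS,
ISSSTE, PEMEX, SEDENA, SEMAR) deliver about 95% of public obstetric services,
three of them in all 32 states and three with partial state presence. When
demand concentrates in one or two institutions while others hold idle delivery
rooms and gynecologists, the system as a whole under-produces even though its
total capacity could meet need. `deacare` quantifies that mismatch.

The analysis object is the **decision-making unit (DMU)**: one institution's
operation within one state. Its **technical efficiency** is measured
non-parametrically by data envelopment analysis (DEA) against the best-practice
frontier spanned by all DMUs.

## The model

For DMU $i$ with input vector $x_i \ge 0$ and output vector $y_i \ge 0$, and
matrices $X, Y$ collecting all units column-wise, the input-oriented
envelopment program under constant returns to scale (the CCR model) is

$$
\theta_i = \min \{\, \theta \;:\; Y\lambda \ge y_i,\;
\theta x_i - X\lambda \ge 0,\; \lambda \ge 0 \,\}.
$$

$\theta_i \in [0, 1]$ is the largest equiproportional (radial) contraction of
$i$'s inputs that some nonnegative combination $\lambda$ of observed units
could sustain at $i$'s output level; $\theta_i = 1$ puts the unit on the
frontier. Variable returns to scale (the BCC model) adds
$\sum_j \lambda_j = 1$ and is available via
`dea_config(returns_to_scale = "variable")`, but constant returns is the
default and the model used throughout: with segmented demand, the relevant
question is proportional over-resourcing, and CRS makes the score invariant
to joint scaling of a unit (a small and a large clinic with the same
input-output mix score identically).

Input orientation rather than output orientation is deliberate: each
institution's population is assigned by law, so a unit cannot expand output at
will; it can only be judged on the inputs it ties up producing its observed
output.

Slacks (residual input excess / output shortfall after the radial
contraction) are recovered in a **second phase** that maximizes total slack at
the fixed optimal $\theta$, so the reported score is purely radial and never
traded against slack. Alternative optimal $\lambda$ can exist; `peers` is
therefore *a* supporting set, not the unique one.

Two degenerate conventions, both needed in practice:

* a unit with **all outputs zero** gets $\theta = 0$ with status
  `degenerate_zero_output` under CRS (the bundled Mexican table contains
  exactly such a cell: PEMEX in Mexico State, printed 0.000);
* zero values inside an input vector are kept as-is — they only tighten the
  corresponding constraint.

## The LP engine and its verification

The envelopment program is solved by a dense two-phase primal simplex written
for this package (`R/simplex.R`): the problems are small (a few hundred
variables, a dozen rows), the degenerate all-zero right-hand sides of the
envelopment form are exactly where general-purpose tableau codes are
fragile, and owning the solver lets the tests pin its behaviour down. Before
every solve, each input and output dimension is rescaled by its maximum
across units — radial efficiency is provably invariant to per-dimension
rescaling, and the obstetric quantities span five orders of magnitude (tens
of delivery rooms against tens of millions of prenatal visits).

Correctness is never taken on faith; three independent routes check it:

1. **Duality**: the multiplier (dual) form
   $\max_{u,v \ge 0} u \cdot y_i$ s.t. $v \cdot x_i = 1$,
   $u \cdot y_j \le v \cdot x_j \;\forall j$ — a differently shaped LP —
   must return the same score (`dea_multiplier()`); the suite checks
   agreement to $10^{-6}$ on 100 random panels and on the national panel.
2. **Closed form**: with one input and one output,
   $\theta_i = (y_i/x_i)/\max_j (y_j/x_j)$ (`ratio_efficiency_1d()`); the
   suite checks 1000 random 1-D panels to $10^{-9}$.
3. **LP-free grid bound**: evaluating the CCR ratio definition on a coarse
   simplex grid of weights (`ratio_grid_bound()`) yields a certified lower
   bound on every score.

The frozen reference values for the six-institution national panel were
additionally computed with an unrelated external LP implementation and are
asserted at $10^{-6}$.

## The three-stage pipeline

**Stage 1** scores each DMU (`dea_frontier()`). The default is one pooled run
on 2012–2018 period-total quantities — one score per DMU for the whole
period, matching the bundled national totals; `dea_per_year()` provides the
alternative reading (average of seven annual runs), since published
descriptions of pooled multi-year DEA are often ambiguous between the two.

**Stage 2** (`summarize_efficiency()`) arranges scores in a state ×
institution `efficiency_matrix()` in which absence (an institution not
operating in a state) is `NA` and *distinct from a present 0*; every mean is
unweighted over present cells only. Three national averages are reported
side by side because they answer different questions and genuinely differ in
a fragmented system: the mean of the six institutional means (0.410 on the
bundled table), the mean of the 32 state means (0.460), and the mean over
all 153 DMUs (0.453). The **efficiency gap** is the spread of institutional
means (0.660). DMUs are classified against two thresholds
(`dea_thresholds()`): saturated above 0.82 (strict) and untapped capacity at
or below 0.22 (inclusive) — the highest and lowest institutional averages
observed in the reference system, kept as package defaults so the bundled
analysis reproduces. On the bundled table, 20.3% of DMUs are saturated and
62/153 = 40.52% are untapped; summaries elsewhere that print 40.6% reflect
a different rounding of the same count, which the report notes rather than
asserts.

**Stage 3** (`correlate_with_context()`) relates state mean efficiency to
state GDP per capita. Spearman's rank correlation is the primary statistic
(monotone association, robust to GDP's skew); Pearson's $r$ is computed
alongside because generic pairwise-correlation commands report it, and
silently substituting one for the other is a classic reproduction trap. A
GDP-quartile profile (rank-based $n/4$ breaks, quartile 1 = poorest states)
shows the efficiency range within each economic stratum.

`annual_variation()` supports the temporal-stability check: per institution
and dimension, year-over-year percent changes (a change on a zero base is
`NA`, never infinity) and the coefficient of variation of the yearly totals.

## The synthetic generator

`generate_panel()` builds fragmented systems with *known* ground truth:

* `n_anchors` anchor technologies drawn with strictly positive quantities,
  each re-solved and verified CRS-efficient within the anchor set
  (dominated draws are regenerated within a bounded retry budget; where the
  geometry cannot support the requested number — e.g. one input, one
  output — the dominant subset is kept, with a warning);
* for each (state, institution) pair, presence is Bernoulli; a present DMU
  is a random convex combination of anchors, scaled along a CRS ray
  (size heterogeneity), with inputs inflated by $1/\theta^*$,
  $\theta^* \sim \mathrm{U}(0.2, 1)$ by default;
* the anchors are appended to the panel, so the generating frontier is
  identified and the estimated $\hat\theta$ must equal $\theta^*$ *exactly*
  (to LP tolerance) — inefficiency is purely radial by construction, which
  is what makes the recovery test sharp rather than statistical.

Defaults mirror the reference system: 32 states; six institutions with
presence probabilities $(1, 1, 1, 14/32, 25/32, 18/32)$, giving 153 expected
DMUs. What the generator deliberately does **not** emulate: measurement
error (available as optional lognormal noise, excluded from exact-recovery
tests), integer-valued staffing counts (an `integerize` switch rounds, with
recovery then only approximate), temporal autocorrelation, and any
output-quality differences — the model assumes output homogeneity
throughout, so passing tests say nothing about quality-adjusted efficiency
on real data.

`generate_context()` produces positive state GDP-per-capita values that are
either independent of efficiency (`link = "none"`, the null used to check
the stage-3 test's calibration: its 5%-level rejection rate across 500
replicates sits near the nominal 5%) or rank-linked with noise (the power
control).

## Numerical and design choices

* Solver tolerance $10^{-9}$; scores within $10^{-9}$ of 1 are snapped to 1;
  peers require $\lambda > 10^{-6}$.
* Scores are reported at 3 decimals (the precision of the bundled table);
  all arithmetic is full precision. `counts_at_unity` counts cells equal to
  1 at reporting precision.
* The bundled tables anonymize institutions as A–F; the adopted legend
  (A=SS, B=IMSS, C=ISSSTE, D=PEMEX, E=SEDENA, F=SEMAR,
  `mexico_institution_legend()`) follows the order in which the published
  national shares match the institutional narrative. It affects labels only.
* Two variable sets are first-class because both circulate for this
  production process: `"full"` (4 inputs × 4 outputs, the operational
  definitions) and `"reduced"` (3 × 2). The national DEA is run under both
  in `analysis/02_national_dea.R`; the frontier membership coincides.
* Cost ("allocative") efficiency is out of scope: input prices are neither
  bundled nor modelled. So are output-oriented models, Malmquist indices,
  bootstrap inference on $\theta$, and regression of efficiency on
  covariates.

## Problem sizes in the shipped analyses

The test suite and the analysis scripts run the engine on panels of up to
~160 units with 8 dimensions (the full synthetic study scale), 100-panel
duality sweeps, 1000-panel 1-D sweeps, and 500-replicate correlation
calibrations — sizes chosen so each validation property is exercised at the
scale of the reference system while a full run stays comfortably
interactive on a single core.

## Known limitations

* DEA scores are relative to the observed sample: adding a unit can only
  lower (never raise) existing scores, and scores from different panels are
  not comparable.
* The CRS assumption attributes all scale effects to inefficiency; the VRS
  option is provided but the bundled reference scores are CRS.
* With 8 dimensions and 6 national units, most units are efficient by
  dimensionality alone — the national worked example illustrates mechanics,
  not discrimination; the state-level grid (153 units) is where the scores
  separate.
* Quality of care is assumed homogeneous across institutions; no
  case-mix or quality adjustment is attempted.
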