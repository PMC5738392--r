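---
title: "Generalized Loewe null models and synergy testing for checkerboard assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized Loewe null models and synergy testing for checkerboard assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genloewe)
```

## The problem

Early drug-combination screens read out a checkerboard: serial dilutions of
two compounds, alone and in all pairwise combinations. To decide whether a
combination is worth pursuing, the observed off-axis readouts are compared
with a *null model* — the effect expected if the two compounds did nothing
special together. Combinations that beat the null are called synergistic,
those that fall short antagonistic. The null model is not meant to be
mechanistically true; it is a calibrated baseline that only needs the
mono-therapy concentration-response curves.

The most widely used baseline is Loewe concentration additivity, which
pictures the assay as a single (virtual) enzyme whose molecules are bound,
mutually exclusively, by either compound. Classical Loewe breaks down when
the two compounds have different maximal effects — a full agonist paired
with a partial agonist, a neutral antagonist (binds but does nothing), or
an inverse agonist (pushes the readout the other way). This package
implements a generalization that keeps the competitive-binding picture
while allowing compound-specific maximal effects, together with two
lack-of-fit tests (MeanR and MaxR) that turn deviations from the null
surface into calibrated synergy/antagonism calls.

## The model

Each mono-therapy curve is a four-parameter log-logistic (Hill) function.
Occupancy — the fraction of enzyme bound by compound $j$ at concentration
$c$ — is

$$o_j(c) = \frac{1}{1 + (i_j/c)^{h_j}},$$

with EC50 $i_j$ and Hill coefficient $h_j$, and the readout is the linear
map

$$R_j(c) = b + (m_j - b)\, o_j(c),$$

where the baseline $b$ (readout of the untreated system) is shared by all
compounds in the assay and $m_j$ is the compound's maximal effect. $m_j$
may be above, below or equal to $b$: the same formalism covers full,
partial, inverse and neutral agonism.

For a mixture with doses $c_j$, total occupancy keeps the classical Loewe
form — it never references the maximal effects:

$$\sum_j \frac{c_j}{i_j}\left(\frac{1-o}{o}\right)^{1/h_j} = 1 .$$

The left side decreases strictly from $+\infty$ to $0$ as $o$ runs over
$(0,1)$, so the root exists and is unique whenever any dose is positive.
The combination readout is then the occupancy-weighted blend of the
compound-specific scaled effects,

$$r = b + o \sum_j (m_j - b)\, f_j , \qquad
  f_j = \frac{c_j}{i_j}\left(\frac{1-o}{o}\right)^{1/h_j},$$

where $f_j$ is the fraction of bound enzyme occupied by compound $j$; the
$f_j$ sum to one. Two structural consequences anchor the test suite:

* **Sham additivity.** A compound combined with itself predicts exactly
  the marginal readout at the total dose — the defining Loewe property.
* **Classical reduction.** When all $m_j$ are equal the prediction
  collapses to $r = b + o\,(m - b)$, the classical Loewe readout.

A neutral antagonist ($m_j = b$) still competes for occupancy but
contributes nothing to the readout sum — that is how it dilutes an
agonist in the prediction (e.g. the worked value $r = 1/3$ for an agonist
and a neutral antagonist both at their EC50 with $b = 0$, $m = (1, 0)$).

```{r}
agonist <- marginal_curve(b = 0, m = 1, ec50 = 1, hill = 1)
blocker <- marginal_curve(b = 0, m = 0, ec50 = 1, hill = 1)
predict_readout(list(agonist, blocker), c(1, 1))[c("occupancy", "readout")]
```

## Fitting the marginals

`fit_marginals()` estimates the seven free parameters
$(b, m_1, m_2, \log i_1, \log i_2, h_1, h_2)$ jointly by non-linear least
squares over all mono-therapy and untreated wells, with one shared
baseline. Choices that matter:

* **Log-scale EC50s.** Keeps the estimate positive and makes the standard
  error of $\log i_j$ — the quantity the quality filter screens — a direct
  entry of the Gauss-Newton parameter covariance at the optimum.
* **Initialization and restarts.** The start is heuristic (baseline from
  the zero-dose wells, maximal effect from the top dose, EC50 at the
  half-effect dose, Hill 1), followed by a short deterministic ladder of
  perturbed restarts. Levenberg-Marquardt with an analytic Jacobian does
  the minimization.
* **Bounds.** Hill coefficients are constrained to $[0.1, 10]$ and
  $\log$ EC50 to a generous window around the observed dose range; both
  prevent degenerate excursions on flat or unlucky data. Runs that stop
  on the iteration cap are kept as candidates — they are almost always
  the unidentified-asymptote ridge (huge $m$, EC50 far beyond the dose
  range), which is a genuine least-squares solution that the quality
  filter, not the optimizer, should judge.
* **Quality filter.** A pair is analyzed only if the standard deviation
  of each $\log(\mathrm{EC50})$ estimate is at most 10 (natural log,
  inclusive comparison, configurable). Fits failing the filter return an
  `"invalidated"` analysis rather than a synergy call.
* **Growth transform.** For growth-type readouts with multiplicative
  noise, `growth_transform()` (a natural log) can be applied before
  fitting via `log_transform = TRUE`. It is off by default so the core
  method stays agnostic to the readout scale; the exact
  instantaneous-growth preprocessing used for kinetic growth curves is
  assay-specific and left to the caller.

## The MeanR and MaxR tests

Let $d$ be the vector of mean observed minus predicted readouts over the
$k$ off-axis dose combinations. Its null covariance has two parts:
measurement noise $\hat\sigma^2\,\mathrm{diag}(1/n_i)$ (from the marginal
fit's residual variance, assumed homoscedastic) and the covariance $C_p$
of the predictions themselves, induced by marginal-parameter uncertainty.
$C_p$ is estimated by a parametric residual bootstrap (default 100
refits): resample mono readouts from the fitted curves plus
$N(0, \hat\sigma^2)$ noise, refit, re-predict.

* **MeanR** is the omnibus quadratic form
  $M = d^\top V^{-1} d / k$ with $V = \hat\sigma^2\mathrm{diag}(1/n_i) + C_p$.
* **MaxR** is $T = \max_i |t_i|$ with $t_i = d_i / \sqrt{V_{ii}}$. Each
  point is called non-additive when $|t_i|$ exceeds the $(1-\alpha)$
  quantile of the null distribution of the maximum — a built-in
  familywise multiplicity control across the grid. Call direction follows
  the configured effect convention (`decreasing_effect = TRUE` by
  default: lower readout means stronger effect, so an observed readout
  below the prediction is synergy).

Two null distributions are available; `null_method = "auto"` picks the
parametric one when off-axis replicates exist and the bootstrap otherwise:

* **Parametric.** $M$ is referred to $F(k, \mathrm{df})$, df being the
  residual degrees of freedom of the marginal fit. The MaxR null samples
  multivariate normal vectors with the correlation structure of $V$,
  each draw scaled by $\sqrt{\mathrm{df}/\chi^2_{\mathrm{df}}}$ because
  $V$ scales with the (few-df) residual variance estimate.
* **Bootstrap** (default 1000 runs). Each run replays the whole pipeline
  under the fitted null: mono readouts resampled from the fitted curves,
  marginals refitted, the surface re-predicted, off-axis errors drawn
  from $N(0, \hat\sigma^2)$, and both statistics recomputed with $V$
  rescaled by the resampled residual variance. The draws therefore carry
  every estimation-noise source the observed statistics do, which is
  what makes the test hold its level on single-replicate boards.
  P-values use the $(r+1)/(B+1)$ estimator, so they are never zero and
  are bit-reproducible under a seed.

The overall call is driven by MeanR; MaxR localizes the responsible dose
combinations.

## The simulator and what the validation shows

`simulation_spec()`/`generate_board()` generate checkerboards from known
ground truth: mono wells on the true curves, off-axis wells on the true
generalized-Loewe surface plus an optional injected deviation (a scalar
on every off-axis point or a targeted per-point shift), homoscedastic
Gaussian noise everywhere. Defaults describe a realistic desk-scale
growth-inhibition experiment: an 8 × 8 board (seven 2-fold dilutions per
compound centered on the EC50, plus dose zero), a full agonist
($b = 0.1$, $m_1 = 1$, $i_1 = 1$, $h_1 = 1$) paired with a partial
agonist ($m_2 = 0.6$, $i_2 = 10$, $h_2 = 2$), one replicate, and noise
sd 0.045 — 5% of the full agonist's dynamic range.

The validation suite runs, among others: a 500-board type-I study at
$\alpha = 0.05$ with the bootstrap null (200 null runs, 50 Cp runs per
board — reduced from the defaults so a full study stays in the minutes
range on one core), a two-level power ladder (uniform off-axis shifts of
−0.08 and −0.24, 100 boards each), and a localization study (100
replicated boards with a single −6σ off-axis spike, requiring MaxR to
flag exactly that point with the right direction). The simulator shares
its noise model with the tests' assumptions (Gaussian, homoscedastic, no
plate effects or outliers), so passing these studies validates the
statistical machinery, not robustness to real-plate artifacts.

## Numerical choices

* Occupancy roots come from vectorized bisection on
  $o \in [10^{-12}, 1-10^{-12}]$ (90 halvings, i.e. far below the
  $10^{-12}$ tolerance); monotonicity guarantees the bracket. Roots
  beyond the bracket ends (doses absurdly far from every EC50) clamp to
  the nearest end.
* All expressions avoid the catastrophic cancellation of $1/o - 1$ near
  full occupancy by using $(1-o)/o$, and the readout inversion uses
  $(m-r)/(r-b)$ rather than $(m-b)/(r-b) - 1$; the blending weights are
  renormalized to sum to one exactly.
* $V$ receives an escalating diagonal ridge only if its Cholesky
  factorization fails (a rank-deficient bootstrap $C_p$ at small run
  counts can leave it semi-definite).
* A board fitted essentially exactly — residual sd and every off-axis
  deviation below $10^{-8}$ of the readout scale — carries no evidence
  against additivity: both tests then report a zero statistic with
  $p = 1$ instead of comparing rounding noise against rounding noise.
* Degenerate flat curves ($m_j \approx b$) fit cleanly but are not
  invertible and, in the presence of noise, fail the quality filter
  through their exploded $\log(\mathrm{EC50})$ uncertainty.

## Known limitations

* The parametric null is mildly anti-conservative at desk-scale designs
  (measured around 6–8% empirical size at nominal 5% in our 400-board
  checks): the $F$/max-normal references treat the prediction error as
  exactly normal, which the non-linear refit error is not. The bootstrap
  null, which replays the pipeline, holds its level and is the default
  whenever no replicates force a choice.
* With a single replicate and 15 mono wells, a *uniform* off-axis shift
  is partly confounded with marginal-estimation uncertainty (it
  resembles a global prediction error), so MeanR's power against small
  uniform shifts is modest; replication sharpens it considerably.
  Localized deviations are MaxR's territory.
* Finite-sample NLS bias on Hill coefficients is real at 5% noise with
  seven doses (order noise²); the unbiasedness check in the test suite
  therefore runs in the low-noise regime where that bias sits below
  Monte-Carlo resolution, and the residual-variance calibration check
  runs at the full default noise.
* Variance homogeneity across wells is assumed throughout; there is no
  unequal-variance extension, no plate-effect or outlier modeling, and
  no cross-board multiplicity control (calls are per board).
* The readout prediction is an occupancy-weighted blend of the $m_j$ and
  is not clamped to any physically bounded range.
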