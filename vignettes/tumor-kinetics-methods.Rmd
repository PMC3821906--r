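---
title: "Modelling tumor volume response to fractionated radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumor volume response to fractionated radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtkinetics)
```

## The model

`rtkinetics` describes a tumor as a population of cells in seven
compartments: sensitive cycling (`Np`) and quiescent (`Nq`) cells, their
radioresistant counterparts (`Nrp`, `Nrq`), and three dying stages
(`Nd1`–`Nd3`). Measured volume is proportional to the total over all seven
(`1e9` cells per cc by default; every result except `V0` is invariant to
this constant).

Untreated growth is governed by four observable parameters: the doubling
time `Td`, the growth fraction `GF` (fraction of cells in cycle), the mean
cell-cycle duration `Tc`, and the rate `gamma` at which quiescent cells
re-enter the cycle (at most 0.01/day — anything faster would not be
quiescence). From these, `derive_rates()` computes the cycle-completion
rate `u`, the quiescent loss rate `mu_q`, the potential doubling time
`Tpot`, and `theta`, the fraction of newborn cells that stay in cycle.
`theta` is chosen as exactly the value for which the discrete update
admits balanced exponential growth: the population then doubles every `Td`
days *to machine precision* and `Np/(Np+Nq)` stays equal to `GF`. This is
possible at any step size because flows are scaled by an effective step
length `dt_prime = (exp(log(2) dt/Td) - 1)/(log(2)/Td)` rather than `dt`
itself. The default step is 1 day.

Killed cells are not removed instantly. A fraction delivered at time
`t_tr` moves `Kp`% of cycling and `Kq`% of quiescent sensitive cells
(or a single `K`% of both, in the minimal model) into a three-stage dying
pipeline; each stage is cleared with per-day probability `D`, so the time
from kill to disappearance is a sum of three geometric waits with mean
`3/D` days (4 days at `D = 0.75`, 15 at `D = 0.2`). Dying cells still
contribute volume until they exit stage III. This delayed-loss structure
is what lets the model reproduce tumors that keep shrinking weeks after
the last fraction.

Two optional mechanisms extend the model:

* **Recruitment** (`StRec`): inside a window after treatment start the
  re-entry rate is replaced by `gamma_rec > 0.01`/day, modelling
  accelerated repopulation from the quiescent pool (reoxygenation,
  nutrient availability). Recruitment needs a quiescent pool to act on, so
  its variants always carry the `GF`/`Tc` growth structure, whichever kill
  structure they use.
* **Resistance** (`ResIni`/`ResInd`): either a fraction `Rini` of cells is
  resistant from the start, or a fraction `Rind` of the sensitive
  survivors converts at each fraction. Resistant cells grow like sensitive
  cells and are never killed; under sustained treatment they become the
  dominant population, producing the characteristic plateau in otherwise
  well-responding tumors.

## Fitting

Fitting maximizes the Gaussian likelihood of *log* volumes, with the
residual scale profiled out analytically (`sigma_hat` is the RMS log
residual). Measurement error in CT volumetry is multiplicative, typically
5–10%, which the log scale renders homoscedastic. Observations below the
CT detection limit are recorded *at* the limit and fitted as exact values
there — a conservative convention that can only understate a treatment
effect; a censored-likelihood alternative (`censored_likelihood = TRUE`)
integrates the Gaussian tail instead and is off by default. One caveat of
the exact-at-limit convention: several consecutive follow-ups pinned at
the limit present the fitter with an artificial plateau, which the
selection ladder can attribute to a plateau mechanism (resistance or
recruitment) the data do not actually contain; when late follow-ups are
censored, the integrated-likelihood option is the safer choice for model
*selection*, whatever convention is used for reporting.

The optimizer is L-BFGS-B on a transformed scale (`V0`, `Td`, `Tc` in
logs) within literature-informed bounds (`Td` 10–1000 days, `GF` up to
0.95, `Tc` 0.5–15 days, kill percentages 0–100, `D` 0.01–1). The
likelihood surface separates into qualitatively distinct basins (low/high
kill, slow/fast dying), so the multistart combines one data-informed
start, a small grid over those regimes, and Latin-hypercube draws, then
screens starts by a single objective evaluation, optimizes the most
promising third, and polishes the winner. A fit is reported as converged
when a restarted optimization cannot improve it. Everything is
deterministic given the configuration seed. `gamma` is fixed at 0 by
default: preliminary fits with it free do not improve the likelihood, and
the data cannot identify it (it can be freed per fit).

Two numerical guards matter in edge regions. Parameter combinations
implying `Tpot > Td` (negative cell loss) or `theta` outside `[0, 1]` are
kinetically inconsistent and are rejected — in the objective they incur a
smooth penalty so searches are pushed back into the consistent region.
And when the per-step quiescent outflow `(gamma_rec + mu_q) * dt_prime`
would exceed the pool (possible at fitted recruitment rates near 1/day),
both flows are rescaled so the compartment empties exactly rather than
going negative; this affects only extreme transients, never balanced
growth, where exactness is a tested invariant.

Confidence intervals are profile-likelihood based: a parameter is moved
away from its estimate, all others re-optimized, until the profile log
likelihood drops by `qchisq(0.95, 1)/2 ≈ 1.9207`; the crossing is located
by root finding, and endpoints that run into the box bounds are truncated
there and flagged. An effectively unidentifiable parameter shows up as an
interval spanning its whole box — the pipeline reports the dying rate as
"not detectable" in that case (with negligible kill the data say nothing
about how fast killed cells disappear), routing classification to the
slow branch.

## Model selection

Following the principle of parsimony, `select_model()` fits the minimal
model first and adopts the standard model only if the likelihood-ratio
test (degrees of freedom = difference in free-parameter counts; the
profiled `sigma` is never counted) is significant at `alpha = 0.05`. It
then adds recruitment and resistance variants to the adopted base and
keeps the best significant extension; extensions that are significant but
not significantly better than the winner are reported as alternates, as
are tied resistance mechanisms — initial and induced resistance fit
equally well in practice and the data cannot distinguish them.

The recruitment window is a model configuration, not an estimated
parameter: a small grid (early burst days 1–3, longer window 1–13,
delayed recruitment from the 3rd or 4th week) is scanned and the
best-likelihood window kept. Because this selects the best of several
fits, the recruitment test is Bonferroni-corrected over the grid size —
without the correction the ladder adopts spurious recruitment at roughly
double the nominal rate.

When no pretreatment scan exists, `Td` is not estimable; the whole ladder
is run at the two fallback doubling times (25 and 150 days) and both
outcomes are reported. Kill and dying-rate estimates are robust to this
choice; post-treatment regrowth predictions are not.

## Response classification

Fitted responses are typed on a 2×2 grid: kill is "high" when `K` (or
`Kp`) reaches 5% per fraction under conventional fractionation (group L)
or 35% under hypofractionation (group S), and dying is "fast" when
`D >= 0.5` (thresholds inclusive; a not-detectable `D` counts as slow).
Type A (high/slow) shrinks slowly but durably; B (high/fast) shrinks
rapidly; C (low/slow) and D (low/fast) are poor responders. Applied to
the bundled reference-cohort best fits, the classifier reproduces the
recorded response-type column exactly (counts 2/2/1/0 for A–D in group
L; 4/3/2/3 in group S).

## The synthetic-data generator

`scenario_spec()`/`generate_timecourse()` emulate the study conditions
the analysis assumes: exponential pretreatment growth; a conventional
course (weekday fractions of 1.8–2.5 Gy over 6–10 weeks, day 0 a Monday)
or a hypofractionated course (5 × 10 Gy inside two weeks); a planning
scan 14 days before treatment; a CT immediately before every fraction;
follow-ups about one week, two weeks, one month, and two months after the
last fraction; multiplicative lognormal noise with CV 0.07 (middle of the
5–10% range, median-1 so log volumes are Gaussian around the model); and
a 0.1 cc detection limit (not reported in the source data; configurable).
The early follow-up is part of the default calendar because without it a
9–12-day hypofractionated course yields only 8 observations and the
8-parameter recruitment model would be formally underdetermined —
real series of this kind include several post-treatment scans.

`archetype_suite()` packages seven scenarios — one per response type per
group in which it occurs — parameterized from representative rows of the
bundled cohort. What the generator deliberately does *not* emulate:
contouring artifacts (atelectasis, fibrosis, inflammation) that decouple
CT volume from cell number, scan-to-scan correlation of contouring error,
and irregular real-world calendars. Passing tests therefore demonstrate
the estimator's behavior under the model's own assumptions, not
robustness to imaging pathology.

## What the simulations show (and their limits)

The test suite and `scripts/acceptance.R` measure, at deliberately modest
problem sizes chosen to keep a full run in minutes on one core:

* exponential exactness of the discretization (relative error below
  1e-9) and growth-fraction stationarity;
* equivalence of the uniform-kill model and the compartment-kill model at
  `Kp = Kq`;
* noiseless recovery of all four minimal-model parameters within 1% from
  a conventional-course series;
* 95% profile-interval coverage for `K` and `D` close to nominal over 200
  replicates at 5% noise;
* likelihood-ratio test size close to the nominal 5% over 200 replicates.

Identifiability degrades sharply for the 7–8-parameter standard and
recruitment models on short hypofractionated series (~9 observations): at
7% noise the end-to-end archetype battery recovers the intended response
type in roughly 80% of replicates, with misses concentrated where the
kill estimate sits near the 35% threshold. This mirrors the wide
confidence ranges reported for such fits and is a property of the data
design, not of the optimizer — with noise off, the battery recovers all
seven types. Mixed-effects pooling across patients, not attempted here,
is the natural remedy when cohorts are larger.
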