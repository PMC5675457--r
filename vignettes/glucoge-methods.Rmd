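---
title: "Methods: hybrid glucose forecasting by grammatical evolution"
author: "glucoge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid glucose forecasting by grammatical evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucoge)
```

## Overview

`glucoge` builds personalized mid-term (120-minute) forecasters of
continuous glucose monitoring (CGM) readings for people with type 1
diabetes.  The approach is hybrid: discrete carbohydrate and insulin
events are first transformed into continuous physiological signals — the
meal glucose rate of appearance (Ra) and the insulin on board (IOB) —
and a grammatical-evolution (GE) engine then searches a grammar-defined
space of symbolic expressions that map lagged values of (CGM, Ra, IOB),
plus an optional circadian sinusoid, to the CGM value two hours ahead.
One expression is evolved per day segment (nocturnal, breakfast, lunch,
dinner), giving a piecewise personalized model.

## Physiological preprocessing

**Meal absorption.** A meal of `CHO` grams eaten at time 0 contributes a
rate of appearance

$$Ra(t) = CHO \cdot CHO_{BIO}\,\frac{t\,e^{-t/t_{max,G}}}{t_{max,G}^2},$$

with population values $t_{max,G} = 50$ min and $CHO_{BIO} = 0.8$.  The
curve peaks exactly at $t_{max,G}$ and integrates to $CHO_{BIO}$ times
the ingested mass.  Meals superpose linearly.  Carbohydrate is kept in
grams throughout, so Ra is g/min-scaled; the grammar's evolved constants
absorb any fixed unit factor, and a grams-to-milligrams factor (1000) is
available where absolute units matter.  The kernel is truncated at
$t > 12\,t_{max,G}$, where it carries less than $10^{-4}$ of the mass.

**Insulin on board.** Delivered insulin decays through two serial
compartments,

$$\dot C_1 = u(t) - K C_1,\qquad \dot C_2 = K(C_1 - C_2),\qquad
IOB = C_1 + C_2,$$

integrated by explicit forward Euler on the 1-minute delivery grid with
$K = 0.039\ \mathrm{min}^{-1}$ (a 2-h nominal duration of insulin
action; the DIA-to-K mapping is kept as a lookup with this single
published pair).  Boluses are impulses — the full dose enters $C_1$ at
the recorded minute, matching pump bolus records — while basal enters as
a rate.  The scheme is stable ($K\,\Delta t = 0.039 < 1$) and its
impulse response converges at first order to the closed form
$e^{-Kt}(1+Kt)$; the tests verify that halving the step halves the peak
deviation.

**Bolus calculator.** Mealtime doses follow the standard calculator
$I_{bolus} = CHO_{IN}/CR + (G_B - G_T)/CF$ with the carbohydrate ratio
`CR` (g/U), correction factor `CF` (mg/dl per U), glucose target $G_T$
and preprandial fingerstick $G_B$.  The correction sign follows clinical
convention (glucose above target adds insulin); the opposite printed
convention is available behind `correction_sign`.  Negative computed
doses clamp to zero.

## The grammar and expression semantics

The predictor grammar (shipped as `inst/extdata/glucose.bnf`) derives
sentences of the form

```
ExprG=([G] op [Ra] op [IOB]) op [Circadian]
```

where each signal block is a sum of zero or more terms
`GetX(l0, l1, op, preop, (a), (d))`.  A term reads its source signal at
lag `l0` (in 5-min CGM samples, drawn from the grid {0,1,2,4,…,22}),
divides by the constant `a`, applies a chain of unary pre-operators
(`sqrt`, `sin`, `log`, `pow`, `exp`, `cos`), and combines with the
constant `d` under `op`.  Constants are fixed-point values in
[00.0, 99.9] derived digit by digit.  The circadian component is
$A\cos(\omega n + \varphi)$ with $\omega$ parameterized in cycles/day
(the raw constant scaled by $2\pi/288$, there being 288 five-minute
samples per day) and the amplitude clipped at 30 mg/dl — 20% of a
nominal 150 mg/dl mean CGM level — so day-to-day modulation stays
within a 20% band.

Design choices worth making explicit:

* The published grammar excerpt gives `GetX` four arguments with no
  constants, while the accompanying continuous-time semantics and the
  worked example require a per-term scale and offset.  The shipped
  grammar therefore carries two constant arguments per term, making the
  stated semantics realizable.  Each `GetX` call contributes exactly one
  term at lag `l0`; the second lag argument `l1` delimits the admissible
  window and must satisfy `l0 < l1`, a violating term invalidating the
  expression.
* `pow` is unary in the grammar and is interpreted as squaring.
* Empty blocks (λ-productions) evaluate to the neutral element of the
  operator joining them (0 for `+`/`-`, 1 for `*`/`/`), so sentences
  remain well-formed when a block is absent.
* The circadian rule's leading `/ *` operator choice scales the
  amplitude (`A * cos` or protected `A / cos`); the three constants are
  assigned in the order amplitude, frequency, phase — a documented
  convention, since the source does not fix one.
* All arithmetic is protected so any sentence evaluates finitely on
  finite inputs: `log(x) = log|x|` with `log(0) = 0`, `sqrt(x) =
  sqrt|x|`, division by zero yields 1, `exp` arguments clip to ±50 and
  squaring clips to ±10^10.

**Mapping.** Genotypes are variable-length strings of 8-bit codons.
Standard GE mapping expands the leftmost non-terminal, choosing
production `codon mod n` at every choice point; single-production rules
consume no codon.  The codon string may be reused ("wrapped") at most
twice — two *additional* passes, our reading of the wrap budget — after
which an unfinished derivation is marked invalid.  Invalidity is a
value: such individuals stay in the population with worst-marker
fitness, preserving the population size without a repair loop.

## Fitness: the glucose-specific penalized error

The fitness of an expression on a training segment is the mean of
pointwise penalized squared errors,

$$gMSE = \frac1N \sum_t Pen(g_t, \hat g_t)\,(g_t - \hat g_t)^2 ,$$

where the penalty inflates clinically dangerous errors: overestimation
when the reference is hypoglycemic (a missed low) and underestimation
when it is hyperglycemic (a missed high).  The printed form of the
penalty in our source material is typographically corrupted, so the
function is reconstructed from its cited definition as a product of
smooth logistic transitions:

$$Pen = 1 + \alpha_L\,\bar S(g; T_L, \beta_L)\,S(e; \gamma_L)
          + \alpha_H\,S(g; T_H, \beta_H)\,\bar S(e; -\gamma_H),$$

with $e = \hat g - g$, constants $\alpha_L = 1.5$, $\alpha_H = 1$,
$\beta_L = 30$, $\beta_H = 100$, $\gamma_L = 10$, $\gamma_H = 20$,
$T_L = 85$, $T_H = 155$ mg/dl, and $S(x; c, w) = \text{logit}^{-1}(4(x -
c)/w)$.  The error-axis transitions are centered at $+\gamma_L$ and
$-\gamma_H$, so perfect predictions carry essentially no penalty.  The
reconstruction is isolated in a single function (`pen()`); its asserted
surface is the bound $Pen \in [1, 3.5]$, continuity, directional
monotonicity, and the danger ordering $Pen(50, 75) > Pen(175, 150)$.
Because both transition pairs decay exponentially, the hypoglycemic
branch is strictly monotone only until the transitions saturate
(overestimates beyond roughly +55 mg/dl); the tests assert strictness on
the clinically relevant band.

Reported metrics are RMSE, MAD (mg/dl) and MARD (%), each with a
glucose-weighted counterpart in which the pointwise error is multiplied
by `Pen` before averaging.  MAD is reported in mg/dl, matching the
tabulated results rather than the inconsistent unit header of the
formula listing.  Clarke error-grid classification uses the canonical
published boundary inequalities with ties resolved toward the more
benign zone; an exhaustive lattice test checks the five zones partition
the domain.

## The evolutionary loop

Defaults follow the study configuration: population 50, 2000
generations, tournament size 2, single-point variable-length crossover
with probability 0.90 (independent cut points per parent; cut pairs that
would orphan a child are redrawn, preserving total codon count),
integer-flip mutation at 0.005 per codon, elitism 2, maximum 2 wraps.
Initial genotype lengths are uniform on [15, 100] codons (the source
does not state bounds; these are exposed in `ge_control()`).  Fitness
values are cached by genotype, and only timestamps whose *target* falls
in the training segment enter the loss — mathematically equivalent to
holding the output constant off-segment, and cheaper.

One deliberate deviation from purely random initialization: the initial
population contains the hand-coded genotype of the persistence predictor
(current CGM carried forward).  This guarantees the invariant that the
returned model never underperforms the trivial clinical baseline — a
property random initialization cannot promise — at the cost of one of
50 random individuals.  It can be disabled (`seed_baseline = FALSE`).

## The synthetic cohort

No deposited data exist for this problem: the original experiments used
a proprietary simulator.  The package therefore ships a self-contained
virtual-patient generator whose *statistical structure* matches the
stated study conditions: 14 days; three daily meals near 07:00, 13:00
and 19:00 with Gaussian sizes of mean 50, 60 and 63.5 g and 20% CV
(floored at 10 g, times jittered ±30 min); carbohydrate counting error
of 20% CV applied to the announced meal size; boluses from the standard
calculator using a noisy preprandial fingerstick; 20-g rescue
carbohydrates at most every 20 min when a fingerstick reads below
60 mg/dl; a sinusoidal circadian insulin-sensitivity modulation of 20%
amplitude tracked by a time-varying basal profile; CGM sampled every
5 min through a 10-min first-order sensor lag with additive AR(1) noise
(2 mg/dl marginal SD, lag-1 correlation 0.7 on the 5-min grid), and 5%
CV fingerstick noise.  Fingerstick hypoglycemia checks run every 20 min
whenever true glucose is below 80 mg/dl — a monitoring-behavior
assumption the study description leaves implicit.  Meal clock times are
inferred from the published day segmentation.

The glucose dynamics behind the generator are a declared surrogate — a
minimal model chosen so every downstream stage is testable, with *no*
fidelity claim against the regulatory-grade simulator:

$$\dot G = EGP(X_a) - S_g G - S_I\,c(t)\,X_a G + k_{carb} Ra(t),
\qquad \dot X_1 = p_2(u - X_1),\qquad \dot X_a = p_2(X_1 - X_a),$$

with glucose effectiveness $S_g = 0.002\,\mathrm{min}^{-1}$, insulin
sensitivity scale $S_I = 0.4$ (per U/min of action), a two-compartment
insulin-action chain ($p_2 = 0.012\,\mathrm{min}^{-1}$, activity peaking
about 80 min after a bolus — deliberately slower than carbohydrate
absorption, as in vivo), carbohydrate gain $k_{carb} = 1000/V$ with
distribution volume $V = 1.6$ dl/kg, circadian multiplier $c(t)$ of 20%
amplitude, and endogenous production $EGP = 1.2$ mg/dl/min suppressed
linearly by above-basal insulin action (strength 0.4, exactly neutral at
basal action so the steady state is preserved).  Insulin-induced
hypoglycemia in this model arises, as physiologically, from EGP
suppression rather than from glucose-proportional clearance alone.
Glucose is clamped to [20, 600] mg/dl and basal rates solve the
fixed-point equation for the patient's target (`basal_for_target()`).

Cohorts draw per-patient body mass (normal, 70 ± 10 kg, floored at
45), insulin sensitivity and endogenous production (log-normal, 20% and
10% log-SD), a glucose target (normal 120 ± 15, clipped to [95, 150]
mg/dl), circadian phase (uniform), and two therapy imperfections: a
log-normal carbohydrate-ratio error (15% log-SD) and a log-normal basal
titration error (10% log-SD).  The derived therapy parameters
(`CR`, `CF`) are computed from each patient's own physiology and then
perturbed — mirroring how real therapy is titrated to the patient but
never perfectly.  These spreads were chosen so that the generated data
reproduce two qualitative features of the study data: between-patient
spread of mean glucose exceeding within-patient day-to-day spread, and a
realistic incidence of rescue-triggering hypoglycemia (roughly one
rescue every one to two patient-days; most patients experience at least
one low per fortnight).  Child seeds derive deterministically from the
master seed, so cohorts are exactly reproducible.

What the generator does *not* emulate: meal-composition effects on
absorption shape, exercise, illness, sensor dropouts and pressure
artifacts, calibration drift, and the full nonlinear physiology of the
regulatory-grade simulator.  Passing tests on this cohort demonstrate
that the pipeline is correct and that the method behaves sensibly on
data with the right structure — not that the published accuracy figures
transfer to real patients.

## Piecewise training and evaluation protocol

Days split into train (1–10) and test (11–14).  The day tiles into four
6-h segments — Nocturnal 01:00–06:59, Breakfast 07:00–12:59, Lunch
13:00–18:59, Dinner 19:00–00:59 (wrapping midnight) — half-open on the
minute grid, so 07:00 belongs to Breakfast.  A (history, target) pair
belongs to the segment owning the *target* clock time; history may cross
the boundary.  The first 120 min of a record yield no pairs
(insufficient lag history), which slightly reduces day-1 pair counts.
An alternative window set (09:00–13:00, 15:00–19:00, 19:00–01:00) fits
late-postprandial models that skip the two unpredictable hours after
each meal; the third window is implemented at its printed six-hour
extent even though the companion text implies four hours — the
inconsistency is inherited from the source and noted here.

Per-patient reports follow the standard 12-column layout (six metrics,
A+B headline plus the five zones) for train and test, with a "24 hour"
row equal to the arithmetic mean of the equal-volume segment rows;
cohort tables average patient rows.  Fitted model sets serialize to
JSON via the canonical phenotype text form and reload bit-exactly.

## Problem sizes used by the test suite

The full study protocol (100 patients × 4 segments × 2000 generations)
is available through the defaults and the CLI preset, but the package's
own test suite uses reduced, seeded configurations chosen to exercise
every code path at desk scale: recovery of a planted grammar-derivable
expression with population 30 and 100 generations over ten seeds, and an
end-to-end gate of three simulated patients with population 30 and 200
generations whose test-day Clarke A+B percentage must reach at least
90%.  That gate is an artifact-level sanity bound, deliberately weaker
than the headline accuracy reported for the proprietary-simulator
cohort, which is not reproducible here.

## Known limitations

* The penalty function is a reconstruction; alternative readings of the
  corrupted printed form would change fitness values (though not the
  qualitative ordering properties, which are pinned by tests).
* The lag grid caps history at 22 samples (110 min) for term lags while
  the published worked example references a 24-sample lag; the grammar
  follows the printed lag grid, and the discrepancy is inherent to the
  source.
* The surrogate cohort supports method development and testing only;
  conclusions about clinical accuracy require the original simulator or
  real data.
* Evolution is single-threaded and deterministic per seed; results are
  independent of evaluation order by construction (generational model
  with cached fitness).
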