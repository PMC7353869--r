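---
title: "Methods: emulating a real-time ventilation feedback device"
author: "ventfeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a real-time ventilation feedback device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventfeedback)
```

## The problem

Manual bag-valve ventilation is hard to do well: even trained providers
drift out of the recommended tidal volume (TV) and ventilation interval
(VI). A real-time feedback device placed between the bag and the airway
measures each delivered volume with a mass-flow sensor and prompts the next
squeeze with a countdown and alarm. This package reproduces, in software,
three layers of work around such a device:

1. the **device signal chain** — sampling, quantisation, flow transfer,
   tidal-volume accumulation, breath detection, interval timers, alarms;
2. the **bench validation** of the device against known ventilator
   deliveries, summarised by difference ratios and tolerance bands;
3. the **crossover-trial analysis** of adequacy outcomes with marginal
   logistic (GEE) models for participant-clustered binary data.

Everything is driven by synthetic waveforms, so no hardware or external
data is required.

## Waveform synthesis

Two generators produce ground-truth flow on a fine time grid (default
1 ms — much finer than the device's 25 ms sampling, so device sampling is a
genuine down-sampling of the analogue signal rather than a reinterpretation
of it).

**Ventilator traces** (`gen_ventilator_trace()`) model a volume-controlled
mode: with respiration rate $r$ breaths/min and inspiration:expiration
ratio $i{:}e$, the cycle lasts $60/r$ s and inspiration lasts
$T_I = (60/r)\,i/(i+e)$ s, during which flow is the constant
$\mathrm{TV}/T_I$; expiratory flow is zero. The bench settings are rate
10/min and I:E = 1:5, so a breath is a 1-s rectangular pulse every 6 s.

**Bag-squeeze traces** (`gen_bagvalve_trace()`) model operator
variability: squeeze volumes are drawn from a normal distribution
truncated to $(0, V_{\max}]$ — $V_{\max} = 1300$ mL for an adult bag,
300 mL for a paediatric bag — and onset-to-onset intervals from a normal
truncated below at the squeeze duration (an operator cannot start a squeeze
before finishing the previous one). Each squeeze delivers its volume over
1 s by default, shaped either as a half-sine (default; its smooth onset
exercises the device's threshold-crossing logic) or a rectangle (handy for
closed-form checks). Published squeeze-shape data are not available, so
neither profile claims physiological fidelity; both integrate exactly to
the drawn volume.

The flow sensor maps flow linearly to voltage,
$$V_\text{out} = 1\,\mathrm{V} + 4\,\mathrm{V}\cdot
  \frac{\text{flow}}{\text{full-scale flow}},$$
so 1 V means zero flow and 5 V full scale. The sensor's full-scale flow is
a required configuration value; the default is 100 000 mL/min
(≈1667 mL/s), chosen so the peak of a large 1-s squeeze stays inside
range. The pressure channel maps 0–10 kPa to 0.5–4.5 V; it carries a crude
flow-proportional surrogate pressure and exists to exercise the display
fields, not to model lung mechanics.

## The device signal chain

`sample_and_quantize()` reads the three analogue channels at 40 Hz and
converts each voltage to a 10-bit code by
$\lfloor V/V_\text{ref}\cdot(2^{10}-1)\rfloor$, clamped to the code range,
then back to a voltage as $\text{code}/(2^{10}-1)\cdot V_\text{ref}$. This
floor-plus-edge-reconstruction convention keeps 0 V and $V_\text{ref}$
exact and bounds the error by one least-significant bit (≈4.9 mV at
10 bits / 5 V), which translates to ≈2 mL/s of flow with the default full
scale. Out-of-range voltages clamp and are counted in the `n_saturated`
attribute. The firmware inverts the sensor transfer with readings below
the 1 V intercept treated as zero flow; the emulator integrates
reconstructed voltages (whether the physical device integrates raw codes
instead is unknowable from the outside, and the two differ by less than a
quantisation step).

`detect_breaths()` is the controller's state machine. A breath opens when
flow stays at or above the onset threshold (default 2000 mL/min
≈ 33 mL/s, held for 2 consecutive samples) — the threshold value is an
implementation choice, picked far below any plausible squeeze peak and
above quantisation noise. From onset, the device accumulates flow over a
**fixed window of 70 samples (1.75 s)**:
$\mathrm{TV} = \sum_{k} \text{flow}_k \cdot 25\,\mathrm{ms}$. The window
is fixed-length rather than threshold-bounded; inspiration time (onset
until flow first drops below threshold, capped at the window) is reported
separately. No new onset can open inside an active window, so two squeezes
less than 1.75 s apart merge into one detected breath — a documented
device behaviour, not an error. Onset-to-onset differences give the
ventilation interval; the last breath has none.

`run_display()` replays the display at the sampling rate — last TV,
seconds since last breath, countdown
$\max(0, T_\text{target} - \text{elapsed})$, peak pressure, battery
percent (linear 3.0 V → 0 %, 4.2 V → 100 %) — and fires one `bagging_due`
alarm per inter-breath gap at the moment elapsed time reaches the target
interval (default 6 s, the lower edge of the optimal 6–8 s range; the
session start opens the first gap).

**Error budget.** For a noise-free rectangular pulse of peak flow $f$, the
detected TV differs from the true volume by at most one quantisation step
of flow times the window length, plus one sampling period times $f$ (edge
alignment). With default settings this bound is under 2 % at every bench
level (150–550 mL), and the test suite asserts it rather than assumes it.

## Bench validation

`run_validation()` replays the bench protocol: each of the five set
volumes {150, 250, 350, 450, 550} mL is delivered 25 times (125
measurements), each rep is pushed through the emulator, and the device
reading is compared with the reference — the exact integral of the
noise-free flow — via the difference ratio
$$\frac{\mathrm{TV}_\text{device} - \mathrm{TV}_\text{reference}}
       {\mathrm{TV}_\text{reference}}.$$
The report carries per-level means/SDs, a per-level mean-comparison
p-value, and the proportions of ratios within ±5 % and ±10 % (inclusive;
the ±5 % count can never exceed the ±10 % count).

Bench hardware noise is surrogated by Gaussian voltage noise on the flow
channel (default SD 0.1 V), tuned only so the per-level device SDs are of
the same order as a physical bench run (a few mL to ~14 mL); it is not a
sensor model. Two consequences are worth knowing. First, because sub-1 V
readings clamp to zero flow, symmetric voltage noise rectifies into a
small positive volume bias over the accumulation window, which is most
visible as a larger *relative* error at the lowest set volume — the same
qualitative pattern a physical bench shows. Second, noise spikes during
expiration can fabricate onsets, so each rep takes the first detected
breath, and reps with no detection are reported as missing rather than
dropped. With `noise_sd = 0` the whole report is deterministic and every
ratio sits inside the discretisation bound.

The per-level mean comparison uses Welch's unequal-variance $t$ (the safer
default when one side — the reference — has near-zero variance), with a
paired option since the protocol delivers paired measurements. When both
samples are numerically constant the statistic is undefined and the
convention p = 1 (equal means) / p = 0 (different) applies.

## Adequacy classification

The study definitions are closed intervals: optimal TV 420–480 mL (adult
bag) and 120–180 mL (paediatric bag) — the same 60 mL width; below is
hypoventilation, above hyperventilation; volumes beyond the bag maximum
(1300 / 300 mL) remain hyperventilation but are flagged implausible.
Optimal VI is 6–8 s inclusive. Boundary inclusivity is a deliberate
convention (the ranges are published without strictness) and is tested
explicitly at the boundaries. Each session summary counts TV classes over
all breaths and VI classes over the $n-1$ onset-to-onset intervals — the
last breath of a session contributes to TV but not VI.

## Trial analysis

`simulate_trial()` reproduces the crossover design: half the cohort
performs device-assisted (RAV) sessions first, half non-assisted (NV)
first; each participant runs one 2-minute session per bag size per period
and crosses arms between periods. Operator behaviour per arm × bag size
defaults to the published per-arm session statistics (e.g. unassisted
adult-bag squeezes ~392.8 ± 136.4 mL every 6.37 ± 3.17 s; assisted ones
432.0 ± 63.9 mL every 6.84 ± 1.13 s), the feedback effect thus being
modelled as a shift toward target and a shrinkage of spread.

**What the generator does and does not emulate.** Truncated-normal
volumes and intervals reproduce the first two moments of each arm, not the
full empirical distributions, which were visibly non-normal — assisted
operators heap tightly inside the optimal bands, unassisted intervals are
heavy-tailed. Consequently the simulated *category proportions* (e.g. the
optimal-VI share of assisted sessions) are not expected to match the
published ones, and only the weakest such comparison is asserted anywhere:
for unassisted adult-bag sessions the normal approximation puts ~16 % of
volumes in 420–480 mL, within a documented ±6-point tolerance of the
observed 18.46 %. No chest compressions, airway mechanics, fatigue or
learning effects are modelled.

`proportions_table()` reproduces the results-table arithmetic (counts and
percentages to 2 dp), `chi_square_2xk()` the Pearson comparisons, and
`crude_odds_ratio()` gives the cluster-ignoring 2×2 odds ratio with a
Woolf interval — applied to the published adult-bag optimal-TV counts it
gives ≈3.96, *near but not equal to* a population-averaged model estimate
(3.90 in the study), precisely because it ignores within-participant
clustering. That gap is expected, not a defect.

### The marginal logistic model

Repeated binary adequacy outcomes are clustered by participant, so the
model of record is a population-averaged logistic regression fitted by
generalised estimating equations (`gee_logit()`, written for this
package): with $\mu_{ij} = \operatorname{logit}^{-1}(x_{ij}'\beta)$,
Fisher scoring solves
$$\sum_i D_i' V_i^{-1}(y_i - \mu_i) = 0,\qquad
  V_i = A_i^{1/2} R(\rho) A_i^{1/2},$$
alternating with the moment estimate of the exchangeable correlation from
Pearson residuals,
$\hat\rho = \sum_i \sum_{j<k} e_{ij}e_{ik} \big/ (N_\text{pairs} - p)$,
until the largest coefficient change is below $10^{-6}$ (at most 100
iterations; non-convergence is flagged, never silent). The scale is fixed
at 1, standard for binary outcomes. Reported standard errors are always
robust (sandwich); odds ratios are exponentiated coefficients with Wald
intervals. The exchangeable inverse is applied in closed form
($R^{-1} = \tfrac{1}{1-\rho}[I - \tfrac{\rho}{1+(n_i-1)\rho}J]$), so the
fit is a few vectorised cross-products per iteration and handles thousands
of clusters in well under a second. Degenerate outcomes, fewer than two
clusters, and separation (|linear predictor| > 30) raise errors.

Design choices: the crossover period effect is *not* in the default model
(the published model used device assistance, bag type and their
interaction only) but is available via `include_period = TRUE`; no
multiplicity adjustment is applied, matching the published analysis.
Because the raw participant-level data are not public, the printed trial
odds ratios cannot be desk-checked; the package instead verifies the
estimator by properties — exact agreement with ordinary logistic
regression for independence/unclustered data, recovery of a known
marginal odds ratio (3.9) within 10 % on a 2000-cluster simulation, and
~95 % null coverage over 100 replicates — with correlated binaries built
so their marginal probabilities are exact by construction
(`simulate_clustered_binary()`).

### Sample size

`mcnemar_sample_size()` implements the conditional (Connett–Smith–McHugh)
paired-proportions formula
$$n = \left\lceil \frac{\big(z_{\alpha/2}\sqrt{\psi} +
  z_\beta\sqrt{\psi - d^2}\big)^2}{d^2} \right\rceil,$$
with $\psi$ the discordant-pair proportion and $d = p_A - p_B$. At the
pilot operating point (85 % vs 35 % optimal, $\psi = 0.5$, 80 % power) it
gives 14 pairs at $\alpha = 0.05$ and 17 at $\alpha = 0.025$. The study
that motivated this package reported 26 participants per group from the
same inputs; that figure cannot be reconciled with the conditional
formula, so the calculator documents the formula it uses rather than
reverse-engineering a multiplier to reach 26.

## Numerical conventions and degenerate inputs

* Fine grid 1 ms; the inspiratory sample count is rounded, so per-breath
  volume is exact up to one grid step times peak flow (asserted).
* Zero-duration specs yield empty traces; empty sample streams yield empty
  breath tables; empty sessions yield zero counts and `NA` moments.
* Truncated-normal draws use inverse-CDF sampling, so `sd = 0` degenerates
  cleanly to the clamped mean and identical seeds give bit-identical
  traces; the firmware path contains no randomness at all.
* All interval classifications are inclusive at both ends.

## Problem sizes

The shipped tests and the acceptance script use: 2-minute sessions on the
1 ms grid; bench validation at 5 levels × 25 reps; trial simulations of
2–26 participants; GEE checks on 2000-cluster recovery and 100 × 500-cluster
null coverage. These sizes make every statistical check stable at fixed
seeds while the whole suite completes in well under a minute.

## Known limitations

* No lung/airway mechanics, gastric inflation or oxygenation physiology;
  pressure is display plumbing.
* The noise surrogate is a voltage-noise stand-in for a physical bench,
  so published bench *values* (means, SDs, band percentages) are matched
  in protocol and qualitative behaviour, not numerically.
* Operator behaviour is a two-moment model; published categorical
  proportions from real sessions are not reproduction targets.
* The accumulation window cannot re-trigger; ventilation faster than one
  breath per 1.75 s is deliberately merged, as the device would.
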