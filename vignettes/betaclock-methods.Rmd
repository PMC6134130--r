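---
title: "Modelling clock-gated insulin secretion under conflicting light and food cues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clock-gated insulin secretion under conflicting light and food cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaclock)
```

## The biological problem

Nocturnal rodents eat at night. Their pancreatic β cells carry a local
circadian clock that prepares the insulin-exocytosis machinery ahead of the
nightly meal, so that when glucose arrives the secretory apparatus is
already in place. The clock itself listens to two external timing signals
(zeitgebers): nutrient cues that follow the feeding schedule, and
SCN-driven neural cues that follow the light–dark cycle. When food access
is experimentally restricted to the rest (light) phase — daytime feeding,
DF — these two cues point twelve hours apart. `betaclock` implements a
mechanistic ODE model of this situation and the full in-silico experimental
programme around it: feeding-schedule inversion, cue-strength scans,
architecture ablations, anticipation analysis, and parameter calibration.

## Model structure

The integrated system has 15 ordinary differential equations: 13 model
variables (9 clock components, glucose, insulin, and the mRNA/protein of a
generic exocytosis factor EXO) plus a 2-equation food-intake subsystem.

**Clock.** The 9 clock components are mRNA and protein for *Bmal1*, *Per*,
*Cry* and *Rev-Erb*, plus one PER-CRY complex. Isoforms are merged and no
cytoplasmic/nuclear distinction is made. BMAL1 protein (standing in for
CLOCK-BMAL1) activates *Per*, *Cry*, *Rev-Erb* and *Exo* transcription; the
PER-CRY complex inhibits the *action* of BMAL1 (a multiplicative Hill
repression on the BMAL1-activated terms, not on BMAL1 synthesis); REV-ERB
protein represses *Bmal1* transcription. Every regulation is a product of
Hill activation/repression terms; complex formation is mass action; every
species decays linearly. This is a standard Goodwin/Leloup-style
construction; the ROR activating arm on *Bmal1* is deliberately omitted —
only the Rev-Erb repressive loop is modelled.

**Metabolism.** Food intake raises blood glucose; insulin promotes glucose
uptake (a bilinear `k_gi * insulin * glucose` term on top of first-order
clearance); glucose has a basal production term. Insulin follows the
coincidence-gated balance

$$\frac{d[\mathrm{Ins}]}{dt} = k_i\, f_{glu}\, f_{exo} - d_i\,[\mathrm{Ins}],$$

where \(f_{glu}\) is a saturating Hill function of glucose and
\(f_{exo}\) a saturating Hill function of EXO protein. Secretion is high
only when glucose *and* the clock-driven exocytosis capacity are high
simultaneously — the coincidence mechanism at the heart of the model.

**Zeitgebers.** The SCN cue is a clipped cosine: a half-cosine bump peaking
at ZT6 (mid light phase), zero through the dark half-cycle, scaled by the
coupling strength `cneur` and added to *Rev-Erb* transcription. The clipped
(rather than raised) cosine was chosen because it delivers twice the
rhythmic amplitude per unit of DC input; the DC component shifts the
Rev-Erb operating point and, with it, the entrained period, so a high
rhythmic-to-DC ratio keeps entrainment stable across the whole `cneur`
scan while leaving the cue strong enough to hold *Bmal1*'s phase against a
shifted feeding schedule. The glucose cue enters *Per* transcription as an
additive Hill term of strength `c_glu` (an additive rather than
multiplicative combination with the BMAL1 drive; the choice is switchable
in the rate law but additive is the package default).

**Food intake.** The feeding window (default: the full dark phase,
ZT12–24, duration 12 h; configurable) defines a smooth square drive. Two
ODEs turn it into the nutrient signal: a fast *eating activity* variable
tracks the drive, a slow *satiety pool* integrates the activity, and the
signal entering the glucose equation is
`max(activity - satiety, 0)` — a front-loaded pulse that peaks one to two
hours after the window opens and then fades as satiety builds. This
mirrors the measured burst of pellet intake at dark onset, and it matters
mechanistically: if the nutrient signal were the smoothed square itself,
blood glucose would integrate through the window and peak at its *end*,
which reverses the alignment geometry between the glucose gate and the
clock gate and with it the entire metabolic phenotype.

## How the phenotypes arise

Under nighttime feeding (NF) the glucose bump peaks early in the dark
phase. *Per*, driven by the glucose cue, peaks there too; *Bmal1*, held by
the SCN cue acting through REV-ERB, peaks in near antiphase; EXO protein,
downstream of BMAL1, rises through late day and peaks just after the meal
starts. The two secretion gates overlap, secretion is efficient, and the
pre-meal rise of \(f_{exo}\) on a basal glucose background produces a slow
anticipatory insulin rise followed by a steep post-meal rise — a slope
rupture.

Inverting the feeding schedule moves the glucose cue by 12 h while the SCN
cue stays put. *Per* follows the food almost fully; *Bmal1* is twisted
between the conflicting inputs and shifts only partially. Because EXO
follows the *Bmal1* arm, its phase shifts by less than the glucose bump
does: the gates decouple, their coincidence index drops, insulin falls and
glucose rises (hypoinsulinemia and hyperglycemia), and the anticipatory
rise disappears. All of these statements are computed, not assumed: the
test suite and `scripts/acceptance.R` re-derive each one from fresh
integrations.

## Architectures

Two ablations probe the role of each clock layer, both realised by
replacing a signal with its temporal mean:

* `no_central_clock` — the SCN cue is replaced by its mean
  (`cneur / pi`, known in closed form). Food is then the only zeitgeber,
  and a feeding inversion shifts *every* clock component by exactly 12 h
  with unchanged insulin: the system adapts completely, but (as the
  re-entrainment analysis shows) only after several transient cycles,
  because the local clock has inertia.
* `no_clock` — *Exo* transcription is replaced by its mean over the
  entrained physiological NF cycle (computed and cached by
  `ablation_reference()`). Secretion then follows glucose alone: NF and DF
  become metabolically identical up to a 12 h rotation, anticipation is
  absent, and the metabolic response to a schedule switch is essentially
  immediate.

## Phase and metabolic metrics

Peak phases are grid argmaxima refined by quadratic interpolation through
the three bracketing samples, reported modulo 24 h; flat signals (as EXO
mRNA under `no_clock`) have undefined phase and are reported as `NA`.
Between-condition shifts use the minimal circular distance (in [0, 12] h)
with a delay/advance tag; the differential-shift statistic is the signed
circular difference (Bmal1 − Per) in one condition minus the other,
wrapped to (−12, 12]. Amplitudes are peak-to-trough. The coincidence index
is the normalised overlap
\(\oint f_{glu} f_{exo}\,dt / \sqrt{\oint f_{glu}^2 dt \oint f_{exo}^2 dt}\),
which is 1 exactly when the gates are proportional and is invariant to
joint time shifts and separate rescalings.

Anticipation is quantified from the insulin profile: the mean slope over
the 3 h before food onset (`pre_slope`), the mean slope over the 3 h
after, and the anticipation index `pre_slope * window / amplitude`
(the fraction of the cycle amplitude climbed during the pre-meal window).
A slope rupture is declared when the normalised pre-onset slope exceeds
`theta_pre = 0.5` amplitude-fractions per 24 h and the post-onset slope is
at least `slope_ratio = 2` times the pre-onset slope. The thresholds are
stored as function defaults, documented here, and were fixed by the three
reference scenarios (NF: rupture; DF and no-clock: none), whose normalised
pre-onset slopes are well separated (about 0.60 / 0.45 / 0.17). A perfectly
clockless profile does not reach exactly zero index because glucose and
insulin carry a few hours of joint relaxation memory from the previous
feeding window; the residual is about 2% of the cycle amplitude.

## Numerical choices

Integration uses `deSolve::lsoda` on a compiled-C right-hand side (the
plain-R rhs is exported as the readable reference and cross-checked
against the compiled one in the tests). Default tolerances are
`rtol 1e-8 / atol 1e-10`; the test-suite and acceptance runs use
`rtol 1e-6 / atol 1e-8`, which changes phase estimates by well under
0.01 h while keeping the full suite under half a minute. Entrainment is
detected cycle-by-cycle from a fixed, documented initial state (all
variables at 0.1): the run is converged when the normalised cycle-to-cycle
sup distance (per-variable, scaled by amplitude or mean) falls below 1e-3;
unconverged runs are flagged, never silently returned. The uniform output
grid is 0.05 h. Free-running behaviour is probed by holding both cues at
their temporal means; with the reference parameters the clock then
oscillates autonomously with a period near 23 h, and with the cues absent
altogether (`cneur = 0`, constant food drive) the system is allowed to
reach either a non-24 h free-run or a steady state — both are reported as
"not 24 h-entrained", which is the honest label.

Re-entrainment times after an NF→DF switch are counted as full cycles
until the post-switch trajectory matches the final DF limit cycle within
the same normalised tolerance, reported separately for all model variables
and for the metabolic pair (glucose, insulin).

## Calibration

Sparse time-course tables (variable, time, value, replicate; typically
6 points/day) are interpolated with a least-squares Fourier series (mean
plus two harmonics at the 24 h fundamental — more harmonics are not
supportable at this sampling density). The fitting objective entrains the
model and sums amplitude-normalised squared residuals against the target
curves, by default on the table's own sampling grid: a sharp, asymmetric
waveform like the calibrated *Per* profile carries about an hour of
band-limiting bias in its two-harmonic peak, and evaluating between the
samples would push the fit toward that bias. Parameter points that fail to
entrain cost a fixed 1e6 penalty, which keeps the derivative-free search
inside the entrained regime without gradients.

The optimiser is a from-scratch Hooke–Jeeves pattern search: exploratory
coordinate moves with per-coordinate steps, pattern (extrapolation) moves
from improved base points, multiplicative step shrinking, optional box
projection, deterministic throughout. Parameter refits run in log space —
rate constants span scales and must stay positive — inside an 8-fold box
around the perturbed start, which keeps the search off degenerate ridges
such as jointly rescaled secretion/clearance pairs. Practical
identifiability is *not* claimed for the full parameter set; the recovery
harness restricts to small free subsets whose effects are visible in
distinct observables (for example glucose clearance, EXO transcription
scale and insulin clearance against glucose, EXO and insulin curves).

The reference parameter set shipped with the package is itself a product
of this machinery plus staged design: the clock core was laid out around a
symmetric operating point with each Hill term near half-saturation, gains
were pushed past the oscillation threshold, the clock block was
time-rescaled to a circadian free-run, and the coupling/metabolic block
was then calibrated by pattern search against the qualitative phenotype
(differential phase shift, syndrome direction, coincidence ordering,
anticipation contrast, free-run band). Hill exponents are 4–10; the
largest (on the REV-ERB arm) provide the loop gain that a 4-stage chain
with linear degradation needs to oscillate.

## What the synthetic data do and do not emulate

`generate_pseudo_experiment()` samples the entrained cycle at a circadian
bench-study density (every 4 h, 3 replicates by default) and applies
multiplicative lognormal noise with constant CV (default 0.1) — the error
structure of positive expression/hormone measurements. It reproduces the
sampling scheme and noise character of real profiles, not their biological
sources of variation: there are no animal-to-animal random effects, no
ultradian meal microstructure, and the "truth" underlying each table is
the deterministic model itself. Passing recovery tests therefore
demonstrates that the pipeline is correct and the chosen parameters are
identifiable from such designs — not that the model fits any particular
animal.

## Known limitations

* The small-shift response is stiffer in *Bmal1* than the large-shift
  compromise would suggest: a ±2 h feeding shift changes the Bmal1–Per
  phase relation by about 1.5 h (at ±1 h it stays under 1 h), while a 12 h
  inversion splits the arms by over 4 h. In this rate-law family the same
  couplings control both behaviours; parameter changes that soften the
  small-shift response (stronger PER-CRY→Rev-Erb transmission, weaker SCN
  hold) either collapse the differential shift at 12 h or push the
  strongly driven conditions into period-doubled (48/72 h) locking
  windows. Insulin amplitude, by contrast, is robust to small shifts
  (within ±4%).
* Glucagon/α-cell regulation, β-cell mass and proliferation,
  glucocorticoid and temperature cues, and insulin feedback on central
  food-intake control are out of scope by design.
* The entrained dynamics sit in a genuinely nonlinear regime: a few
  combinations of strengthened couplings lock at multiples of 24 h.
  `run_to_limit_cycle()` labels such runs as not entrained rather than
  folding them.

## Problem sizes used by the tests

The test suite entrains the model a few dozen times (up to 200 cycles per
run), runs the `cneur` scan at the 0.05 step over [0, 1.55], Monte-Carlo
checks noise calibration with 20 seeds and 200 replicates, and performs
one three-parameter recovery (about 150 objective evaluations). The whole
suite completes in well under a minute on a single core.
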