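---
title: "Equilibrium-point FES modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium-point FES modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaafes)
```

## The problem

Functional electrical stimulation (FES) of a single muscle gives poor force
control: the current-to-force map is strongly nonlinear, and a joint driven
by an agonist–antagonist pair is redundant — many stimulation pairs produce
the same force. The equilibrium-point view resolves both problems at once.
For the elbow, driven by the biceps (flexor) and triceps (extensor), the
two stimulation channels are re-coded as

- the **EAA ratio** $r_E = I_e / (I_f + I_e)$ — the extensor share of the
  total drive, which sets the joint's equilibrium point, and
- the **EAA activity** $a_E = I_f + I_e$ — the total drive, which sets the
  joint stiffness,

where $I_f, I_e \in [0, 1]$ are *normalized* stimulation intensities. Each
muscle's physical current is mapped onto $[0,1]$ between its contraction
threshold $I'_{min}$ and its pain-free maximum $I'_{max}$ (both in mA,
calibrated per subject and per muscle); normalization removes most of the
flexor/extensor asymmetry and the per-subject nonlinearity. With the elbow
held isometric at 90°, changing $r_E$ at constant $a_E$ changes the hand
force, negative for flexion and positive for extension.

The package implements the full workflow around this coding: command
decoding and calibration, stimulation protocol generation, a linear plant
model from $r_E$ to hand force, frequency-response identification of that
plant, forward force prediction, and validation scoring — exercised end to
end on a synthetic virtual subject.

## The plant model

The ratio-to-force map in the isometric posture is modelled as a
critically damped second-order lag with dead time (SOPDT):

$$G(s) = K\,\frac{\omega_n^2}{s^2 + 2\zeta\omega_n s + \omega_n^2}\,
e^{-\tau s}, \qquad \zeta = 1 .$$

- $K$ (N per unit ratio) is the steady-state gain: force per unit $r_E$.
- $\omega_n$ (rad/s) is the natural angular frequency; it reflects joint
  stiffness and grows with $a_E$ (the bundled anchors give 14.3, 19.0 and
  20.5 rad/s at $a_E$ = 0.5, 0.8, 1.0 for one subject).
- $\zeta$ is fixed at 1: the measured gain curves are flat at low
  frequency and roll off at the second-order rate without resonance, so
  damping cannot be resolved from the data and the critically damped form
  is assumed.
- $\tau$ (s) is the stimulation-to-force latency, 0.045–0.100 s across the
  bundled subjects.

Assumptions: linearity in $r_E$ at fixed $a_E$ (identification is done at
$a_E = 1$), isometric posture (no joint motion), no fatigue, and additive
superposition of voluntary and electrical commands — the measured force
under simultaneous voluntary effort and stimulation is the voluntary
baseline plus the plant response.

The model is deliberately literal: a constant input $u$ settles at $K u$,
so the worked-example plant ($K = 11.22$, $\omega_n = 20.5$, $\tau = 0.05$,
i.e. denominator $s^2 + 41 s + 420.25$) answers a unit step with 11.22 N.

## Simulation numerics

`sopdt_simulate()` works at 1 kHz (the force acquisition rate; coarser
steps are refused above `dt = 1` ms, and a warning is raised when
$\omega_n\,dt > 0.2$). The second-order core is discretized *exactly*: the
state transition over one step is the matrix exponential of the companion
matrix (closed form for $\zeta = 1$), so there is no integration error and
no stiffness constraint.

The input is interpolated linearly between samples (first-order hold)
rather than held constant (zero-order hold). A zero-order hold behaves
like an extra $dt/2$ of input delay — about 0.03 rad of spurious phase at
the top of the measurement grid ($\omega \approx 63$ rad/s) — which would
bias the identified dead time by half a sample. With the first-order hold
the simulated frequency response matches the analytic one to better than
0.04 % in gain and well below 0.001 rad in phase over the whole grid.

The dead time is applied as an integer-sample input shift, $\tau$ rounded
to the nearest millisecond. The bundled $\tau$ values are all multiples of
5 ms, so for them the delay is exact; for arbitrary $\tau$ the rounding
error is at most 0.5 ms. Initial conditions are zero: output before
$\tau$ (plus input onset) is exactly zero.

## Stimulation protocols

All generators emit 1 kHz `eaa_trace` objects with half-open cycle
intervals ($t_i = i/\text{rate}$), so cycle segmentation downstream is
unambiguous.

- `sweep_sinusoid(T)`: the identification probe
  $r_E(t) = -0.5\sin(2\pi t/T) + 0.5$ at $a_E = 1$ — the full ratio range,
  centred on balanced co-contraction. The probe grid
  (`frequency_grid()`) spans $T$ = 0.1–0.5 s in 0.025 s steps (17
  periods, $\omega \approx 12.6$–$62.8$ rad/s).
- `composite_sinusoid()`: the two-period validation input, weights
  0.6/0.4 on periods 0.3/0.6 s.
- `step_trace(step_schedule())`: the ratio staircase, $0 \to 1 \to 0$ in
  0.2 steps with a 3 s dwell.
- `burst_trace(burst_spec())`: three 1 s bursts (two 0.5 s cycles each) at
  onsets 1, 4, 7 s with the channels *off* in between — off means 0 mA,
  below the contraction threshold, not "held at $r_E$ = 0".
- `am_carrier()`: the stimulator's 60 Hz amplitude-modulated sine carrier,
  synthesized at ≥ 6 kHz; the per-cycle peak of the waveform reproduces
  the commanded envelope.

**Lead-in choice.** Each sweep is preceded by a 0.5 s lead-in. The package
defaults to *holding* $r_E = 0.5$ (balanced co-contraction) during the
lead-in, rather than leaving the channels off, and
`identify_subject()` additionally inserts at least 0.6 s of unrecorded
warm-up cycles before the 10 recorded ones. The reason is the literal
plant convention above: with an off lead-in, stimulation onset presents
the plant with a $K/2$ step whose transient has not died out two cycles
into a short-period sweep — at $T = 0.1$ s and $\omega_n = 14$ rad/s it
corrupts the steady-cycle gain estimate by several percent. Starting from
the operating point and recording only once the oscillation is steady is
standard practice in frequency-response measurement and removes the bias
(recovery error drops below 0.05 %). An `lead = "off"` option preserves
the off lead-in where the transient itself is of interest.

## The virtual subject

`sample_subject(seed)` draws a ground-truth plant uniformly and
independently within the ranges spanned by the six bundled subjects
($\omega_n \in [14.0, 31.4]$ rad/s, $K \in [1.04, 11.22]$ N,
$\tau \in [0.045, 0.100]$ s, $\zeta = 1$), plus a calibration drawn within
the corresponding per-muscle current bounds. No parameter covariance is
claimed — the printed six-subject sample is too small to estimate one.

`run_protocol()` turns a command trace into replicate "measured" force
traces:

$$f_i(t) = a_E\,G_{a_E}(s)\,r_E(t) + f_{\text{baseline}} + c_{\text{asym}}
+ \varepsilon_i(t)$$

- **Activity dependence.** When an activity map is supplied and the
  protocol runs at $a_E \ne 1$, the plant's $\omega_n$ is substituted
  through the map (piecewise-linear through the anchors, clamped at the
  ends) and the effective gain scales with $a_E$ — total drive sets both
  stiffness and force displacement. At $a_E = 1$, the identification
  condition, the subject reduces exactly to its ground-truth plant.
- **Asymmetry.** Real recordings show the oscillation centre shifted
  toward extension when the input period is 0.4 s or less, attributed to
  the extensor responding faster than the flexor. The generator
  reproduces this phenomenology with a rectified offset
  $c_{\text{asym}} = \text{asymmetry} \cdot K \cdot \max(0, 0.4 - T)/0.4$
  on active samples. This is an explicitly synthetic stand-in — no
  mechanistic model of the speed difference is published — and it is *not*
  part of the ideal plant, which models only the amplitude ratio and phase
  difference.
- **Noise.** Gaussian white noise at the 1 kHz sample level, default
  $\sigma = 0.5$ N. No noise magnitude is published; 0.5 N gives realistic
  single-trial traces (visible noise on forces of a few newtons) while
  leaving the trial- and cycle-averaged waveforms clean, and it is
  configurable and recorded in every manifest.
- **Reproducibility.** Subject, trial noise and every downstream artifact
  derive from integer seeds; the same seeds give byte-identical outputs.

What the generator does *not* emulate: muscle fatigue, day-to-day
calibration drift, recruitment-curve nonlinearity beyond the affine
calibration map, voluntary-command variability, and any coupling between
noise level and stimulation intensity. Passing tests therefore show that
the *analysis* is correct under the model's own assumptions, not that the
model captures every feature of real recordings.

## Identification pipeline

For each probe period, three replicate traces are averaged pointwise; the
record after onset is cut into whole cycles and cycles 3–8 (1-based, six
cycles) are averaged into one representative cycle — the first two cycles
absorb any residual transient, and the averaging reduces the noise
variance by the factor (trials × 6). One cycle is then fit by sin–cos
harmonic regression,

$$f(t) \approx p\,\sin(2\pi t/T) + q\,\cos(2\pi t/T) + c
= A\,\sin(2\pi t/T + \phi) + c,$$

with $A = \sqrt{p^2+q^2}$ and $\phi = \mathrm{atan2}(q, p)$, a convention
pinned by test: $p = A\cos\phi$, $q = A\sin\phi$, so the reconstruction is
exact on any single-harmonic cycle. Only the fundamental is fitted; the
offset $c$ is estimated but excluded from the transfer-function fit and
reported separately as the oscillation-centre diagnostic.

Bode samples are gain $= A / 0.5$ (the ratio sinusoid's amplitude) in dB,
and phase relative to the $-\sin$ input convention (fitted phase minus
$\pi$), wrapped to $(-\pi, \pi]$ and unwrapped across increasing frequency
by minimal jumps — for any SOPDT truth on this grid the unwrapped phase is
monotonically decreasing.

`fit_sopdt()` is deterministic, with no random restarts:

1. $(K, \omega_n)$ by least squares of the gain curve in dB. For fixed
   $\omega_n$ the optimal $K$ in dB is the mean residual, so the problem
   is a 1-D search in $\omega_n$: a 200-point log-grid over 5–100 rad/s
   followed by bounded refinement (`optimize`, tolerance $10^{-10}$).
2. $\tau$ by regressing the residual phase
   $\varphi + 2\arctan(\omega/\omega_n)$ on $-\omega$ through the origin,
   clamped at $\tau \ge 0$.

A warning is issued when the fitted corner lies outside the sampled band.
The high-frequency slope diagnostic (`fit_gain_slope()`, default band:
upper half of the grid) is reported in dB/dec; on the $\zeta = 1$
asymptote it is $-40$ dB/dec, while over the finite measurement grid —
which barely reaches $3\omega_n$ — it is necessarily shallower.

Measured performance under the package's own study conditions (20 seeds,
noise 0.5 N, 3 trials × 10 cycles, the 17-period grid): median parameter
errors below 1 % for $K$, $\omega_n$ and $\tau$, worst cases below 10 %.
At zero noise, recovery is better than 0.05 % with $\tau$ exact up to the
millisecond rounding.

## Validation

Three verification experiments (`run_verification()`) score a model's
forward prediction against the virtual subject's trial-averaged response:

- **continuous** — the composite input, scored over the last full 0.6 s
  steady-state cycle (the whole-trace score is also reported; the scored
  segment is recorded in the report, since the published protocol does not
  state which was used);
- **stepwise** — the staircase, scored over the settled final 1 s of each
  3 s dwell (steady values are what the comparison is about);
- **voluntary** — the bursts on a held baseline of ±10 N, scored over the
  full trace.

The score is the multiple coefficient of determination, implemented as
$R^2 = 1 - SS_{res}/SS_{tot}$ about the measured mean (the published
report does not spell out its formula; this is the standard choice), plus
the maximum absolute error in N. $R^2$ is invariant to a common affine
rescaling and errors on a constant measured trace. Self-validation — the
subject's own plant as the model, no noise, no asymmetry — scores exactly
1.0 on all three experiments, and plateau errors on the staircase stay
under 2 N for any model within the identification tolerance.

## Degenerate inputs and tie-breaks

- $a_E = 0$ (rest): both channels off at 0 mA — *not* at $I'_{min}$, which
  is a contraction threshold, not zero output. The ratio is undefined at
  rest and stored as `NA`.
- Computed intensities outside $[0,1]$ by $\le 10^{-9}$ are clamped
  (floating-point noise); larger excursions raise an unrealizable-command
  error naming the muscle and sample.
- Constant-cycle harmonic fits: the design matrix is always full rank on
  distinct sample times; rank deficiency (degenerate time bases) is an
  error, and $R^2$ is `NA` on a constant cycle.
- $\tau$ estimates are clamped at 0; a delay-free system fits within one
  phase-sample equivalent of zero.

## Problem sizes

The bundled tests and the acceptance script run the pipeline at its
natural scale: 17 periods × 3 trials × 10 recorded cycles at 1 kHz per
identification (≈ 0.1 s of compute per subject), 20-seed recovery studies,
and 9–33 s validation traces. Everything completes in seconds on one core.

## Known limitations

- The plant is literal in $r_E$: a constant ratio of 0.5 predicts a
  sustained $K/2$ extension force, whereas balanced co-contraction in a
  real isometric posture produces near-zero force. The identification is
  insensitive to this (offsets are excluded), but absolute force
  predictions inherit the convention.
- $\zeta = 1$ is assumed, not estimated; plants far from critical damping
  would be mis-fit.
- The asymmetry offset is phenomenological; its rectified-linear shape in
  $T$ is a modelling convenience.
- Near the ends of the ratio range ($r_E$ close to 0 or 1) a single muscle
  acts alone and the linear model is least accurate; the stepwise
  experiment shows this as larger plateau error at the extreme levels.
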