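---
title: "Two-conductance gating analysis: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-conductance gating analysis: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgate)
```

## The biophysical setting

Hv1-type voltage-sensor domains conduct protons. The wild-type channel
carries a single depolarization-activated conductance (G_AQ). When the
outermost S4 arginine is replaced by histidine, a second,
*hyperpolarization-activated* proton "shuttle" conductance (G_SH)
appears in the resting state. A whole-cell recording from such a
channel therefore superposes three currents:

$$I(V,t) = G_\mathrm{SH}\,m_\mathrm{SH}(t)\,(V-E_\mathrm{H})
         + G_\mathrm{AQ}\,m_\mathrm{AQ}(t)\,(1-b(V))\,(V-E_\mathrm{H})
         + G_\mathrm{LEAK}\,V,$$

with $E_\mathrm{H}$ the Nernstian proton reversal potential set by the
pH gradient, $m$ the gating variables, and $b(V)$ an optional
instantaneous outward-only block (an arginine engineered at the outer
pore position acts as a tethered blocker of outward current, relieved
immediately upon hyperpolarization). The analysis problem is to take
families of step-protocol sweeps and recover the gating parameters of
both conductances — even though neither conductance reaches both of
its plateaus inside an experimentally accessible voltage range.

## Gating model and its assumptions

Each gated conductance follows a two-state Boltzmann steady state with
an explicit polarity flag,

$$p_\infty(V) = \frac{1}{1+\exp\!\big(s\,(V-V_\mathrm{eff})/dx\big)},
\qquad s = \begin{cases} +1 & \text{hyperpolarization-activated}\\
-1 & \text{depolarization-activated}\end{cases}$$

and first-order kinetics with separate fixed activation and
deactivation time constants. Slope factors are always stored positive;
the gating direction lives in the polarity flag, because fitted slope
factors are conventionally reported positive for rising and falling
curves alike. The effective midpoint shifts with bath pH,
$V_\mathrm{eff} = V_{0.5} + s_\mathrm{pH}\,( \mathrm{pH_o} - 6.5)$ with
$s_\mathrm{pH} = -40$ mV per pH unit by default — the canonical
ΔpH-dependence of proton-channel gating (measured slopes for the two
branches are −44.2 and −41.0 mV/pH unit; −40 is the round value the
validation simulation uses). Assumptions worth stating:

* the two conductances gate **independently** (they are fitted
  independently; a coupled sequential scheme would be a model
  extension, not an analysis change);
* time constants are voltage-independent within each relaxation
  direction — tail extrapolation only requires that the decay be
  exponential;
* the block is an algebraic function of voltage with no state
  variable, consistent with monophasic, hook-free tail decays.

## Physical constants and units

CODATA values of R and F are used; the default temperature is
293.15 K, at which RT/F = 25.26 mV (reported as 25.3) and the Nernst
slope is 58.17 mV/pH unit (reported as 58.2). Measured tail reversal
slopes of ~52–56 mV/pH unit are common in real recordings (buffer
limitations); the package exposes temperature as a parameter rather
than reconciling printed round values. Units are mV, nS, pA and ms
throughout, so that pA = nS × mV without conversion factors.

## What the simulator emulates — and what it does not

`simulate_sweep_set()` produces one trace per test step for a
three-epoch protocol (hold → step → tail). Within each constant-voltage
epoch the gating variable relaxes as an exact exponential evaluated
per sample, so the integration has **no step-size error**: refining
the sampling interval reproduces the same currents to rounding (this
is tested). Noise, when requested, is additive white Gaussian on the
current, seeded.

Emulated: two opposite Boltzmann conductances, ohmic leak, Nernstian
reversal, −40 mV/pH_o midpoint shifts, instantaneous outward-only
block, seeded noise. Deliberately not emulated: capacitance
transients, series-resistance error, P/N subtraction artifacts,
pH-buffer depletion drift (real large currents sag as the local pH
gradient collapses), multi-state or single-channel stochastic gating.
Passing tests on simulated data therefore validate the *estimators*
under the model's statistical structure; they cannot certify behavior
under drift or uncompensated access resistance, which a real recording
would add.

### Reference parameter sets

`reference_parameter_sets()` encodes the channel variants the
reproduction run exercises, with a 1.5 nS leak throughout: the
two-conductance variant (G_SH 4.6 nS, V₀.₅ −189 mV, dx 42.1; G_AQ
22.2 nS, V₀.₅ +29.4 mV, dx 24.9), its blocked counterpart (G_AQ
midpoint +26.3 mV, dx 16.3, full outward block with midpoint −60 mV
and 10 mV steepness — steep and complete enough that the steady
outward current is leak within a few percent), midpoint-shifted
variants (+65 and +105 mV on the G_AQ midpoint), and a WT-like single
conductance. The WT-like midpoint is set to +70 mV with dx 16.2 so
that the operational 2%-of-maximum threshold falls at +7 mV, the
scale of tabulated wild-type thresholds; its kinetics are slow
(τ_act 300 ms), which leaves midpoint recovery exact because a
uniform activation shortfall rescales the tail curve without moving
its midpoint.

## The estimators

**Instantaneous tail current.** Tails are fit with
$I(t)=I_0+A\,e^{-(t-t_0)/\tau}$ and reported as $I_0+A$, the value at
the instant of the voltage change. The default window starts two
samples after the transition (skipping the simulator's instantaneous
jump sample) and ends at five initial-guess time constants. Inside the
pipeline the window is deliberately **short** (20 ms by default): when
a fast deactivating conductance and a slowly relaxing one overlap in
the tail, a long window lets the slow component bend the fit and bias
the extrapolation by tens of pA exactly where the two nearly cancel; a
short window anchors the exponential to the fast component and
relegates the slow one to the plateau term (worst-case extrapolation
error ~0.5 pA on the reference sets, versus ~30 pA with a long
window).

**Threshold V_THR.** Published thresholds come from visual
inspection; the package substitutes a reproducible dual criterion: the
smallest step voltage whose leak-corrected tail magnitude exceeds
max(k·baseline SD, f·max|I_TAIL|), with k = 3 and f = 0.02, and stays
above it at every larger voltage. On a noiseless Boltzmann the 2%
criterion lands at $V_{0.5} - dx\ln(0.98/0.02)$, and the estimate is
translation-equivariant, so midpoint shifts propagate to threshold
shifts within one grid step.

**Tail-relation decomposition.** With the tail potential fixed, the
tail-current-versus-step-voltage relation is exactly a constant leak
pedestal plus a falling and a rising logistic. The pipeline therefore
fits that three-part model directly (`decompose_two_conductances()`
with a free offset) instead of subtracting a straight line over a
"flat" window: a logistic foot is never truly linear, and linear
extrapolation of the hyperpolarization-activated branch produces
spurious threshold crossings ~40 pA in magnitude on the reference
sets.

**First-derivative Gaussian (V_PEAK).** dG/dV is computed by central
differences on the measurement grid (three-point nonuniform-grid
weights at interior points, one-sided at the ends — exact for
quadratics) and fitted with the area-form Gaussian above. The
derivative of a logistic peaks at its midpoint, so V_PEAK estimates
V₀.₅ without needing either plateau. Properties that hold and are
tested: on untruncated curves V_PEAK matches V₀.₅ within 2 mV; the
estimator is shift-equivariant; leak subtraction is unnecessary
because a constant conductance vanishes under d/dV (the Gaussian
baseline term absorbs any residual). A conventions note: the sech²
shape of a logistic derivative is not a Gaussian, and published center
values from this method can carry a systematic half-grid-step offset
if the numerical derivative is one-sided and plotted at a grid
endpoint (a +5 mV shift at 10 mV spacing reproduces the offset seen
in published validation values); central differences are free of that
bias, which is why this package uses them.

**Constrained and shared fits.** Any Boltzmann or Gaussian parameter
can be fixed (fixed parameters are returned exactly as supplied), and
several datasets can be fitted jointly with shared parameters — e.g. a
single slope factor across pH conditions, or a Gaussian width
transferred from the least-truncated condition to the others. The
reproduction run uses exactly that strategy for the
hyperpolarization-activated branch: the width fitted at the most
acidic bath pH (where the curve sits furthest inside the protocol) is
held fixed at higher pH, mirroring how severely truncated conditions
are handled in practice.

**Two-conductance decomposition.** The U-shaped leak-subtracted G–V
relation is fitted as the sum of a falling and a rising Boltzmann
(six parameters, amplitude-bounded at zero). Five seeded, jittered
restarts guard against component swapping and local minima; components
are identified by polarity, and a component whose amplitude collapses
toward zero is flagged rather than silently reported.

## Analysis windows

Fit windows are explicit arguments everywhere, never inferred. The
reproduction default for the Gaussian branch is −240…−100 mV: the
upper edge is kept well below the depolarization-activated range
because in unblocked variants the rising branch's derivative foot
(amplitude G_AQmax/4dx, an order of magnitude larger than the falling
branch's peak) otherwise leaks into the window and drags V_PEAK
positive — visible at bath pH 7.5, where the rising branch sits 40 mV
more negative. This is the same reason the blocked construct is the
preferred background for the pH series.

## Numerical choices, degenerate inputs, tie-breaks

* Nonlinear least squares is Levenberg–Marquardt (`minpack.lm`),
  with slope factors and widths bounded positive and fit failures
  raised as classed conditions carrying diagnostics.
* Conductance points within 1 mV of the reversal potential are
  excluded and flagged, never interpolated.
* Duplicate voltages are an error for the derivative; voltages are
  sorted internally where order is not semantic.
* Degenerate tails (constant traces) return amplitude ≈ 0 with
  I_TAIL = I₀; flat Boltzmann data are flagged as ill-conditioned.
* The reversal-potential estimator interpolates linearly between the
  bracketing tail points (exact here, because the instantaneous tail
  is linear in the tail potential) and signals when no bracket exists.

## Problem sizes

The test and reproduction runs use 23–45-step protocols (10–20 mV
grids over −240…+200 mV), 200 ms steps, 100 ms tails at 1 ms sampling
— a few hundred samples per sweep, seconds per full five-variant,
three-pH reproduction. These sizes resolve every relevant time
constant (≥ 8 samples per τ) and leave the exact-update simulator
indistinguishable from finer grids.

## Known limitations

* The two-conductance model is phenomenological: no coupling between
  the branches, no voltage-dependent time constants.
* V_THR is an operationalization of a subjective call; only
  *differences* of thresholds between constructs on a common grid are
  robust, absolute values depend on the criterion constants.
* Gaussian V_PEAK on severely truncated curves depends on the window
  and (when free) the width; absolute values should be read with the
  width-sharing strategy in mind.
* The simulator's SEM-free noiseless defaults mean across-cell
  variability is only available through the seeded noise-sweep mode,
  which models instrument noise, not biological spread.
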