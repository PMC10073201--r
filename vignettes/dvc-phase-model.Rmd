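---
title: "A three-oscillator phase model of circadian rhythms in the dorsal vagal complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-oscillator phase model of circadian rhythms in the dorsal vagal complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvcphase)
```

## The system and the model

The dorsal vagal complex (DVC) of the brainstem contains three adjacent
circadian oscillators: the area postrema (AP), the nucleus of the solitary
tract (NTS) and the ependymal cell layer lining the fourth ventricle (4Vep).
In ex vivo slice cultures carrying the PER2::LUC bioluminescent reporter,
each region oscillates with a period in the circadian range, and the phase
relationships between regions — the AP leading, the NTS a couple of hours
behind, the 4Vep close to antiphase — are sometimes stable for days and
sometimes drift apart.

`dvcphase` models this triad as Kuramoto-type phase oscillators. Each
region's molecular clock is reduced to a single phase $\theta_i$,
$i \in \{a, n, v\}$, advancing at its intrinsic rate $\omega_i = 2\pi/\tau_i$
and nudged by sine interactions:

$$
\begin{aligned}
\dot\theta_a &= \omega_a + K_{an}\sin(\theta_n - \theta_a + \gamma)
              + K_{av}\sin(\theta_v - \theta_a)\\
\dot\theta_n &= \omega_n + K_{na}\sin(\theta_a - \theta_n - \gamma)
              + K_{nv}\sin(\theta_v - \theta_n)\\
\dot\theta_v &= \omega_v + K_{va}\sin(\theta_a - \theta_v)
              + K_{vn}\sin(\theta_n - \theta_v).
\end{aligned}
$$

$K_{ij}$ (rad/h) is the influence of region $j$ on region $i$; positive
coupling pulls phases together, negative coupling pushes them apart. The
NTS, which is bilateral in these slices, is treated as a single oscillator
(identical halves acting symmetrically on the AP). NTS–4Vep interactions
are taken as negligible, $K_{nv} = K_{vn} = 0$. The AN phase lag $\gamma$
is a phenomenological constant inside the AP–NTS interaction; without it
the locked AP–NTS phase difference could not take the observed values near
(and on either side of) zero.

What is observable is not the phases but their differences. With the
NTS–4Vep couplings zero, the model closes in the two phase differences
$\theta_{an} = \theta_a - \theta_n$ and $\theta_{av} = \theta_a - \theta_v$:

$$
\begin{aligned}
\dot\theta_{an} &= \omega_{an} - \tilde K_{an}\sin(\theta_{an} - \gamma)
                 - K_{av}\sin\theta_{av}\\
\dot\theta_{av} &= \omega_{av} - \tilde K_{av}\sin\theta_{av}
                 - K_{an}\sin(\theta_{an} - \gamma),
\end{aligned}
$$

with detunings $\omega_{ij} = \omega_i - \omega_j$ and total channel
couplings $\tilde K_{ij} = K_{ij} + K_{ji}$. `simulate_phases()` integrates
the first system, `simulate_pd()` the second; a property test holds them to
agree to $10^{-3}$ rad over 200 h.

Internally every phase is in radians; everything user-facing (phase
differences, periods) is in hours, with the conversion fixed at
$24/2\pi$ h/rad and phase differences wrapped to $(-12, 12]$ h.

### Global coupling and its decay

Slice preparation plausibly weakens inter-regional communication, and the
communication channels (neural for AP–NTS, likely paracrine for AP–4Vep)
may deteriorate at different rates. Both effects are modelled by
dimensionless control parameters multiplying each channel's couplings,

$$ s_i(t) = \max(s_{0,i} - c_i t,\; 0), \qquad i \in \{n, v\}, $$

either constant ($c_i = 0$) or decaying linearly to zero. $s = 1$
reproduces the fitted coupling strengths. The single-parameter bifurcation
analysis uses the special case $s_n = s_v = s$.

### Fitted parameters

The packaged defaults (`default_params()`, also shipped as
`inst/extdata/dvc_params.json`) are the fitted network means: intrinsic
periods $\tau_a = 25.7$ h, $\tau_n = 22.5$ h, $\tau_v = 23.4$ h; attractive
reciprocal AP–NTS coupling $K_{an} = 0.031$, $K_{na} = 0.041$ rad/h with
lag $\gamma = 0.770$ rad ($2.9$ h); repulsive AP–4Vep coupling
$K_{av} = -0.045$, $K_{va} = -0.007$ rad/h. Repulsive AV coupling together
with the small detuning produces the near-antiphase AV locking seen in the
data.

## Numerical choices

* **Integration.** Dormand–Prince 5(4) (`deSolve::rkMethod("rk45dp7")`)
  with `rtol = 1e-3`, `atol = 1e-6`, dense output interpolated onto a 1 h
  grid mirroring 1 h-binned recordings. Both tolerances and the grid are
  arguments.
* **Fixed points and the fold.** At a steady state the two sines solve a
  linear system: with $u = \sin(\theta_{an} - \gamma)$,
  $v = \sin\theta_{av}$,
  $A (u, v)^\mathsf{T} = (\omega_{an}, \omega_{av})^\mathsf{T} / s$ where
  $A = \begin{pmatrix}\tilde K_{an} & K_{av}\\ K_{an} & \tilde K_{av}\end{pmatrix}$.
  `fixed_points()` enumerates the four arcsine branch combinations and
  classifies each by the Jacobian eigenvalues (tolerance $10^{-9}$;
  marginal points are labelled `"fold/neutral"`). Because $u, v \propto 1/s$,
  the synchronised state exists down to
  $s_{\text{fold}} = \max(|U|, |V|)$ with $(U, V)$ the $s = 1$ solution —
  a closed form that replaces generic numerical continuation and doubles
  as an independent oracle for the gridded branch tracing in
  `continuation()`. For the default parameters
  $s_{\text{fold}} \approx 0.309$, and exactly one of the four fixed
  points at $s = 1$ is stable, at
  $(\theta^*_{an}, \theta^*_{av}) \approx (1.74, 10.93)$ h. Degenerate
  inputs with $\det A = 0$ raise an error naming the degeneracy; equal
  intrinsic periods are allowed (zero detuning gives
  $s_{\text{fold}} = 0$).
* **Finite-horizon classification.** `sweep_dynamics()` calls a run
  "locked" when the late-window drift rate of both unwrapped PDs falls
  below $10^{-3}$ rad/h. Just below the fold the ghost of the saddle-node
  produces plateaus lasting hundreds of hours, so over a finite horizon
  the classification boundary sits marginally below $s_{\text{fold}}$ —
  an honest property of finite recordings rather than a defect.

## The synthetic-data generator

No public recordings accompany the experimental work, so the package
generates its own. The observation model
(`make_bioluminescence()`) is the simplest map from phase to a
non-negative bioluminescence-like signal:

$$ B_i(t) = A_i\, e^{-t/\tau_d}\,\bigl(1 + \cos\theta_i(t)\bigr)
          + \text{trend}(t) + \varepsilon(t), $$

with amplitude damping time $\tau_d = 200$ h (multi-day signal decay), a
slow polynomial baseline and additive Gaussian noise
($\sigma = 0.05$ by default, i.e. 5% of the unit amplitude — high enough
SNR that ridge extraction is unambiguous). The defaults keep the trend well
below the 48 h detrending cutoff so the wavelet stage sees a clean
oscillation.

Ensembles (`make_ensemble()`) emulate the between-preparation variability
of the ex vivo cohort: 11 recordings by default, AP and 4Vep intrinsic
periods jittered with SDs 1.75 h and 2.03 h (the observed
between-preparation SDs), the NTS period held at its mean (it is by far the
least variable), and a schedule menu of constant couplings in $[0, 1]$ plus
linear decays reaching zero between 100 and 200 h. One ensemble seed fans
out to per-recording seeds, so every member is reproducible bit-for-bit
from its logged ground truth (`regenerate_recording()`).

What the generator does *not* emulate: single-cell heterogeneity and
desynchronisation within a region, amplitude–phase interaction, circadian
waveform asymmetry, and structured (non-Gaussian, autocorrelated)
measurement noise. Passing tests therefore demonstrate that the analysis
chain is internally consistent and recovers known ground truth under its
own observation model — not that it is robust to every pathology of real
bioluminescence data.

## The rhythm-analysis stage

Recordings are detrended by subtracting a Hamming-windowed sinc low-pass
(cutoff period 48 h, mirror-padded edges), then transformed with an
analytic Morlet continuous wavelet transform on a linear grid of 101
periods spanning 10–48 h. The Morlet base frequency is
$\omega_0 = 2\pi$, and power is normalised flat in amplitude — a
unit-amplitude sinusoid attains power $\approx 1$ with its maximum at its
own period. Two consequences of that normalisation are worth noting:

* the scale-to-period map is $\text{period} = \text{scale}\cdot 2\pi/\omega_0$
  (scale = period at $\omega_0 = 2\pi$), which is what centres the argmax
  on the true period under flat normalisation;
* the Morlet response to a sinusoid is Gaussian in scale, so log-power is
  locally parabolic — the ridge period is refined to sub-grid resolution by
  a three-point parabola through log-power, reducing the 0.38 h grid
  quantisation to well under 0.05 h.

The ridge (`extract_ridge()`) takes the per-time argmax of power; phase is
the argument of the complex coefficient on the ridge, unwrapped in time.
Points whose ridge period exceeds the local cone of influence (e-folding
time $\sqrt 2 \times$ scale from either edge) are kept but flagged, and all
averaged statistics exclude them. Phase differences between ridges are
wrapped to $(-12, 12]$ h with the convention that positive AN-PD and AV-PD
mean the AP peaks first. A noise-free round trip — simulate, render,
detrend, transform, ridge — recovers periods within 1% and phase
differences within 0.25 h away from the edges.

## Phase-difference metrics

* **Stability score.** The wrapped PD trace is binned into 96 fixed 15 min
  bins over $(-12, 12]$ h and scored by the modal fraction
  $y = \max_i h_i / \sum_i h_i \in [1/96, 1]$; a prominent single plateau
  gives $y$ near 1, uniform drift gives the floor.
* **Constant-PD segments.** A channel counts as locked wherever
  $|d\theta_{ij}/dt| < 0.01$ rad/h for at least 24 h. The derivative is
  taken on the unwrapped PD by centred differences after a 3 h
  moving-average — the threshold presumes a smooth derivative, and 1 h
  sampling is coarse enough that raw differences ripple; the 3 h window is
  a declared choice of this package. Each maximal qualifying run is
  reported with its mean PD $\theta^*$ and collective period $\tau^*$, the
  mean of the two regions' mean ridge periods over the run (their
  fractional mismatch should stay below 4%; `period_mismatch()` warns
  above it). Traces with several plateaus are flagged multistable and
  excluded from fitting (`select_fit_traces()` keeps the most stable
  unimodal traces), since it is ambiguous which plateau is the steady
  state.

## Closed-form coupling estimation

Each channel is fitted in isolation from its locked observables.

For AP–4Vep, the two-oscillator steady state gives
$\tilde K_{av} = \omega_{av}/\sin\theta^*_{av}$, and the collective
frequency while locked, $\Omega^*_{av} = 2\pi/\tau^*_{av}$, gives the
asymmetry $\Delta K_{av} = K_{va} - K_{av} =
2(\Omega^*_{av} - \langle\omega\rangle_{av})/\sin\theta^*_{av}$; the two
directed strengths follow. The inversion is singular at
$\theta^* \in \{0, \pm 12\}$ h and errors there.

For AP–NTS the lag adds one unknown, and
$(\tilde K_{an}, \gamma)$ pairs are degenerate given $\theta^*_{an}$ alone.
The relaxation rate breaks the degeneracy: a small perturbation decays at
$\lambda = -\tilde K_{an}\cos(\theta^*_{an} - \gamma)$, and combining this
with the steady state yields
$\tilde K_{an} = \sqrt{\lambda^2 + \omega_{an}^2}$ — an identity the
estimator satisfies by construction (guarded by a tautology test). The lag
follows on the stable branch,
$\gamma = \theta^*_{an} - \arcsin(\omega_{an}/\tilde K_{an})$ with
$\cos(\theta^*_{an} - \gamma) > 0$ consistent with $\lambda < 0$, and
$\Delta K_{an}$ from the collective frequency with
$\sin(\theta^*_{an} - \gamma)$ in the denominator. In the asymmetry
formulas the sine argument is always the channel's own plateau; the
estimators normalise $\Delta K$ as $K_{\text{AP}\to\text{partner}} -
K_{\text{partner}\to\text{AP}}$.

$\lambda$ itself is fitted by nonlinear least squares of
$y = a e^{\lambda t} + b$ (`minpack.lm`) to the unwrapped AN-PD. The fit
window is a deliberate design choice: it starts at the first sample within
0.2 rad of the plateau and runs *through* the plateau to the end of the
trace. Stopping at the detected plateau start would leave only the
large-amplitude part of the approach, where the sine nonlinearity makes
the local rate up to ~10% faster than the linearisation; the exponential
tail inside the "constant" segment is exactly the regime where the
linearised rate holds, and including it brings the fitted $\lambda$ within
about 2% of the linearisation in noise-free simulation. Degenerate fits
(amplitude $\approx 0$, window under 12 h, trace never approaching the
plateau) raise errors rather than returning numbers.

Two practical notes from the recovery experiments
(`run_channel_estimation()`): plateau observables are measured on a run
started at the locked state, because a run that locks mid-record carries an
approach tail into the detected segment that biases $\theta^*$ by
$\sim 0.1$ h; and $\lambda$ is fitted on the PD trajectory itself rather
than the wavelet-derived PD, because the relaxation time constant
($\approx 16$ h at the fitted parameters) lies below the wavelet's
$\sim 24$ h temporal support, which low-passes the transient.

`recouple()` reassembles the full three-oscillator model from the two
channel fits. The joint stable state shifts slightly relative to the
two-oscillator plateaus (the AV plateau moves from 10.17 h to 10.93 h); the
shift is reported rather than hidden.

Per-experiment estimates are averaged across recordings when an ensemble is
fitted (each recording yields its own observables), rather than estimating
once from averaged observables; both routes are available since the
estimators are plain functions of the observables.

## Problem sizes and scope

All shipped analyses run at desk scale: simulations of 150–400 h at 1 h
output, wavelet grids of 101 periods over 150–300 samples, ensembles of 11
recordings, continuation grids of a few hundred points. These sizes match
the ex vivo recordings the model emulates and keep every script and the
full test suite comfortably fast.

Out of scope by design: stochastic phase dynamics (the model is
deterministic; noise enters only through the observation model), networks
of more than three oscillators, single-cell lattices, and bifurcation
analysis in parameters other than the global coupling. The statistics of
the original 11 experimental recordings (per-experiment stability scores,
trajectory counts) cannot be reproduced without the unavailable raw data;
the ensemble study checks the qualitative menagerie instead.
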