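---
title: "Information processing capacity from event-related BOLD: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information processing capacity from event-related BOLD: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcmodel)
```

## The model

`ipcmodel` treats a single brain region as a lossless (or partially lossy)
information-handling unit. Information delivered to the region is either
taken for processing or held in an input store, which gives the
conservation law $c\,I(t) = I_p(t) + I_m(t)$, with $0 \le c \le 1$ the
retained fraction ($c = 1$: lossless). Writing the normalized neuronal
activity as both the utilization of the processing unit,
$x = H_p/p$, and the utilization of the store, $x = I_m/m$, and assuming
the capacities are constant over a short task (an adiabatic
approximation), differentiation of the conservation law yields a
first-order linear ODE:

$$\frac{dx}{dt} = -\frac{p}{m}\,x(t) + \frac{c}{m}\,H(t),$$

where

* $p$ — processing capacity, bit/s: the maximal information processing
  rate;
* $m$ — input storage capacity, bits: how much delivered information can
  wait for processing;
* $H(t)$ — information arrival rate, bit/s;
* $T_c = m/p$ — the circuit time constant, seconds.

A stimulus that delivers $\alpha$ bits effectively instantaneously is an
impulse $H(t) = \alpha\,\delta(t)$; the response is the abrupt-onset
exponential $x(t) = (\alpha/m)\,e^{-t/T_c}u(t)$, with $x(0^-) = 0$ and
$x(0) = \alpha/m$ (right-continuous jump). The model is an RC circuit
($R = m$, $C = 1/p$) and is algebraically identical to a single-region
dynamic causal model $\dot x = -\sigma x + \beta e(t)$ under
$\sigma = p/m$, $\beta = c/m$ (`sdcm_map()`, `sdcm_inverse()`).

### The two-state trial response

Event-related responses show an onset burst followed by delayed
inhibition (a clearing/negative-feedback signal) and, often, a smaller
secondary excitation. All components traverse the same circuit, so they
share the decay rate $k = p/m$:

$$x(t) = a\,e^{-kt}u(t) \;+\; c\,e^{-k(t-2T)}u(t-T_1)
  \;-\; b\,e^{-k(t-T)}u(t-T_0),$$

with $T$ the sampling period (TR, default 2.5 s). Note the convention:
$b$ and $c$ are amplitudes referenced at $T$ and $2T$ even when the
onsets $T_0, T_1$ differ from those times;
`two_state_onset_amplitudes()` converts to the physical jump sizes
$\beta/m$ and $\alpha_1/m$ at the onsets.

### Identifiability: everything is relative

With impulse inputs only the ratios $(a, k) = (\alpha/m,\ p/m)$ enter the
data, so absolute $p$, $m$, $\alpha$ are not identifiable and are never
reported. The derived quantities (`derive_capacities()`) are the relative
processing capacity $p/\alpha = k/a_{\mathrm{ref}}$, the relative storage
capacity $m/\alpha = 1/a_{\mathrm{ref}}$, and $T_c = 1/k$, where
$a_{\mathrm{ref}}$ is the fitted amplitude of a stated reference
condition — by default the Congruent condition, under the assumption that
its input information is the same across groups. Every report states the
reference cell (`capacity_table()$reference`).

## Forward model and the synthetic-data generator

BOLD is the convolution $y = x * h$ of the activity with a canonical
double-gamma hemodynamic response function,

$$h(t) = A\left[\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}
  {\Gamma(\alpha_1)} - c_r\,
  \frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}
  {\Gamma(\alpha_2)}\right],$$

with defaults $\beta_1 = \beta_2 = 1$ (so $\alpha_1, \alpha_2$ are the
response and undershoot delays in seconds; defaults 6 and 16),
$c_r = 1/6$, and $A$ chosen so the kernel's peak equals 1
("peak-normalized"; pass a numeric `A` for a raw scale). The kernel is
supported on $[0, 32]$ s (beyond which it is below $10^{-6}$ of peak for
the default shapes).

Simulation runs on a fine grid ($dt = 0.1$ s, 25 times the TR
resolution) with an exact one-step exponential propagator — the ODE is
linear with constant coefficients, so discretization error is not a
confound in recovery tests. Impulses are applied as right-continuous
jumps of $c\,\alpha/m$ at their (grid-snapped) times. Sampling takes
every TR-th fine sample; measurement noise is white Gaussian by default,
with an AR(1) option because trial-averaged fMRI noise is temporally
correlated.

`generate_paradigm()` emulates a flanker-style rapid event-related
design: 4 runs of 164 volumes at TR 2.5 s, each starting with a 10 s
fixation baseline, then 32 trials per condition (Congruent, Incongruent,
Neutral) per run at randomized onsets on TR multiples. That geometry
implies a mean onset-to-onset interval of
$4 \times 164 \times 2.5 / 384 = 4.27$ s; `paradigm_summary()` also
reports the mean gap between consecutive onsets, since "inter-stimulus
interval" is ambiguous between the two definitions.

`ground_truth()` fixes the generating parameters. Defaults, chosen once
as a realistic operating point: $k = 0.8$/s ($T_c = 1.25$ s, inside the
range implied by behavioural response times of 2–3 s at
$T_r/T_c \approx 2{-}2.6$); input information $\alpha_C = 1$ bit
(the unit of the relative scale), $\alpha_{IC} = 1.3$ bits — the
Incongruent condition carries a higher information load; inhibition of
$0.6\,\alpha$ at $T_0 = 2$ s and secondary excitation of $0.15\,\alpha$
at $T_1 = 5$ s; Neutral trials are generated but, like the study design
they emulate, not fitted. An `error_rate` option drops trials at random,
mimicking the exclusion of incorrect behavioural responses.

Two design modes matter for validation:

* **dense** (mean ISI 4.27 s): hemodynamic responses overlap
  heavily. A naive trial average of the raw signal then contains
  contamination from neighbouring trials (in the real pipeline this is
  removed upstream by overlap-correcting multiple regression at the
  voxel level, which is out of scope here). This mode is provided to
  study that design-induced bias, not for clean recovery.
* **isolated** (`min_isi_s` large, default tests use 65 s): one trial's
  neuronal response (~15 s) plus hemodynamic support (32 s) has fully
  decayed before the next trial's averaging window, so the trial average
  is an unbiased single-trial BOLD impulse response. Recovery and
  prediction-error claims are made in this mode; they quantify the
  inversion itself, not the upstream overlap correction.

What the generator does **not** emulate: physiological noise spectra,
scanner drift and motion (removed upstream in practice), spatial
structure/voxel heterogeneity, and behavioural variability beyond the
error-rate filter. Passing tests therefore validate the model and its
inversion, not the whole experimental pipeline.

## Inversion

The estimation chain mirrors the three-step procedure the model is
designed for:

1. **Deconvolution** (`deconvolve_ls()`): the neuronal response at TR
   resolution on $[0, \mathrm{support}]$ (default 15 s, i.e. 7 knots) is
   estimated from the sampled BOLD by least squares,
   $\min_x \|y - Cx\|^2 + \lambda\|x\|^2$. The operator $C$ carries the
   TR knots through natural-spline interpolation to the fine grid, the
   fine-grid causal convolution with $h$, and TR sampling — exactly the
   discretization of the forward model. (A convolution matrix built from
   $h$ sampled directly at the TR is first-order inconsistent with the
   continuous convolution — the abrupt onset sample alone carries an
   $O(\mathrm{TR})$ quadrature error — and cannot support noise-free
   round trips.) $\lambda = 0$ by default; if the normal equations are
   ill-conditioned (condition number above $10^{10}$ — e.g. a 7-point
   window, whose $t = 0$ sample carries no information because
   $h(0) = 0$), a fallback ridge $10^{-6}\,\mathrm{tr}(C^TC)/n$ is
   applied with a message.
2. **Spline upsampling** (`spline_upsample()`): natural cubic spline
   through the knots, evaluated at 0.1 s. Natural boundary conditions
   are the documented choice; they reproduce straight lines exactly but
   not general cubics.
3. **Two-state fit** (`fit_two_state()`, `fit_two_state_shared()`): for
   fixed $(k, T_0, T_1)$ the model is linear in $(a, b, c)$, so the
   amplitudes are profiled out by non-negative least squares at every
   onset pair — $T_0 \in [0, 2T]$, $T_1 \in [T, 4T]$, $T_0 \le T_1$, on
   a 0.1 s grid, scanned exhaustively with precomputed Gram entries and
   closed-form support enumeration. Ties in the scan break toward the
   earliest $(T_0, T_1)$. The remaining 1-D problem in $k$ is searched
   globally: a log-spaced sweep over $[0.01, 10]$ s$^{-1}$, a dense scan
   of the valley, and local refinement of the leading minima.
4. **Validation** (`predict_and_score()`): the fitted response is pushed
   back through the HRF and sampled; the mean squared error against the
   observed BOLD is the accuracy measure.

### Why the fit is finished in the BOLD domain

A natural spline through 2.5 s knots is a poor representation of
exponentials with $T_c \lesssim 2$ s, so a fit performed purely against
the upsampled deconvolved response inherits a systematic bias in $k$
(tens of percent for fast responses in our experiments). When the
observed BOLD and the HRF are available — always, in this pipeline —
`fit_two_state()` therefore refines all parameters against the BOLD
prediction error itself, the same criterion used for validation and HRF
selection. For noise-free data generated by the model family this makes
recovery exact; the deconvolved response remains the reported `x_est`.

### Near-degeneracy in $k$ and its regularization

The profiled objective in $k$ is a shallow valley that can contain
several deep, narrow dips: with free onsets, extreme delayed-component
amplitudes can compensate a wrong decay rate almost perfectly. Two
numerical policies deal with this:

* the search enumerates and refines all leading local minima of a dense
  valley scan rather than trusting a single golden-section descent;
* a Tikhonov penalty on the delayed amplitudes, relative to the primary
  component's energy, suppresses the pathological compensations. Its
  weight adapts to the data: a first pass at a numerical floor
  ($10^{-6}$) measures the minimized residual, and when that residual
  indicates noise, the weight is rescaled to $3\times$ the relative
  residual energy. Noise-free fits are thus essentially unpenalized
  (recovery to $\ll 1\%$), while noisy fits are stabilized in proportion
  to the noise.

Degenerate inputs: an identically zero response is rejected with an
error; an exactly cancelling event train yields the zero signal by
construction.

### Shared decay rate across conditions

Within a group the processing capacity is taken as constant across task
conditions, so `fit_two_state_shared()` fits the Congruent and
Incongruent responses with one shared $k$ (pooled objective) while
amplitudes and onsets remain condition-specific. The amplitude ratio
$a_{IC}/a_C$ then estimates $\alpha_{IC}/\alpha_C$ under the shared-$m$
assumption. Per-condition independent fits (`fit_two_state()` per
series) remain available for diagnostics.

### Fixed and flexible HRFs

`select_hrf()` runs the full inversion per candidate kernel shape and
keeps the minimal-MSE candidate. In *flexible* mode every dataset
selects its own kernel; in *fixed* mode the winner on a designated
reference dataset (conventionally the oldest group's Incongruent
response) is applied to all datasets. Because the response delay affects
the prediction much more than the undershoot delay, candidate grids over
$\alpha_1$ are the ones that matter.

## Group reporting

`average_series()` averages BOLD across regions/subjects *before*
fitting (the "overall performance" convention — averaging fits instead
is not equivalent and is not done). `capacity_table()` tabulates
$p/\alpha$, $m/\alpha$, $T_c$ and time-to-peak per group-by-condition
cell, always naming the normalization reference; with behavioural
response times it reports $T_r/T_c$ per cell and the descending $T_c$
ordering, optionally checked against an expected ordering. Cells with
anomalously low fitted activity (below half the most active cell by
default) are annotated — low activity may reflect an activation deficit
rather than high capacity — and the annotation is deliberately not an
interpretation.

## Numerical choices and validation scales

* Fine grid 0.1 s; HRF support 32 s; kernel peak normalization.
* Exact propagator for simulation; trapezoidal cumulative quadrature for
  $I_p$ (second-order, grid-consistent).
* Onset grids at 0.1 s; decay-rate bounds $[0.01, 10]$ s$^{-1}$.
* Conservation residuals are checked at $dt = 10^{-3}$ s, where the
  trapezoidal error is below $10^{-6}$ of the delivered bits for
  $k \le 2$/s.
* Validation problem sizes: 50 noise-free deconvolution round trips;
  20 random ground truths for end-to-end recovery ($k$ within 1%,
  amplitude ratios within 2%, achieved with two orders of magnitude to
  spare); 40 replicates for the noisy fit calibration (median $k$ error
  ~1% at 2% peak noise); 100 noisy replicates for the two-group
  capacity-ordering check (young $T_c = 1$ s vs old $T_c = 2$ s,
  recovered in at least 95%).

## Known limitations

* The naive trial average is biased in dense designs (see above); the
  package does not implement overlap-correcting regression.
* With 7-point impulse responses the decay rate is weakly identified
  under noise; pooling conditions (shared $k$), trials and subjects is
  the intended remedy, as is reporting $T_c$ at the group level.
* Capacities are constants per simulation (adiabatic assumption);
  time-varying $p(t), m(t), c(t)$ are out of scope.
* Single region only: no coupled multi-region networks, no stochastic
  dynamics inside the ODE, no nonlinear (Balloon-type) hemodynamics.
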