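# ipcmodel

Information-processing-capacity modelling of regional event-related BOLD
responses.

`ipcmodel` is for researchers who want to interpret the shape of a brain
region's event-related fMRI response in information-theoretic terms: how
fast the region processes arriving information (processing capacity
*p*, bit/s), how much it can buffer (input storage capacity *m*, bits),
and how quickly its activity therefore decays (time constant
*T<sub>c</sub> = m/p*, seconds).

## The model

The package treats a region as an information-handling unit obeying a
conservation law — delivered information is either taken for processing
or held in an input store, *c·I(t) = I<sub>p</sub>(t) + I<sub>m</sub>(t)*
with retained fraction *c* (lossless: *c = 1*). Identifying the
normalized neuronal activity *x(t)* with the utilization of both units
yields a first-order linear ODE:

```
dx/dt = -(p/m) x(t) + (c/m) H(t)
```

where *H(t)* is the information arrival rate (bit/s). A stimulus
delivering α bits at once is an impulse α·δ(t), giving the abrupt-onset
exponential *x(t) = (α/m)·e^(−t/T_c)·u(t)*. Event-related trials are
described by a two-state excitatory/inhibitory response sharing one
decay rate *k = p/m*:

```
x(t) = a e^{-kt} u(t) + c e^{-k(t-2T)} u(t-T1) - b e^{-k(t-T)} u(t-T0)
```

and measured BOLD is *y = x \* h* with a canonical double-gamma
hemodynamic kernel *h*, sampled at the TR. Only ratios are identifiable
from impulse inputs, so results are reported as relative capacities
*p/α = k/a* and *m/α = 1/a* against a stated reference condition, plus
*T<sub>c</sub> = 1/k*. The mapping σ = p/m, β = c/m connects the model
to the self-connectivity of a single-region dynamic causal model
(`sdcm_map()`).

The package provides the full loop:

* **Forward**: `simulate_ipc()` (exact exponential propagator),
  `hrf_kernel()`, `convolve_bold()`, `sample_and_noise()`;
* **Synthetic studies**: `generate_paradigm()` (flanker-style
  rapid event-related design, 4 × 164 volumes at TR 2.5 s, 32
  trials/condition/run, mean onset-to-onset interval 4.27 s),
  `ground_truth()`, `generate_subject()`, `trial_average()` (7-point
  impulse responses over 0–15 s);
* **Inverse**: `deconvolve_ls()` (least-squares hemodynamic
  deconvolution), `spline_upsample()` (natural cubic spline to 0.1 s),
  `fit_two_state()` / `fit_two_state_shared()` (exhaustive onset-grid
  scan with profiled non-negative amplitudes and a global decay-rate
  search, finished against the BOLD prediction error), `select_hrf()`
  (fixed/flexible kernels by minimal MSE), `derive_capacities()`,
  `predict_and_score()`;
* **Reporting**: `average_series()`, `capacity_table()`,
  `report_markdown()`, plus TSV/JSON readers and writers and a thin
  command-line wrapper in `inst/cli/ipcmodel.R`.

## Worked example

Simulate a two-condition study with known ground truth (k = 0.8/s, so
T<sub>c</sub> = 1.25 s; the Incongruent condition delivers 1.3× the
Congruent information), then invert it:

```r
library(ipcmodel)
design <- generate_paradigm(n_runs = 2, volumes_per_run = 410,
                            trials_per_condition = 8,
                            conditions = c("C", "IC"),
                            mode = "isolated", min_isi_s = 65, seed = 42)
truth <- ground_truth(ipc = ipc_params(p = 1, m = 1.25),
                      alpha = c(C = 1, IC = 1.3),
                      noise = noise_model("white", sigma = 0.01, seed = 1))
subj <- generate_subject(design, truth)

irfs <- lapply(c(C = "C", IC = "IC"), function(cond)
  trial_average(subj$bold, design, cond, window_s = 15))
round(irfs$C$values, 4)
#> [1]  0.0013  0.1497  0.6528  0.3009  0.0674  0.0142 -0.0196

xf <- lapply(irfs, function(y)
  spline_upsample(deconvolve_ls(y, hrf_params()), fine_dt = 0.1))
fits <- fit_two_state_shared(xf, y_list = irfs, hrf = hrf_params())
fits$C
#> <two_state_params> a = 0.7525, b = 0.3471, c = 0.1036, k = 0.6558 /s
#>   (T_c = 1.525 s), T0 = 1.90 s, T1 = 4.70 s
derive_capacities(fits$C, hrf = hrf_params())
#> <derived_capacities> p/alpha = 0.8715 /s, m/alpha = 1.329,
#>   T_c = 1.525 s, T_y = 5.1 s
fits$IC$a / fits$C$a     # recovered alpha_IC / alpha_C (true 1.3)
#> [1] 1.340728
predict_and_score(fits$C, hrf_params(), irfs$C)$mse
#> [1] 3.949825e-07
```

The 7-point vector is the trial-averaged BOLD impulse response of the
Congruent condition; the fit recovers the decay rate within the
uncertainty this noise level permits (a 7-point response identifies *k*
only weakly — noise-free, recovery is exact), the condition amplitude
ratio within ~3%, and predicts the observed BOLD with a mean squared
error of ~4·10⁻⁷ in peak-normalized units. With noise removed the same
pipeline recovers *k* to better than 0.1% and amplitude ratios to
machine precision (see `tests/testthat/test-acceptance.R`).

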