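# scdeconv

Sparse deconvolution of skin conductance through a three-compartment
physiological state-space model.

## The problem

Electrodermal activity (EDA) — measured as skin conductance (SC) in
microsiemens — is driven by brief bursts of sudomotor nerve activity.
Recovering that sparse autonomic (ANS) activation from a single noisy SC
channel, together with the person-specific sweat dynamics, is the core
problem for psychophysiology labs and wearable-device pipelines that use
EDA as an arousal readout.

`scdeconv` models SC with three compartments: duct sweat `x1` (filled by
impulsive activation `u`, cleared with rise time `tau_r`), surface sweat
from pore opening `x2` (fast decay `tau_p`; the *phasic* component), and
sweat diffused into the stratum corneum `x3` (slow decay `tau_d`; the
*tonic* component). In continuous time

    dx1/dt = -x1/tau_r + u(t)
    dx2/dt =  eta_p x1/tau_r - x2/tau_p
    dx3/dt =  eta_d x1/tau_r - x3/tau_d,      y = x2 + x3 + noise,

with `eta_p + eta_d = 1` (0.5/0.5 by default). The system is discretized
exactly at 4 Hz (zero-order hold). Estimation alternates:

- **E-step** — iteratively re-weighted fixed-interval smoothing that
  approximates a generalized-Gaussian sparsity prior (`p = 0.5`) on `u`,
  with the regularization weight chosen by windowed, SVD-based
  generalized cross-validation, and sub-threshold activations pruned;
- **M-step** — interior-point minimization of the expected complete-data
  negative log-likelihood over `(tau_r, tau_p, tau_d)` under the
  physiological constraints `tau_r >= 0.2 s`, `tau_p >= 2 tau_r`,
  `tau_d >= 15 tau_p` and Gaussian priors.

A simulator (`generate_bundle()`) reproduces the validation protocol —
sparse trains, clean compartment signals, Gaussian or pink noise at a
phasic-referenced SNR — and an evaluation module supplies reconstruction
R², component RMSE, activation amplitude error, and event-related
ROC/AUC against a stimulus schedule.

## Worked example

```r
library(scdeconv)

params <- physiological_params(tau_r = 2.0040, tau_p = 5.4545,
                               tau_d = 81.8175)
bundle <- generate_bundle(params, K = 800, n_impulses = 25,
                          snr_db = 25, seed = 1)
bundle
#> Synthetic SC bundle: K = 800 (200 s at 4 Hz), 25 impulses, 25 dB gaussian noise

fit <- deconvolve(bundle$observed, em_config(seed = 1))
fit
#> Skin-conductance deconvolution
#>   samples: 800 at 4 Hz (200 s)
#>   tau_r = 2.6239 s, tau_p = 5.2477 s, tau_d = 78.7162 s
#>   pulses: 49, R^2 vs observations: 1.0000
#>   converged: FALSE; first 30 s are burn-in

metrics_report(fit, bundle)
#> Deconvolution metrics
#>   R^2 vs clean truth: 0.9999
#>   R^2 vs observations: 1.0000
#>   pulses: 49
#>   RMSE (uS): total 0.008185, phasic 0.3021, tonic 0.3024
#>   tau errors (%): r 30.9, p 3.79, d 3.79
#>   amplitude error: 0.7767 uS/s
```

Reading the numbers: the reconstruction matches the noiseless ground
truth almost perfectly (R² 0.9999; the criterion of interest is
R² ≥ 0.98 at 25 dB), and the decay constants `tau_p`, `tau_d` come back
within a few percent. The pulse count (49 vs 25 true) includes noise
excursions that cleared the 0.25 uS/s activation floor — post-hoc
thresholding removes most. The rise time `tau_r` of the *unobserved*
duct compartment is only weakly identified at this record length and
noise level and tends to sit on its `tau_p / 2` bound; treat it as a
bound-constrained, order-of-magnitude estimate (see the methods
vignette, `vignettes/sc-deconvolution-methods.Rmd`, for the full
analysis). `converged: FALSE` means the iteration cap, not a failure:
the final EM phase creeps along a shallow valley.

## Command-line interface

```sh
inst/cli/scdeconv simulate   --out sim --seed 3 --K 800 --impulses 25 --snr 25
inst/cli/scdeconv deconvolve --in sim.csv --out fit --seed 3
inst/cli/scdeconv evaluate   --in fit --truth sim --out metrics.json
```
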