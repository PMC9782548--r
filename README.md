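# lowrankMRS

Low-rank Hankel denoising and quantitative evaluation of single-voxel
magnetic resonance spectroscopy (MRS) signals, for spectroscopists and
methods developers who want a self-contained, fully seeded testbed for
linear-predictability denoising of low-SNR ³¹P and ¹H free induction
decays (FIDs) — the regime of small-voxel, short-scan preclinical brain
studies.

## What it computes

A noiseless FID that is a sum of *K* damped complex exponentials
(one per resolvable metabolite resonance),

```
x_t = Σ_k a_k exp(iφ_k) exp((2πi f_k − π lw_k) t Δt),
```

has a Hankel embedding `H[i,j] = x[i+j]` (shape `W × (N−W+1)`,
`W = N/2` by default) of rank exactly *K*, while white noise spreads over
all singular values. The denoiser keeps the best rank-*r* approximation
`H̄ = Σ_{k≤r} σ_k u_k v_kᴴ` (Eckart–Young, via SVD; `r` = number of basis
metabolites: 13 for ³¹P, 16 for ¹H) and reconstructs a length-*N* FID
from the first row and last column of `H̄` (anti-diagonal averaging is
available as the Cadzow-style alternative).

Around that core the package provides:

* a synthetic generator emulating 9.4 T mouse-brain acquisitions
  (³¹P whole brain: 4096 points / 16,025.64 Hz, raw SNR ≈ 5;
  ¹H striatum: 2048 points / 4401.41 Hz, raw SNR ≈ 71; a stroke-like ¹H
  variant with attenuated metabolites and elevated lactate), with
  configurable peak tables and seeded white complex noise;
* a windowed linear-combination fitter (non-negative amplitudes, fitted
  zero/first-order phase, global shift and damping, polynomial
  baseline), per-metabolite Cramér–Rao lower bounds in %SD (999 = not
  detected), and the LCModel-convention SNR = (spectral maximum − baseline) /
  (2 × RMS residual);
* a Monte-Carlo harness producing paired raw-vs-denoised comparison
  tables (mean ± SD, % difference from raw, paired t-tests with
  sentinel filtering);
* text formats for FIDs (bit-exact round trip), peak tables and result
  tables, a YAML experiment configuration, an optional minimal
  NIfTI-MRS export, and a CLI (`mrsCLI()`, wrapped by
  `inst/cli/lowrankmrs.R`) with `simulate`, `denoise`, `fit` and
  `evaluate` subcommands.

## Worked example

```r
library(lowrankMRS)

acq <- AcquisitionParams("P31", n_points = 1024L)
tab <- defaultPeakTable("P31")          # 13 metabolites, PCr at 0 ppm
gt  <- synthesizeFID(tab, acq)
noisy <- addNoise(gt, sigma = 0.8, rng_seed = 7)

fit_raw <- fitSpectrum(noisy, makeBasis(tab, acq))
den     <- lowrankDenoise(noisy, DenoiseParams(r = 13))
fit_den <- fitSpectrum(den, makeBasis(tab, acq))

round(c(snr_raw = fittedSNR(fit_raw), snr_denoised = fittedSNR(fit_den)), 2)
#>      snr_raw snr_denoised
#>         4.77        11.43
round(rbind(raw = crlbPct(fit_raw), denoised = crlbPct(fit_den))[, 1:4], 1)
#>          PCr gamma-ATP alpha-ATP beta-ATP
#> raw      8.3      13.3       9.9     50.1
#> denoised 3.4       5.9       4.2    999.0
```

The noisy phosphorus spectrum sits at SNR ≈ 5; rank-13 denoising more
than doubles it, and the CRLBs (fit uncertainty, % of the estimated
amplitude) of the well-detected metabolites drop by more than half. The
broad, weak β-ATP resonance illustrates the flip side at this single
seed: its amplitude collapses in the denoised fit and is reported with
the conventional "not detected" sentinel 999, which downstream paired
statistics exclude pairwise.

A full paired experiment:

```r
cfg <- experimentConfig(tab, acq, target_snr = 5,
                        denoise = DenoiseParams(r = 13L))
exp <- runExperiment(cfg, n_replicates = 50, master_seed = 101)
summarizeExperiment(exp)[1, c("mean_raw", "mean_denoised", "pct_diff", "p_value")]
#>   mean_raw mean_denoised pct_diff      p_value
#> 1     4.72         14.01   196.97 7.904739e-25
```

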