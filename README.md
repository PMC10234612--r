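# llrfmri

Locally low-rank denoising and evaluation of fMRI time series.

## What this is for

As fMRI pushes to smaller voxels and faster sampling, zero-mean Gaussian
("thermal") noise from the MR detection chain comes to dominate each
voxel's temporal variance. Patch-based locally low-rank (LLR) denoising
— NORDIC-style — removes exactly the components of the data that cannot
be distinguished from thermal noise, without the loss of spatial
precision that smoothing incurs. This package is for methods
researchers who want to *evaluate* that claim quantitatively: it pairs a
complete implementation of the denoiser (and its standard comparators)
with a complex-valued fMRI phantom of known ground truth and the full
evaluation battery used in the denoising literature.

## The core method

For each position of a sliding cubic patch of side `k` (smallest `k`
with `k^3 >= 11 T`), the complex data form a Casorati matrix
`X ∈ C^(k^3 × T)`. After dividing out the parallel-imaging noise
amplification `g(x)` and a smooth per-volume phase estimate, all
singular values of `X` at or below

    tau(m, T, sigma) = E[ s_max of an m×T i.i.d. complex Gaussian(sigma) ]
                     ≈ sqrt(2) * sigma * (sqrt(m) + sqrt(T))

are set to zero (Monte-Carlo mean, 100 draws; `sigma` estimated from the
data by Marchenko–Pastur patch analysis or supplied). Overlapping patch
reconstructions are averaged, phase and g-factor restored. The
comparators are MPPCA (magnitude-domain patch PCA with
Marchenko–Pastur noise classification), Gaussian spatial smoothing (+1
and +1.5 voxel FWHM) and sliding-window temporal smoothing (9–10.5 s).

The evaluation battery: GLSQ task GLMs with AR(1)/ARMA(1,1)
prewhitening, FIR (TENT) deconvolution, calibrated global and local
spatial-ACF smoothness (FWHM), Monte-Carlo cluster-size thresholds,
tissue-wise normalized spectra, exhaustive leave-p-out FIR
cross-validation with R², and a local-perturbation-response probe.
See `vignettes/thermal-noise-denoising.Rmd` for the science and every
modeling choice.

## Worked example

```r
library(llrfmri)

# a pure-noise complex phantom with spatially varying g in [1, 2]
spec <- phantom_spec(grid_dims = c(32, 32, 12), n_volumes = 120,
                     n_runs = 1, sigma_thermal = 1,
                     baseline = c(background = 0, csf = 0, gm = 0, wm = 0),
                     task_amplitudes = list(target = c(target = 0,
                                                       nontarget = 0)),
                     physio = list(), spont = NULL, drift_amp_pct = 0,
                     g_params = list(g_min = 1, g_max = 2, fwhm_vox = 12))
sim <- simulate_run(spec)
res <- nordic_denoise(sim$series, g = sim$truth$g_map)
res
#> <denoise_result> sigma_hat = 1, threshold = 66.46, mean rank = 0.49

rmap <- removed_noise_map(sim$series, res$denoised)
cor(as.vector(rmap), as.vector(sim$truth$g_map))
#> [1] 0.9601941
```

The estimated noise sd matches the simulated truth (1.0), the denoiser
retains on average half a component per patch (there is nothing but
noise to keep), and the map of what was removed correlates at r = 0.96
with the g-factor map — noise removal without anatomical structure.
On task phantoms the same pipeline raises the Target-ROI mean
t-statistic from ≈ 6 (standard) to well above the +1-voxel-smoothing
comparator while increasing residual smoothness by < 10% (vs ≈ 90% for
+1.5-voxel smoothing); the numbered scripts under `analysis/` print
those tables and write them to `results/`.

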