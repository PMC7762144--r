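# specratio

Compare how spectral power is distributed across frequency bands in
multivariate stationary time series — even when the number of components
differs between the series being compared.

The motivating setting is epoch-based analysis of multi-electrode brain
recordings (EEG, local field potentials): each epoch is modeled as a
stationary multivariate process, latent sources are extracted per epoch, and
the number of sources changes from epoch to epoch. Entrywise spectral
comparisons are then undefined, but the *proportion* of spectral power in a
band is not.

## The statistic

For a d-variate stationary epoch with spectral matrix f(ω), define the band
power and the **FS-ratio** (frequency-specific spectral ratio)

    r(a,b) = ∫ₐᵇ ‖vec f(ω)‖₂² dω ,        R(a,b) = r(a,b) / r(0,π) ,

a scalar in (0, 1) that is blind to d. The package provides:

- **Spectral estimation** — kernel-smoothed periodogram matrices
  f̂(ω) = (2π/T) Σⱼ K_h(ω − ωⱼ) I(ωⱼ) with periodic (circular) smoothing,
  plus squared coherence and pre-whitening utilities.
- **FS-ratio** and its population oracle for analytic spectra.
- **Scan statistic** λ̂ₐ = 1 − r̂(0, a−Δ)/r̂(0, a) over a frequency grid,
  with automatic discovery of power-carrying bands (excess over the exact
  flat-spectrum profile) and a multiscale consensus across Δ values.
- **Equality test** for two epochs of equal dimension: L2 discrepancy
  D̂ = ∫ₐᵇ ‖vec(f̂_X − f̂_Y)‖₂² dω standardized by plug-in estimates of its
  null mean and variance (kernel constants A_K, B_K), one-sided normal
  p-value.
- **Stationary block bootstrap** percentile confidence intervals for the
  FS-ratio, with automatic (flat-top rule) block-length selection.
- **Simulators** — AR(2)/VAR fixtures and a two-regime multi-epoch benchmark
  whose latent dimension switches from 3 to 2 midway.
- **Pipeline + CLI** — epoch-wise traces over manifest-listed CSV files,
  pre/post group summaries and band rankings; a thin command-line wrapper in
  `exec/specratio`.

## Worked example

Eight epochs of the bundled two-regime benchmark: the first three are
trivariate with spectral power near normalized frequencies 0.22–0.33, the
rest bivariate with a resonance at 0.12. The FS-ratio tracks the change
through the dimension switch:

```r
library(specratio)
set.seed(42)
epochs <- lapply(1:8, function(i) example_epoch(i, n_epochs = 8, n_time = 1000))
bands <- list(peak = frequency_band(0.10, 0.14, unit = "normalized"),
              mid  = frequency_band(0.20, 0.35, unit = "normalized"))
run <- run_epochs(epochs, bands,
                  config = list(scan = FALSE, n_replicates = 200,
                                block_length = 50, seed = 1))
cbind(d    = run$epoch_dims,
      peak = round(run$traces$peak$epoch_values, 3),
      mid  = round(run$traces$mid$epoch_values, 3))
#>      d  peak   mid
#> [1,] 3 0.003 0.793
#> [2,] 3 0.003 0.798
#> [3,] 3 0.002 0.846
#> [4,] 2 0.796 0.002
#> [5,] 2 0.658 0.002
#> [6,] 2 0.696 0.001
#> [7,] 2 0.604 0.003
#> [8,] 2 0.678 0.002
```

Despite the epochs living in different dimensions, the traces are directly
comparable: at the regime switch the proportion of power in the 0.10–0.14
band jumps from ~0.003 to ~0.68, while the 0.20–0.35 band collapses from
~0.81 to ~0.002. Group summaries quantify the change (bootstrap interval
endpoints pooled per group):

```r
group_summary(run$traces$peak, list(pre = 1:3, post = 4:8))
#>   group band n    mean  median       sd ci_lower ci_upper
#> 1   pre <NA> 3 0.00273 0.00286 0.000259  0.00176  0.00661
#> 2  post <NA> 5 0.68644 0.67791 0.070373  0.43188  0.80852
```

The equality test (same dimension required) separates a bivariate VAR(1)
from a process with an AR(2) resonance inside the tested band:

```r
set.seed(7)
x <- simulate_var(list(matrix(c(0.5, 0.1, 0.1, 0.5), 2, 2)), NULL, 2048)
y <- epoch_series(cbind(simulate_ar2(ar2_spec(1.25, -0.75), 2048),
                        simulate_ar2(ar2_spec(1.25, -0.75), 2048)))
spectral_equality_test(x, y, frequency_band(0.1, 0.2, unit = "normalized"))
#> 	L2 spectral matrix equality test (normal approximation)
#> data:  two 2-variate epochs of length 2048
#> z = 50.084, p-value < 2.2e-16
```

Closed-form spectral peaks of the benchmark's AR(2) processes
(`ar2_peak_frequency`, normalized scale):

```r
sapply(list(c(1.25, -0.75), c(-0.8, -0.7), c(0.25, -0.75)),
       function(p) ar2_peak_frequency(ar2_spec(p[1], p[2])))
#> [1] 0.1199539 0.3307202 0.2267068
```

## Command line

```sh
exec/specratio simulate-example1 --out data/ --epochs 600 --samples 1000 --seed 1
exec/specratio run --manifest data/manifest.yaml --out results/ --replicates 500
exec/specratio scan --epoch data/epoch_0301.csv --out profile.csv
exec/specratio eqtest --epoch-x a.csv --epoch-y b.csv --band 0.1,0.2 --out eq.json
exec/specratio summarize --trace results/trace_Beta.csv --split 300 --out summary.csv
```

See the vignette (`vignettes/spectral-power-ratios.Rmd`) for the model,
estimator conventions, design decisions and known limitations.
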