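# vbpbb

Isolate and test periodically correlated (PC) mean components of a
daily time series with a bandpass-filtered, period-aligned block
bootstrap.

Environmental exposure records — the motivating case is 16 years of
daily mean PM2.5 for a single city — carry periodic mean structure on
several scales at once: an annual cycle and its harmonics, and a
workweek rhythm, all buried in strongly autocorrelated noise. The
quantity of interest at a period *p* is the periodic mean
μ_j = E[X(t) | t mod p = j], j = 0, …, p−1, with a confidence band
that says whether the variation across phases is real.

The package implements the **variable bandpass periodic block bootstrap
(VBPBB)**: each component of interest is first isolated with a
Kolmogorov–Zurbenko Fourier Transform (KZFT) bandpass filter

    KZFT_{m,k,ν}(t) = Σ_s a_s^{k,m} · X(t+s) · e^{−i2πνs} ,

(a k-fold iterated moving average of odd window m, demodulated at the
centre frequency ν), then bootstrapped with blocks of length equal to
its period, aligned on phase — the generalized seasonal block bootstrap
(GSBB) scheme — so every resampled observation keeps its phase in the
cycle. The band between the phase-wise 2.5th and 97.5th percentiles of
B = 1000 bootstrapped periodic means is the 95% CI band; a component is
significant when the band excludes every flat periodic mean (zero lies
strictly inside the range of its upper bound and inside the range of
its lower bound). Because the filter removes noise and unrelated
frequencies *before* resampling, VBPBB bands are many times narrower
than the GSBB bands obtained from the raw series, which is what makes
weak but real periodicities detectable. A synthetic-data generator
with known periodic structure (`simulate_series()`) backs all of this
with ground truth.

## Worked example

Sixteen synthetic years of daily data with six planted periodic
components (periods 365, 183, 122, 20, 13, 7 days) in red AR(1) noise,
run through the full pipeline at the standard filter windows:

```r
library(vbpbb)

sim <- simulate_series(example_study_spec(seed = 1))
cfg <- bootstrap_config(B = 1000, alpha = 0.05, seed = 1)
res <- run_vbpbb(sim$series, default_plans(), cfg)
print(summary_table(res), digits = 3)
#>         label period frequency upper_min upper_max lower_min lower_max
#> 1      annual    365   0.00274    -0.547     0.851    -0.812     0.540
#> 2 half_annual    183   0.00548    -1.950     2.003    -2.024     1.941
#> 3  tri_annual    122   0.00822    -0.758     0.873    -0.872     0.750
#> 4   every_20d     20   0.05000    -0.165     0.220    -0.220     0.164
#> 5   every_13d     13   0.07692    -0.187     0.226    -0.227     0.186
#> 6      weekly      7   0.14286    -0.849     0.949    -0.869     0.932
#>   significant
#> 1        TRUE
#> 2        TRUE
#> ...
```

One row per tested period: the range over phases of the band's upper
and lower bounds, and the zero-straddle verdict. Every planted
component is detected; the band ranges scale with the planted
amplitudes (±2 for the semi-annual term, ±0.2 for the weak 20- and
13-day terms).

How much the bandpass step buys over bootstrapping the raw series:

```r
base <- run_gsbb_baseline(sim$series, 7, cfg)
compare_bands(base, res$weekly$band, label = "weekly")
#> <band_comparison> [weekly] median baseline/VBPBB width ratio: 28.571
```

The GSBB band at the weekly period is ~29× wider than the VBPBB band —
the raw series' noise, seasonal cycle, and harmonics all end up in the
GSBB band's variability, swamping a weekly signal that the filtered
band resolves cleanly. Bands carry a calendar anchor for labelling:

```r
res$weekly$band
#> <ci_band> period p = 7, 95% percentile band from B = 1000 resamples (730 cycles)
#>   upper bound range: (-0.8492, 0.9489)
#>   lower bound range: (-0.8686, 0.9315)
#>   phase 0 anchored at 2001-12-31
```

`write_band()` exports phase-indexed CSV (weekday-labelled for p = 7),
`sum_components()` combines the significant components into one band,
and `inst/cli/vbpbb.R` wraps simulate/periodogram/run/compare for shell
use. See the vignette (`vignettes/vbpbb-methods.Rmd`) for the model,
parameter guidance, and known limitations — including why a
*significant* verdict for a weak component should be read with care
while a *non-significant* one is trustworthy.

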