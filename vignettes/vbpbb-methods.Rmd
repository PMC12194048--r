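---
title: "Bandpass periodic block bootstrap: model, choices, and limitations"
author: "vbpbb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bandpass periodic block bootstrap: model, choices, and limitations}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbpbb)
```

## The problem

A daily environmental series such as urban PM2.5 is *periodically
correlated* (cyclostationary): its mean repeats on several scales at
once — a seasonal cycle, its harmonics, and a workweek rhythm — buried
in strongly autocorrelated noise. The quantity of interest is the
**periodic mean** at a period $p$: the vector of phase means
$\mu_j = \mathrm{E}[X(t) \mid t \bmod p = j]$, $j = 0,\dots,p-1$,
together with an uncertainty band that tells us whether the periodic
variation is real or compatible with a flat mean.

A block bootstrap with period-aligned blocks (the generalized seasonal
block bootstrap, GSBB, with block length equal to the period) gives
valid resamples of a periodically correlated series, but applied to the
raw series it resamples *everything*: noise, trend, and every other
periodic component inflate the confidence band at the period under
study. The variable bandpass periodic block bootstrap (VBPBB)
interposes a bandpass filter: each periodically correlated component is
isolated at its own frequency before resampling, so its band reflects
only the variability relevant to that component.

## The KZFT bandpass filter

The Kolmogorov–Zurbenko (KZ) filter of window $m$ (odd) and iteration
$k$ is the $k$-fold iterated simple moving average,

$$ KZ_{m,k}(t) = \sum_{s=-k(m-1)/2}^{k(m-1)/2} a_s^{k,m}\, X(t+s), $$

whose weights $a_s^{k,m} = C_s^{k,m} / m^k$ come from the polynomial
$(1+z+\cdots+z^{m-1})^k$. Its Fourier-transform variant (KZFT) inserts
a complex demodulation $e^{-i 2\pi\nu s}$ into the sum, converting the
low-pass KZ into a bandpass centred at frequency $\nu$ with transfer
magnitude

$$ \left| \frac{\sin(\pi m \Delta\nu)}{m\,\sin(\pi \Delta\nu)} \right|^k,
   \qquad \Delta\nu = \nu' - \nu , $$

the Dirichlet kernel raised to the $k$-th power: unit gain on the
target frequency, zeros at offsets that are multiples of $1/m$. A real
cosine of amplitude $A$ in the passband appears in the complex output
as a phasor of modulus $A/2$; `reconstruct()` doubles the real part to
recover the one-sided spectrum, so the real component comes back at
full amplitude.

Implementation notes:

* `kz_coefficients()` accumulates the polynomial coefficients by exact
  shift-and-add; they are integers over $m^k$ with no convolution
  roundoff (exact while $m^k < 2^{53}$).
* `apply_kzft()` uses demodulate–filter–remodulate, which equals the
  direct sum exactly; the modulation phase is reduced modulo $2\pi$ so
  trigonometric arguments stay small over decades-long series. The
  single-pass convolution with the order-$k(m-1)+1$ weight vector is
  mathematically identical to $k$ iterated moving-average passes but
  needs only one round of edge bookkeeping. The degenerate window
  $m = 1$ bypasses demodulation entirely (the filter is the identity),
  which keeps the GSBB-reduction property below exact to the last bit.
* **Edges.** No shrinking windows and no padding: the $k(m-1)/2$
  positions at each end where the full window does not fit are marked
  invalid and excluded from everything downstream. Truncation costs
  data but introduces no bias at cycle boundaries.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $\nu$ | centre frequency (cycles/day) | $1/p$ | the component under study |
| $m$ | window length (days, odd) | smallest odd $\ge 3p$ | $3$ cycles per window separates neighbouring candidate frequencies while keeping $5844 - (m-1)$ usable days; the six standard plans use the study windows 1095/741/729 instead |
| $k$ | KZ iterations | 1 | each extra iteration multiplies the edge loss by $(m-1)/2$ days; $k=1$ suffices when the passband already excludes interfering frequencies |
| $B$ | bootstrap resamples | 1000 | stable 2.5th/97.5th percentiles |
| $\alpha$ | band level | 0.05 | the conventional 95% band |

When $\nu m$ is not an integer the filtered signal suffers a phase
shift and loses fidelity. `kzft_spec()` records this condition in its
`nu_m_integer` flag rather than refusing: two of the six standard plans
(periods 20 and 13, and the weekly window 729) violate it by
construction of "smallest odd multiple of the period", and the package
reproduces those windows as given.

## Bootstrap and significance

`gsbb_resample()` concatenates whole cycles drawn uniformly with
replacement from the phase-0 block starts $0, p, 2p, \dots$ With block
length equal to the period, every admissible start is a phase-0 start,
so this is the general seasonal scheme without loss; each output
position inherits a source position of identical phase, which is what
preserves the periodic correlation structure. Choices worth knowing:

* a trailing partial cycle ($n \bmod p \neq 0$) is dropped before
  resampling so all blocks are full length — at 16 years of daily data
  and $p \le 365$ that discards under one cycle;
* phase 0 is anchored at the first valid (possibly filter-truncated)
  observation, and the band reports that calendar date so phases can be
  labelled by weekday or month;
* empirical quantiles use the inclusive linear-interpolation convention
  (type 7), stable at the 2.5/97.5 percentiles for $B = 1000$;
* bands are a pure function of (series, $p$, $B$, $\alpha$, seed); each
  component in a multi-component run gets its own deterministic seed
  via `derive_seed()`, implementing the premise that components at
  different frequencies are independent — `sum_components()` relies on
  the same premise when it resamples each component independently and
  adds the tiled periodic means.

A component is **significant** when its band excludes every flat
(constant) periodic mean: zero must lie strictly inside the range over
phases of the band's *upper* bound and strictly inside the range of the
*lower* bound. Equivalently, some phase's interval sits wholly below
zero and some other phase's wholly above — a constant could not do
both. No multiple-testing correction is applied across tested periods;
verdicts are per period.

The GSBB baseline (`run_gsbb_baseline()`) mean-centres the raw series
before resampling so its band lives on the same zero-anchored scale as
the filtered components; with the identity window ($m=1$, $k=1$) the
VBPBB pipeline then reduces to exactly twice the GSBB band — the factor
2 is the one-sided reconstruction convention, and the equality is exact
to the last bit under a shared seed, which the test suite asserts.

## What the synthetic generator emulates — and what it does not

`simulate_series()` builds `trend + periodic components + AR(1) noise`,
with the noise initialized from its stationary distribution so there is
no burn-in transient. `example_study_spec()` fixes the study
conditions used throughout the tests and the acceptance script: 5844
daily values (16 years), six cosine components at periods
365/183/122/20/13/7 days with amplitudes 0.7/2.0/0.8/0.2/0.2/1.0, a
slight trend, and AR(1) noise ($\varphi = 0.7$, innovation sd 2,
marginal sd $\approx 2.8$) so that no single component is visible to
the eye on a daily scale — the semi-annual term strongest and the
sub-monthly terms weak, as in urban PM2.5 records.

The generator deliberately omits features of real exposure data:
long-memory or seasonally varying noise, amplitude drift across years,
heteroskedasticity, measurement-model artifacts, and missing values
(the methods assume a complete series, and `read_series()` rejects gaps
rather than imputing). Passing tests on this generator demonstrate the
machinery — filter fidelity, phase-preserving resampling, band
reproducibility, width ordering — not that AR(1) is an adequate noise
model for any particular pollutant. Non-integer periods (e.g. 182.5)
are allowed in generation to mirror harmonics of an annual cycle; only
the bootstrap requires an integer period, and the harmonic plans use
the conventional discretizations 183 and 122. Square and sawtooth
waveforms exist to exercise what a single band cannot capture: their
energy deliberately leaks into harmonics outside the passband.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as
follows: coverage of the 95% band uses 200 replicates of a 6-year
(n = 2184) weekly cosine in AR(1) noise with $B = 500$; the
false-positive/power experiment uses the same design with amplitudes 0
and 2; the band-width comparison uses 20 replicates of the full 16-year
three-component design with $B = 1000$. Filter fidelity and coefficient
checks are deterministic and run at the study windows (up to
$m = 1095$).

## Known limitations

* **The significance rule is anti-conservative on pure noise.** The
  filter passes the phase-mean amplitude at the centre frequency
  unchanged (unit gain), but narrows the band: resampling cycles of a
  bandpass-filtered series treats cycles as exchangeable although the
  filter has correlated them over $m$ days, so the band's halfwidth
  understates the sampling variability of the phase-mean amplitude by
  roughly $\sqrt{m/p}$. A Rayleigh-amplitude argument gives a
  false-positive probability of roughly $\exp(-1.92\,p/m)$ for the
  zero-straddle rule on white-ish noise — around half at the default
  $m = 3p$ and approaching 1 at the study's $m = 729$ for $p = 7$ — and
  the acceptance experiment measures exactly this inflation
  (`type1_error_pct`). The practical reading: a *non-significant*
  verdict is strong evidence of flatness, while a *significant* verdict
  for a weak component should be corroborated (e.g. against the
  periodogram power and the GSBB band). Power at realistic amplitudes
  is excellent, and the band-width narrowing relative to GSBB — the
  method's main point — is unaffected.
* Band coverage of the true periodic mean is near nominal for the
  unfiltered period-aligned bootstrap (the acceptance experiment
  measures it at about 95%); the same caveat as above applies to
  coverage of a *filtered* component's band.
* The filters require a complete, equally spaced series; there is no
  missing-data mechanism.
* $m$ and $k$ are taken as given; the package does not search for
  optimal filter arguments.
* GSBB variants with block length different from the period, and
  studentized or bias-corrected intervals, are out of scope.
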