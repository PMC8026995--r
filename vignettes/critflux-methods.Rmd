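---
title: "Methods: dynamic measures and critical-temperature profiling in critflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic measures and critical-temperature profiling in critflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`critflux` analyses uniformly sampled voltage recordings of extracellular
ionic fluxes taken across a bath-temperature sweep, and localises the
temperature at which the dynamics are most regular — the critical
(physiological) temperature — by fitting Lorentzian resonance curves to
inverse dynamic measures. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
generator does and does not emulate.

## Signal model and preprocessing

A recording is a voltage series x(t) in microvolts at a fixed sampling
rate (4.1 Hz in the emulated design, 5000 samples per series). Electrode
drift contaminates the lowest frequencies, so every measure is computed on
a detrended series. Three modes are exposed because all three are common
pre-steps for scaling analyses:

* `mean` — subtract the mean;
* `linear` (default) — remove the global least-squares line; the safest
  choice against slow monotone drift and the default for every
  `measure_series()` call;
* `piecewise_linear` — independent least-squares lines over contiguous
  non-overlapping windows (default 500 samples, i.e. ten windows over a
  5000-sample series). A trailing partial window is detrended by extending
  the final full window's fitted line, which keeps the operation
  idempotent.

Which variant is "right" for a given instrument is an open question; all
measures record the mode used. Input files are rejected if any time step
deviates from the median step by more than 1% — the measures below all
assume uniform sampling.

## Spectral signature

β is the negated ordinary-least-squares slope of log₁₀ power versus log₁₀
frequency. The spectral density is a Welch estimate: 8 segments at 50%
overlap, Hann taper, per-segment demeaning. With one segment the estimator
reduces to the plain periodogram, for which the one-sided spectrum
satisfies Parseval's identity exactly (the test suite checks this to 1%).
The default fit range drops the three lowest nonzero bins — detrending
suppresses them — and the top octave, where the taper rolls off. Both the
segment count and the range are configurable; the fitted range and the
number of bins used are recorded in the returned object. The estimator is
exactly invariant under positive rescaling of the series, and across
exponents 0–2 at N = 5000 its bias is below 0.05 (property-tested with
60–100 seeds per exponent).

## Rescaled-range family

For one block, R/S is the range of the mean-adjusted cumulative sum over
the block standard deviation. The standard deviation uses the population
convention (divide by n), recorded in the output. Five exponents are
reported:

* *empirical* — OLS slope of log₁₀ mean R/S against log₁₀ block size;
* *theoretical* — the same regression applied to the analytic expectation
  of R/S for i.i.d. data (Anis–Lloyd with the (n − ½)/n finite-size
  prefactor; exact gamma form below n = 340, Stirling asymptote above). It
  depends only on the block sizes, not the data, and approaches ½ as all
  blocks grow;
* *corrected R/S* — regression of R/S − E[R/S] + √(πn/2), which removes
  the small-sample bias (mean 0.5 ± 0.03 on a white-noise null, 100
  seeds);
* *corrected empirical* — empirical minus (theoretical − ½), the
  shift-by-expectation convention;
* *simple* — the two largest dyadic scales only.

The default block sizes follow the classical divisor scheme: the analysis
length is the value in [0.99 N, N] with the most divisors between 50 and
half itself, and those divisors are the block sizes, so each size tiles
the trimmed series exactly. For N = 5000 this gives 20 sizes from 50 to
2475 and a theoretical exponent of 0.5301. The scheme is configurable;
because the theoretical exponent is a function of the block set alone,
changing the scheme changes that reference value, which is why the block
sizes are always recorded in the output. DFA (`dfa_alpha`) is provided as
a covariate check with 12 log-spaced scales from 8 to N/8 by default.

## Delay embedding and its parameters

The embedding delay is chosen two ways and both are recorded, since the
conventional choices differ and neither is canonical:

* `acf_delay` — first lag at which the sample autocorrelation falls below
  1/e (a first-zero-crossing rule is available as an option);
* `ami_delay` — first strict local minimum of the average mutual
  information, estimated with a 16-bin equal-width joint histogram. If no
  local minimum exists below `max_lag`, the ACF delay is used with a
  warning. On noiseless periodic signals the binned AMI flattens into a
  plateau around the quarter period; the first strict local minimum then
  sits at the front of that plateau rather than at its centre, which is
  acceptable for embedding purposes (any delay in the plateau decorrelates
  the coordinates).

The embedding dimension uses Kennel's false-nearest-neighbour criteria
with the standard thresholds: a neighbour is false when the extra
coordinate inflates its distance by a factor above 10, or pushes it past
twice the attractor size; the smallest dimension with under 2% false
neighbours wins, capped at `max_dim` (default 12) with a warning — noise
never embeds, so the cap with a warning is the designed behaviour for
stochastic series. The Theiler window defaults to the delay in use. By
default the AMI delay feeds the embedding (`which_delay = "ami"`); the ACF
variant is one switch away and both delays appear in every measure table.

## Largest Lyapunov exponent

`max_lyapunov` implements the Rosenstein mean-divergence method, robust
for short noisy series: each point's nearest Euclidean neighbour outside
the Theiler window is tracked forward, and the mean log distance after k
steps is regressed on k over `fit_range` (default steps 1–10; always
recorded). The slope is the exponent per sample; the per-second value is
the slope times the sampling rate. Both are reported because the natural
unit depends on the downstream use. Two numerical details matter:

* the averaged pair set is fixed in advance (only points trackable for all
  `n_steps` participate), so the curve cannot drift simply because pairs
  enter or leave the average;
* distances are floored at 10⁻¹⁰ of the attractor scale. Noiseless
  periodic orbits revisit states to machine precision; without the floor,
  those ~10⁻¹⁶-scale distances dominate the log averages and produce a
  spurious nonzero slope. With it, a sampled sine yields |λ| < 0.01 per
  sample and the logistic map at r = 4 yields ln 2 within 0.05.

For stochastic series the "exponent" is not a Lyapunov exponent in the
dynamical-systems sense; it is reported as a descriptive divergence rate,
which is how it enters the criticality profile.

## Approximate and sample entropy

Both use Chebyshev distance and template length m = 2 with tolerance
r = 0.2 × SD of the detrended series — the standard convention for
physiological series; both parameters are configurable and stored with
every result. Approximate entropy includes self-matches (Pincus); sample
entropy excludes them (Richman–Moorman) and is the primary channel here
because it is less length-dependent and exactly zero for strictly
repeating signals. With relative tolerance both statistics are invariant
under affine transforms of the signal. A constant series has no defined
relative tolerance and raises an error; passing an absolute tolerance
(`r_type = "absolute"`) instead returns 0 for the constant series. When no
length-(m+1) template pair matches, sample entropy is undefined: the
function returns `Inf` flagged as a sentinel rather than throwing, so a
sweep table stays rectangular and the profiling stage can drop the cell
(`build_profile` counts exclusions). The C++ kernels enumerate candidate
pairs through a value-sorted index on the first template coordinate, which
cuts the O(N²) constant by roughly an order of magnitude without changing
any count; the test suite pins both statistics to exhaustive
template-counting oracles at 10⁻¹⁰.

## The criticality model

The core fitted object is the four-parameter Lorentzian

y(T) = y₀ + A γ² / ((T − T_c)² + γ²),

with free baseline y₀ — inverse-entropy profiles do not fall to zero at
the sweep edges, so a three-parameter peak would bias γ. γ is reported as
the half-width at half-maximum of the peak above baseline (FWHM = 2γ is
also emitted), a declared convention recorded in every fit. Fitting is
Levenberg–Marquardt (`minpack.lm`) from five deterministically jittered
starts seeded by the data (peak location, minimum, half-maximum span);
the best residual wins. Deterministic jitters keep the fit reproducible
and exactly translation-equivariant in T. Goodness of fit is reported as
R² = 1 − SS_res/SS_tot and as `y_error`, the RMS residual after
range-normalising the channel to [0, 1]. Fits with R² < 0.5 trigger a
weak-resonance warning: with 15 temperatures a four-parameter Lorentzian
overfits pure replicate noise to R² around 0.2, while genuine resonances
in this design sit well above 0.7.

`localize_tc` composes a channel transform with the fit: 1/S_s and 1/S_a
(entropy dips at T_c, so the inverse peaks), −1/Λ (stable dynamics give
negative Λ, so the negated inverse peaks), or β unchanged (it peaks
directly). Inversion guards against blow-up with a floor (default 10⁻⁶,
recorded; floored cells are flagged). Weighting by inverse replicate
variance is available but off by default: with two replicates per
temperature a per-point variance estimate has one degree of freedom, and
weights built from it destabilise the fit more than they help. The
`proportionality_check` report computes Pearson correlations among the
available channels over the temperature grid and flags support when all
pairwise correlations reach 0.7 (configurable); channels that were never
measured, or are constant, are excluded or flagged rather than silently
imputed.

## What the synthetic generator emulates

`sweep_config()` defaults encode the emulated study design: 15
temperatures over 30–43 °C, two replicate channels, 5000 samples at
4.1 Hz, sensor noise 0.1 μV, and a spectral exponent following an exact
Lorentzian in temperature from a baseline of 0.475 to a peak of 1.0 at
36.6 °C with half-width 2.67 °C. The temperature range is not documented
for the original design; 30–43 °C brackets the physiological point
asymmetrically, the way a bath sweep plausibly would. The signal amplitude
is 1 μV against the 0.1 μV sensor noise — a 10:1 amplitude ratio chosen
once as a realistic instrument regime (about 1% noise variance).

The essential design decision is that the entropy minimum is *induced
indirectly*: the generator shapes only the 1/f structure β(T), and the
entropy dip emerges because more correlated noise is more regular. Nothing
imposes entropy values directly. This mirrors the physical claim that
criticality is carried by the 1/f structure, and it has a measurable
consequence: sample entropy responds nonlinearly to β — nearly flat below
β ≈ 0.65 and increasingly steep above — so the inverse-entropy channel is
a *sharpened* image of the β-profile. The fitted T_c is unaffected (the
peak location is preserved, and the pipeline recovers it to well within
0.2 °C over 50 sweeps), but the fitted half-width of the entropy channel
is systematically narrower than the generating γ. The β channel itself
does not suffer this attenuation. Analyses that need the width in
generator units should read it from the β channel or calibrate the
entropy response.

What the generator does **not** emulate: any electrochemistry of the
electrode interface, haemodynamics or biological replicate structure,
slow drifts and nonstationarities other than those implied by colored
noise, temperature measurement error (the grid is exact), or the
deterministic wave component that real recordings may contain near
criticality (a damped oscillation term is available but off by default).
Passing tests on synthetic sweeps therefore demonstrates that the
measurement chain is correct and well-calibrated for colored-noise
signals of the study's size, not that real recordings satisfy the model.

Determinism: every series derives its seed from the config seed (odd
offsets for the spectral synthesis, even for sensor noise), so a config
reproduces its file set bit-for-bit and the RNG state of the calling
session is never touched.

## Problem sizes and runtime envelope

The shipped tests run the estimators at the emulated design size
(N = 5000) where the scientific claim depends on it — exponent-recovery
bias (60–100 seeds per exponent), the white-noise Hurst null (100 seeds),
critical-temperature recovery (50 sweeps of 30 series), entropy
monotonicity in β (50 seeds per exponent) and channel proportionality (20
sweeps) — and at smaller sizes (N ≈ 1200–3000) for structural checks
where size is immaterial. The full suite completes in a few minutes on
one CPU; `scripts/acceptance.R`, which regenerates the headline quantities
from scratch, runs in under a minute.

## Known limitations

* The embedding dimension of short noisy physiological series is not
  identifiable in any strong sense; the FNN cap (12) is a reporting
  convention, and Lyapunov estimates at the cap should be read as
  descriptive.
* The `corrected empirical` Hurst variant follows the
  shift-by-expectation convention; other software applies the Anis–Lloyd
  correction inside the regression instead (our `corrected R/S`), and the
  two differ at small N.
* Lorentzian width estimates from inverse-entropy channels are attenuated
  relative to the generating spectral profile, as described above.
* `y_error` is a declared convention (RMS of range-normalised residuals);
  other definitions of a normalised fit error exist.
* The histogram AMI estimator is biased upward for small samples; with
  fewer than ~500 points, 16 bins is too many and the delay should be
  taken from the ACF instead.
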