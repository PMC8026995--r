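# critflux

Nonlinear time-series analysis and critical-temperature profiling of
extracellular ionic-flux voltage recordings.

## The problem

Slow voltage fluctuations recorded from an unperturbed electrolyte (for
example an isolated drop of blood against a reference bath) carry the
signature of the underlying ion dynamics. Across a bath-temperature sweep,
several *dynamic* measures of such recordings change systematically and —
near the physiological temperature — extremally: the 1/f spectral exponent
peaks, while the dynamic entropy of the fluctuations dips. `critflux`
implements the full measurement chain needed to detect and localise that
critical temperature from uniformly sampled voltage series:

- **Preprocessing** — mean, linear or piecewise-linear detrending
  (`detrend()`), delimited-text I/O with a sweep manifest
  (`read_series()`, `read_sweep()`).
- **Spectral signature** — β, the negated slope of the log–log power
  spectral density, from a segment-averaged tapered periodogram
  (`spectral_signature()`); β = 0 white, 1 pink, 2 Brownian noise.
- **Rescaled-range family** — simple, empirical, Anis–Lloyd-corrected and
  theoretical Hurst exponents plus DFA (`hurst_family()`, `dfa_alpha()`).
  The theoretical exponent is the log–log slope of the analytic expectation
  E[R/S]_n over the block sizes, a data-free finite-size reference.
- **State-space reconstruction** — embedding delays from the
  autocorrelation 1/e crossing and the first average-mutual-information
  minimum, false-nearest-neighbour embedding dimension, Takens delay
  embedding, and an attractor-anisotropy (sphericity) diagnostic
  (`acf_delay()`, `ami_delay()`, `embedding_dimension()`,
  `embed_series()`, `sphericity()`).
- **Largest Lyapunov exponent** — Rosenstein-style mean log-divergence of
  tracked nearest neighbours (`max_lyapunov()`).
- **Complexity** — approximate entropy (Pincus Φᵐ − Φᵐ⁺¹, self-matches
  included) and sample entropy (Richman–Moorman −log(A/B), self-matches
  excluded), Chebyshev distance, O(N²) kernels in C++
  (`approximate_entropy()`, `sample_entropy()`).
- **Criticality profiling** — the core model. Per-temperature replicate
  aggregation (`build_profile()`), guarded measure inversion
  (`invert_measure()`), and a four-parameter Lorentzian resonance fit

  y(T) = y₀ + A·γ² / ((T − T_c)² + γ²)

  by multi-start Levenberg–Marquardt (`lorentz_fit()`, a classed model
  object with `print`/`summary`/`coef`/`predict`/`plot`/`residuals`
  methods). `localize_tc()` composes a channel transform — 1/S_s, 1/S_a,
  −1/Λ, or β directly — with the fit; `proportionality_check()` tests
  whether the channels co-vary across the grid.
- **Synthetic sweeps** — `sweep_config()`/`generate_sweep()` emit
  ground-truthed sweeps whose spectral exponent follows a Lorentzian in
  temperature, so every pipeline stage is testable end to end without the
  original recordings.

## Worked example

```r
library(critflux)

cfg <- sweep_config(seed = 1)   # 15 temperatures x 2 replicates, 5000 samples @ 4.1 Hz
sw  <- generate_sweep(cfg)
mt  <- run_measure(sw, measures = c("beta", "sampen", "apen"))
rep <- run_profile(mt, channels = c("s_s", "s_a", "beta"))
summary(rep$fits$s_s)
```

```
Lorentzian resonance fit (channel 1/S_s)

           estimate std_error
t_c        36.63259   0.07279
half_width  1.81958   0.16843
amplitude   0.11424   0.00501
baseline    0.46974   0.00360

FWHM 3.6392 degC | R^2 0.9795 | y_error 0.0473 | n = 15
half_width is HWHM of the peak above baseline
```

The generator placed the resonance at 36.6 °C; the inverse-sample-entropy
channel recovers `t_c` within its standard error. `R²` is the coefficient
of determination of the resonance fit and `y_error` the RMS residual after
range-normalising the channel to [0, 1]. The fitted half-width of the
entropy channel is narrower than the generating β-profile's 2.67 °C
because sample entropy responds nonlinearly to the spectral exponent (see
the methods vignette). The channels co-vary as expected:

```r
rep$proportionality
```

```
       beta 1/S_a 1/S_s
beta  1.000 0.964 0.968
1/S_a 0.964 1.000 0.999
1/S_s 0.968 0.999 1.000
  all pairwise correlations >= 0.70: yes
```

Per-series measures are equally direct:

```r
hurst_family(detrend(sw$series[[14]]))
```

```
<hurst_estimates>
  simple 0.6234 | corrected R/S 0.8274 | empirical 0.8460 | corrected empirical 0.8159 | theoretical 0.5301
  20 block sizes in [50, 2475] (opt_n = 4950, population sd)
```

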