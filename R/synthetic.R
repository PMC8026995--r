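#' Colored (power-law) noise by spectral synthesis
#'
#' Gaussian noise with target one-sided spectrum proportional to
#' `f^(-beta)`: independent complex-Gaussian spectral coefficients are
#' scaled by `f^(-beta/2)`, Hermitian symmetry imposed, and the inverse FFT
#' taken; the result is demeaned and normalised to unit standard deviation.
#' `beta = 0` gives white noise, `beta = 1` pink (1/f) noise, `beta = 2`
#' Brownian-like noise. Output is bit-reproducible from `seed` and the
#' caller's RNG state is left untouched.
#'
#' @param n Number of samples (>= 64).
#' @param beta Spectral exponent in `[0, 3]`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, mean 0, SD 1.
#' @export
colored_noise <- function(n, beta, seed) {
  n <- as.integer(n)
  if (n < 64) stop("colored_noise needs n >= 64")
  if (!is.finite(beta) || beta < 0 || beta > 3)
    stop("beta must lie in [0, 3]")
  nf <- n %/% 2L
  with_seed(seed, {
    re <- stats::rnorm(nf)
    im <- stats::rnorm(nf)
    f <- seq_len(nf) / n
    amp <- f^(-beta / 2)
    spec <- complex(real = re, imaginary = im) * amp
    if (n %% 2L == 0L)  # real Nyquist coefficient
      spec[nf] <- complex(real = re[nf], imaginary = 0) * amp[nf]
    full <- c(0 + 0i, spec,
              if (n %% 2L == 0L) Conj(rev(spec[-nf])) else Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    x <- x - mean(x)
    x / stats::sd(x)
  })
}

#' Configuration of a synthetic temperature sweep
#'
#' Describes a full synthetic experiment: a grid of bath temperatures with
#' replicate voltage recordings whose spectral exponent follows a Lorentzian
#' resonance in temperature,
#' `beta(T) = beta_baseline + (beta_peak - beta_baseline) * g^2 / ((T - t_c_true)^2 + g^2)`,
#' peaking at the physiological temperature. Each series is
#' `signal_sd * colored_noise(beta(T))` plus white sensor noise (and
#' optionally a damped oscillation). The defaults mirror the study design
#' this generator emulates: 15 temperatures, 2 replicate channels, 5000
#' samples at 4.1 Hz, baseline exponent 0.475 rising to 1.0 at
#' `t_c_true = 36.6` degC with half-width 2.67 degC, and 0.1 uV sensor
#' noise.
#'
#' @param temperatures Temperature grid in degC (default 15 points over
#'   30-43).
#' @param n_samples Samples per series (default 5000).
#' @param sampling_rate Hz (default 4.1).
#' @param n_replicates Replicate channels per temperature (default 2).
#' @param beta_baseline,beta_peak Baseline and peak spectral exponents
#'   (defaults 0.475 and 1.0; `beta_peak >= beta_baseline >= 0`).
#' @param t_c_true Resonance centre in degC (default 36.6).
#' @param half_width_true Lorentzian HWHM in degC (default 2.67).
#' @param signal_sd Signal amplitude in uV (default 1).
#' @param sensor_noise_sd Sensor white-noise SD in uV (default 0.1).
#' @param oscillation Optional list `list(frequency, amplitude, damping)`
#'   adding `amplitude * exp(-damping * t) * sin(2 pi frequency t)`.
#' @param seed Master seed; per-series seeds are derived deterministically.
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(temperatures = seq(30, 43, length.out = 15),
                         n_samples = 5000L, sampling_rate = 4.1,
                         n_replicates = 2L,
                         beta_baseline = 0.475, beta_peak = 1.0,
                         t_c_true = 36.6, half_width_true = 2.67,
                         signal_sd = 1.0, sensor_noise_sd = 0.1,
                         oscillation = NULL, seed = 1L) {
  temperatures <- sort(as.numeric(temperatures))
  stopifnot(length(temperatures) >= 1, n_samples >= 64, sampling_rate > 0,
            n_replicates >= 1, half_width_true > 0,
            signal_sd >= 0, sensor_noise_sd >= 0)
  if (!(beta_peak >= beta_baseline && beta_baseline >= 0))
    stop("need beta_peak >= beta_baseline >= 0")
  if (!is.null(oscillation) &&
      !all(c("frequency", "amplitude", "damping") %in% names(oscillation)))
    stop("oscillation needs fields frequency, amplitude, damping")
  structure(list(temperatures = temperatures,
                 n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate,
                 n_replicates = as.integer(n_replicates),
                 beta_baseline = beta_baseline, beta_peak = beta_peak,
                 t_c_true = t_c_true, half_width_true = half_width_true,
                 signal_sd = signal_sd, sensor_noise_sd = sensor_noise_sd,
                 oscillation = oscillation, seed = as.integer(seed)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config> %d temperatures in [%.4g, %.4g] degC x %d replicates, %d samples @ %.4g Hz\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$n_replicates, x$n_samples,
              x$sampling_rate))
  cat(sprintf("  beta: %.4g -> %.4g, resonance at %.4g degC (HWHM %.4g), signal %.4g uV, sensor noise %.4g uV, seed %d\n",
              x$beta_baseline, x$beta_peak, x$t_c_true, x$half_width_true,
              x$signal_sd, x$sensor_noise_sd, x$seed))
  invisible(x)
}

#' Ground-truth spectral-exponent profile of a sweep configuration
#'
#' @param config A [sweep_config()].
#' @return Numeric vector `beta(T)` over `config$temperatures` — exactly
#'   Lorentzian by construction.
#' @export
beta_profile <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  g <- config$half_width_true
  config$beta_baseline + (config$beta_peak - config$beta_baseline) *
    g^2 / ((config$temperatures - config$t_c_true)^2 + g^2)
}

#' Generate a synthetic temperature sweep
#'
#' Emits one [voltage_series()] per temperature/replicate combination with
#' deterministic per-series seeds derived from `config$seed` (odd offsets
#' drive the colored-noise synthesis, even offsets the sensor noise), plus a
#' ground-truth table.
#'
#' @param config A [sweep_config()].
#' @return Object of class `voltage_sweep`: list with `series` (list of
#'   [voltage_series()]), `ground_truth` (data frame: temperature,
#'   replicate_id, beta_true, seed_signal, seed_noise), and `config`.
#' @export
generate_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  bt <- beta_profile(config)
  n <- config$n_samples
  tm <- (seq_len(n) - 1) / config$sampling_rate
  osc <- if (!is.null(config$oscillation)) {
    o <- config$oscillation
    o$amplitude * exp(-o$damping * tm) * sin(2 * pi * o$frequency * tm)
  } else 0
  idx <- 0L
  series <- list()
  gt <- list()
  for (i in seq_along(config$temperatures)) {
    for (rep in seq_len(config$n_replicates)) {
      idx <- idx + 1L
      s_sig <- ((config$seed %% 2147483L) * 1000003 + 2 * idx + 1) %% 2147483647
      s_noise <- s_sig + 1
      x <- config$signal_sd * colored_noise(n, bt[i], s_sig)
      if (config$sensor_noise_sd > 0)
        x <- x + with_seed(s_noise,
                           stats::rnorm(n, 0, config$sensor_noise_sd))
      x <- x + osc
      lbl <- sprintf("T%07.3f_r%d", config$temperatures[i], rep)
      series[[idx]] <- voltage_series(x, config$sampling_rate,
                                      temperature = config$temperatures[i],
                                      replicate_id = rep, label = lbl)
      gt[[idx]] <- data.frame(temperature = config$temperatures[i],
                              replicate_id = rep, beta_true = bt[i],
                              seed_signal = s_sig, seed_noise = s_noise)
    }
  }
  structure(list(series = series,
                 ground_truth = do.call(rbind, gt),
                 config = config),
            class = "voltage_sweep")
}

#' @export
print.voltage_sweep <- function(x, ...) {
  cat(sprintf("<voltage_sweep> %d series (%d temperatures x %d replicates)\n",
              length(x$series), length(x$config$temperatures),
              x$config$n_replicates))
  print(x$config)
  invisible(x)
}

#' Write a synthetic sweep to disk in the series/manifest format
#'
#' Writes one series file per recording, a `manifest.csv`
#' (series_path, temperature_C, replicate_id) readable by [read_sweep()],
#' and `ground_truth.json` holding the full generative configuration and
#' per-series truth.
#'
#' @param sweep A [generate_sweep()] result.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sweep$series, function(s) {
    p <- paste0(gsub("[^A-Za-z0-9_.-]", "_", s$label), ".csv")
    write_series(s, file.path(dir, p))
    p
  }, character(1))
  man <- data.frame(
    series_path = paths,
    temperature_C = vapply(sweep$series, `[[`, numeric(1), "temperature"),
    replicate_id = vapply(sweep$series, `[[`, integer(1), "replicate_id"))
  mp <- file.path(dir, "manifest.csv")
  utils::write.table(man, mp, sep = ",", row.names = FALSE, quote = FALSE)
  cfg <- sweep$config
  cfg$oscillation <- if (is.null(cfg$oscillation)) NULL else cfg$oscillation
  jsonlite::write_json(
    list(config = unclass(cfg), ground_truth = sweep$ground_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
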