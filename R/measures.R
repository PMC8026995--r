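#' Compute the dynamic-measure set of one recording
#'
#' Detrends the series and computes the requested nonlinear measures:
#' spectral signature, the Hurst family, DFA exponent, embedding delays
#' (ACF and AMI), false-nearest-neighbour embedding dimension, largest
#' Lyapunov exponent (on the AMI-delay embedding by default), and
#' approximate/sample entropy. Measures can be subset to save time — the
#' embedding/Lyapunov chain dominates the cost — and absent measures are
#' reported as `NA`.
#'
#' @param series A [voltage_series()].
#' @param measures Character subset of
#'   `c("beta", "hurst", "dfa", "delays", "embedding", "lyapunov", "apen",
#'   "sampen")` (all by default). `"lyapunov"` implies `"delays"` and
#'   `"embedding"`.
#' @param detrend_mode Passed to [detrend()] (default `"linear"`).
#' @param window_length Piecewise-detrend window (samples).
#' @param m,r,r_type Entropy template length and tolerance, see
#'   [sample_entropy()].
#' @param max_dim Cap for [embedding_dimension()].
#' @param which_delay `"ami"` (default) or `"acf"`: delay fed to the
#'   embedding.
#' @param fit_range Divergence-step range for [max_lyapunov()].
#' @return Object of class `measure_set`: a one-row data frame with columns
#'   `label`, `temperature`, `replicate_id`, `n_samples`, `sampling_rate`,
#'   `beta`, `h_simple`, `h_corrected_rs`, `h_empirical`,
#'   `h_corrected_empirical`, `h_theoretical`, `dfa`, `tau_acf`, `tau_ami`,
#'   `emb_dim`, `lambda`, `lambda_per_s`, `s_a`, `s_s`, `s_s_flagged`, plus
#'   parameter bookkeeping (`detrend_mode`, `m`, `r`).
#' @export
measure_series <- function(series,
                           measures = c("beta", "hurst", "dfa", "delays",
                                        "embedding", "lyapunov", "apen",
                                        "sampen"),
                           detrend_mode = "linear", window_length = 500L,
                           m = 2L, r = 0.2, r_type = "sd",
                           max_dim = 12L, which_delay = c("ami", "acf"),
                           fit_range = c(1L, 10L)) {
  stopifnot(inherits(series, "voltage_series"))
  measures <- match.arg(measures, several.ok = TRUE)
  which_delay <- match.arg(which_delay)
  if ("lyapunov" %in% measures)
    measures <- union(measures, "embedding")
  if ("embedding" %in% measures)
    measures <- union(measures, "delays")
  x <- detrend(series, mode = detrend_mode, window_length = window_length)

  out <- data.frame(label = series$label,
                    temperature = series$temperature,
                    replicate_id = series$replicate_id,
                    n_samples = length(series$samples),
                    sampling_rate = series$sampling_rate,
                    beta = NA_real_, h_simple = NA_real_,
                    h_corrected_rs = NA_real_, h_empirical = NA_real_,
                    h_corrected_empirical = NA_real_,
                    h_theoretical = NA_real_, dfa = NA_real_,
                    tau_acf = NA_integer_, tau_ami = NA_integer_,
                    emb_dim = NA_integer_, lambda = NA_real_,
                    lambda_per_s = NA_real_, s_a = NA_real_,
                    s_s = NA_real_, s_s_flagged = FALSE,
                    detrend_mode = detrend_mode, m = as.integer(m), r = r,
                    stringsAsFactors = FALSE)

  if ("beta" %in% measures)
    out$beta <- spectral_signature(x)$beta
  if ("hurst" %in% measures) {
    h <- hurst_family(x)
    out$h_simple <- h$h_simple
    out$h_corrected_rs <- h$h_corrected_rs
    out$h_empirical <- h$h_empirical
    out$h_corrected_empirical <- h$h_corrected_empirical
    out$h_theoretical <- h$h_theoretical
  }
  if ("dfa" %in% measures)
    out$dfa <- as.numeric(dfa_alpha(x))
  if ("delays" %in% measures) {
    out$tau_acf <- suppressWarnings(acf_delay(x))
    out$tau_ami <- suppressWarnings(as.integer(ami_delay(x)))
  }
  if ("embedding" %in% measures) {
    tau <- if (which_delay == "ami") out$tau_ami else out$tau_acf
    max_dim_eff <- min(as.integer(max_dim),
                       max(2L, (length(x$samples) - 100L) %/% tau + 1L))
    out$emb_dim <- suppressWarnings(
      as.integer(embedding_dimension(x, delay = tau,
                                     max_dim = max_dim_eff)))
  }
  if ("lyapunov" %in% measures) {
    tau <- if (which_delay == "ami") out$tau_ami else out$tau_acf
    att <- embed_series(x, dim = out$emb_dim, delay = tau)
    ly <- max_lyapunov(att, theiler_window = tau, fit_range = fit_range)
    out$lambda <- ly$lambda_per_sample
    out$lambda_per_s <- ly$lambda_per_second
  }
  if ("apen" %in% measures)
    out$s_a <- as.numeric(approximate_entropy(x, m = m, r = r,
                                              r_type = r_type))
  if ("sampen" %in% measures) {
    ss <- sample_entropy(x, m = m, r = r, r_type = r_type)
    out$s_s <- as.numeric(ss)
    out$s_s_flagged <- isTRUE(attr(ss, "flagged"))
  }
  class(out) <- c("measure_set", "data.frame")
  out
}
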