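test_that("series round-trip through delimited text preserves values", {
  vs <- voltage_series(c(1.5, -2.25, 3.125, 0.5, 7, -1, 2, 0.125, 9, -4.5),
                       sampling_rate = 4.1, temperature = 36.6,
                       replicate_id = 2L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_series(vs, p)
  back <- read_series(p, temperature = 36.6, replicate_id = 2L)
  expect_equal(back$samples, vs$samples, tolerance = 1e-12)
  expect_equal(back$sampling_rate, 4.1, tolerance = 1e-6)
  expect_equal(back$temperature, 36.6)
})

test_that("sampling rate is inferred from the median time step", {
  p <- withr::local_tempfile(fileext = ".csv")
  tm <- (0:99) / 4.1
  writeLines(c("time_s,voltage_uV",
               paste(format(tm, digits = 10), rnorm(100), sep = ",")), p)
  vs <- read_series(p)
  expect_equal(vs$sampling_rate, 4.1, tolerance = 1e-4)
})

test_that("non-uniform sampling and non-numeric rows are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  tm <- (0:49) / 4.1
  tm[30:50] <- tm[30:50] + 1 / 4.1   # a doubled step mid-series
  writeLines(paste(format(tm, digits = 10), rnorm(50), sep = ","), p)
  expect_error(read_series(p), "non-uniform")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1.0", "0.25,oops", "0.5,2.0"), p2)
  expect_error(read_series(p2), "non-numeric")
})

test_that("mean and linear detrending satisfy their closed forms", {
  const <- voltage_series(rep(5, 4), 1)
  expect_equal(detrend(const, "mean")$samples, rep(0, 4))

  t <- seq_len(200)
  line <- voltage_series(2 + 3 * t, 4.1)
  expect_lt(max(abs(detrend(line, "linear")$samples)), 1e-9)

  # linear-mode output orthogonal to {1, t}
  set.seed(11)
  x <- voltage_series(rnorm(300) + 0.05 * seq_len(300), 4.1)
  d <- detrend(x, "linear")$samples
  expect_lt(abs(sum(d)), 1e-8)
  expect_lt(abs(sum(d * seq_len(300))) / 300, 1e-6)
})

test_that("piecewise detrending removes an exact two-slope ramp", {
  n <- 200; w <- 100
  x <- c(1 + 0.5 * (1:100), 51 - 0.25 * (1:100))
  d <- detrend(voltage_series(x, 1), "piecewise_linear", window_length = w)
  expect_lt(max(abs(d$samples)), 1e-9)
  # oracle: independent per-window least squares
  set.seed(3)
  y <- rnorm(n) + rep(c(0.2, -0.4), each = 100) * seq_len(n)
  dd <- detrend(voltage_series(y, 1), "piecewise_linear", window_length = w)
  manual <- unlist(lapply(1:2, function(k) {
    idx <- ((k - 1) * w + 1):(k * w)
    resid(lm(y[idx] ~ seq_len(w)))
  }))
  expect_equal(dd$samples, unname(manual), tolerance = 1e-9)
})

test_that("detrending is idempotent and preserves length and rate", {
  set.seed(4)
  vs <- voltage_series(cumsum(rnorm(1200)), 4.1)
  for (mode in c("mean", "linear", "piecewise_linear")) {
    d1 <- detrend(vs, mode)
    d2 <- detrend(d1, mode)
    expect_equal(d2$samples, d1$samples, tolerance = 1e-9)
    expect_length(d1$samples, 1200)
    expect_equal(d1$sampling_rate, 4.1)
  }
})

test_that("detrend errors name the minimum length", {
  vs <- voltage_series(rnorm(50), 1)
  expect_error(detrend(vs, "piecewise_linear", window_length = 40), ">= 80")
})

test_that("sweep manifests attach temperatures and reject emptiness", {
  dir <- withr::local_tempdir()
  sw <- generate_sweep(sweep_config(temperatures = c(30, 33, 36, 39),
                                    n_samples = 128, n_replicates = 1,
                                    seed = 9))
  man <- write_sweep(sw, dir)
  back <- read_sweep(man)
  expect_length(back, 4)
  expect_equal(vapply(back, `[[`, numeric(1), "temperature"),
               c(30, 33, 36, 39))
  expect_equal(back[[2]]$samples, sw$series[[2]]$samples, tolerance = 1e-12)

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("series_path,temperature_C,replicate_id", p)
  expect_error(read_sweep(p), "empty manifest")
})
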