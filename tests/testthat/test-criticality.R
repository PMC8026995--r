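make_measures <- function(temps = seq(30, 43, length.out = 15),
                          reps = 2, f = function(T) 1 / (1 + (T - 36.6)^2),
                          noise = 0, seed = 1) {
  # entropy dips at the centre (so its inverse peaks); beta peaks directly
  set.seed(seed)
  do.call(rbind, lapply(temps, function(T)
    data.frame(temperature = T, replicate_id = seq_len(reps),
               s_s = 1 / (1 + f(T)) + rnorm(reps, 0, noise),
               beta = 2 * f(T) + rnorm(reps, 0, noise))))
}

test_that("profiles aggregate replicates with sample SD and drop sentinels", {
  m <- data.frame(temperature = rep(c(30, 33, 36, 39), each = 2),
                  replicate_id = rep(1:2, 4),
                  s_s = c(1, 3, 2, 2, 5, 4, 1, Inf))
  p <- build_profile(m)
  expect_equal(p$s_s_mean[1], 2)
  expect_equal(p$s_s_sd[1], sqrt(2))
  expect_equal(p$s_s_n, c(2L, 2L, 2L, 1L))   # sentinel dropped
  expect_equal(attr(p, "n_excluded"), 1L)
  expect_error(build_profile(m[m$temperature < 36, ]), "4 distinct")
})

test_that("a generated sweep profiles into one row per temperature", {
  sw <- generate_sweep(sweep_config(n_samples = 256, seed = 5))
  mt <- run_measure(sw, measures = "sampen")
  p <- build_profile(mt)
  expect_equal(nrow(p), 15)
  expect_equal(p$s_s_n, rep(2L, 15))
})

test_that("measure inversion applies the floor and sign conventions", {
  expect_equal(as.numeric(invert_measure(c(2, 4), floor = 1e-6)),
               c(0.5, 0.25))
  z <- invert_measure(0)
  expect_equal(as.numeric(z), 1e6)
  expect_true(attr(z, "flagged"))
  lam <- invert_measure(c(-14.04, -15.01), negate = TRUE)
  expect_equal(as.numeric(lam), c(1 / 14.04, 1 / 15.01), tolerance = 1e-12)
})

test_that("noiseless Lorentzian data are recovered exactly", {
  Tg <- seq(30, 43, length.out = 15)
  y <- 0.2 + 1 * 2^2 / ((Tg - 36.6)^2 + 2^2)
  f <- lorentz_fit(Tg, y)
  expect_equal(unname(coef(f)), c(36.6, 2, 1, 0.2), tolerance = 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
  expect_lt(f$y_error, 1e-8)
  expect_equal(f$fwhm, 2 * coef(f)[["half_width"]])
  expect_equal(predict(f, 36.6), 1.2, tolerance = 1e-6)
})

test_that("the fitted centre is unbiased under observation noise", {
  Tg <- seq(30, 43, length.out = 15)
  mu <- 0.2 + 1 * 2^2 / ((Tg - 36.6)^2 + 2^2)
  tc <- vapply(1:200, function(s) {
    set.seed(9000 + s)
    coef(lorentz_fit(Tg, mu + rnorm(15, 0, 0.05)))[["t_c"]]
  }, numeric(1))
  expect_lt(abs(mean(tc) - 36.6), 0.1)
})

test_that("the fit is translation-equivariant and scale-invariant", {
  Tg <- seq(30, 43, length.out = 15)
  set.seed(71)
  y <- 0.3 + 0.8 * 1.5^2 / ((Tg - 36)^2 + 1.5^2) + rnorm(15, 0, 0.03)
  f0 <- lorentz_fit(Tg, y)
  f_shift <- lorentz_fit(Tg + 100, y)
  expect_equal(coef(f_shift)[["t_c"]], coef(f0)[["t_c"]] + 100,
               tolerance = 1e-8)
  expect_equal(coef(f_shift)[["half_width"]], coef(f0)[["half_width"]],
               tolerance = 1e-8)
  f_scale <- lorentz_fit(Tg, 50 * y)
  expect_equal(coef(f_scale)[["t_c"]], coef(f0)[["t_c"]], tolerance = 1e-8)
  expect_equal(coef(f_scale)[["half_width"]], coef(f0)[["half_width"]],
               tolerance = 1e-8)
  expect_equal(f_scale$r_squared, f0$r_squared, tolerance = 1e-8)
  expect_equal(coef(f_scale)[["amplitude"]], 50 * coef(f0)[["amplitude"]],
               tolerance = 1e-6)
})

test_that("a flat profile yields a weak-resonance warning and near-zero R^2", {
  set.seed(72)
  m <- make_measures(f = function(T) 0.5, noise = 0.02)
  p <- build_profile(m)
  expect_warning(f <- localize_tc(p, "s_s"), "weak resonance")
  expect_lt(f$r_squared, 0.5)
})

test_that("localize_tc recovers the centre from channel profiles", {
  m <- make_measures(noise = 0.003, seed = 73)
  p <- build_profile(m)
  f_ss <- localize_tc(p, "s_s")   # entropy dips, inverse entropy peaks
  f_beta <- localize_tc(p, "beta")
  expect_equal(coef(f_ss)[["t_c"]], 36.6, tolerance = 0.1)
  expect_equal(coef(f_beta)[["t_c"]], 36.6, tolerance = 0.05)
  expect_equal(f_beta$channel, "beta")
  expect_true(is.na(f_beta$inversion_floor))
  expect_equal(f_ss$channel, "1/S_s")
  # inverse-variance weighting runs and records its convention
  f_w <- localize_tc(p, "beta", weights = "inverse_variance")
  expect_equal(f_w$weighting, "inverse_variance")
  expect_equal(coef(f_w)[["t_c"]], 36.6, tolerance = 0.1)
})

test_that("proportionality is detected exactly and sign flips are flagged", {
  temps <- seq(30, 43, length.out = 15)
  base <- 1 / (1 + (temps - 36.6)^2 / 4)
  m <- data.frame(temperature = temps, replicate_id = 1,
                  beta = 2 * base,
                  s_a = 1 / (3 * base),   # 1/s_a proportional to base
                  s_s = 1 / (5 * base),
                  lambda = -1 / base)     # -1/lambda proportional to base
  p <- build_profile(m)
  rep <- proportionality_check(p)
  expect_true(rep$supported)
  expect_true(all(abs(rep$correlations - 1) < 1e-10))

  m$beta <- -m$beta
  rep2 <- proportionality_check(build_profile(m))
  expect_false(rep2$supported)
  expect_equal(rep2$correlations["beta", "1/S_s"], -1, tolerance = 1e-10)
})
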