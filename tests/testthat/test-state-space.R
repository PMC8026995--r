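test_that("acf delay follows its closed-form oracles", {
  set.seed(51)
  expect_equal(acf_delay(voltage_series(rnorm(2000), 1)), 1L)

  # sine of period 40: sample ACF ~ cos(2 pi tau / 40) * (1 - tau/N);
  # first lag below 1/e is 8 (acos(1/e) = 1.1943 rad => tau >= 7.6)
  x <- sin(2 * pi * (1:4000) / 40)
  expect_equal(acf_delay(voltage_series(x, 1)), 8L)
  ac <- acf(x, lag.max = 20, plot = FALSE)$acf[-1]
  expect_equal(which(ac < exp(-1))[1], 8L)

  # AR(1), phi = 0.9: theoretical first crossing at tau = 10
  x <- ar1_series(60000, 0.9, seed = 52)
  expect_equal(acf_delay(voltage_series(x, 1), max_lag = 50), 10L)
  expect_equal(ceiling(1 / log(1 / 0.9)), 10)

  expect_error(acf_delay(voltage_series(rep(1, 100), 1)), "zero-variance")
})

test_that("ami delay matches the joint-histogram oracle and finds the sine minimum", {
  set.seed(53)
  x <- rnorm(1500)
  d <- ami_delay(voltage_series(x, 1), max_lag = 30)
  ami <- attr(d, "ami")
  for (tau in c(1, 5, 17))
    expect_equal(ami[tau], oracle_ami(x, tau, 16), tolerance = 1e-10)
  expect_lte(as.integer(d), 3L)  # iid: first minimum almost immediately

  # identical lagged copy: AMI at that lag equals the marginal bin entropy
  xs <- sin(2 * pi * (1:2000) / 40)
  brk <- seq(min(xs), max(xs), length.out = 17)
  pb <- tabulate(findInterval(xs, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), 16)
  pb <- pb[pb > 0] / length(xs)
  ent <- -sum(pb * log(pb))
  ami40 <- attr(ami_delay(voltage_series(xs, 1), max_lag = 45), "ami")[40]
  expect_equal(ami40, ent, tolerance = 0.05)

  # sine of period 40: the binned AMI falls to a plateau spanning the
  # quarter period; the returned delay is the exhaustive curve's first
  # strict local minimum, which sits at the front of that plateau
  d_sine <- as.integer(ami_delay(voltage_series(xs, 1), max_lag = 30))
  full <- vapply(1:30, function(tau) oracle_ami(xs, tau, 16), numeric(1))
  first_min <- which(diff(sign(diff(c(Inf, full)))) > 0)[1]
  expect_equal(d_sine, first_min)
  expect_true(d_sine >= 5 && d_sine <= 15)

  expect_error(ami_delay(voltage_series(rep(2, 600), 1)), "constant")
})

test_that("delay selectors are invariant under positive affine maps", {
  x <- ar1_series(3000, 0.8, seed = 54)
  v1 <- voltage_series(x, 1); v2 <- voltage_series(5 * x + 3, 1)
  expect_equal(acf_delay(v1), acf_delay(v2))
  expect_equal(as.integer(ami_delay(v1)), as.integer(ami_delay(v2)))
})

test_that("delay embedding has the right geometry and count", {
  a <- embed_series(voltage_series(rnorm(10), 1), dim = 3, delay = 2)
  expect_equal(nrow(a), 6)
  x <- rnorm(50)
  a1 <- embed_series(voltage_series(x, 1), dim = 1, delay = 4)
  expect_equal(as.numeric(a1), x)
  a2 <- embed_series(voltage_series(1:5, 1), dim = 2, delay = 3)
  expect_equal(unclass(a2)[1, ], c(1, 4))
  # un-embedding (first coordinate) recovers the series prefix
  a3 <- embed_series(voltage_series(x, 1), dim = 4, delay = 3)
  expect_equal(unclass(a3)[, 1], x[1:nrow(a3)])
  expect_error(embed_series(voltage_series(rnorm(10), 1), 5, 4), "too short")
})

test_that("false nearest neighbours embed a sine in 2 dimensions and cap on noise", {
  xs <- sin(2 * pi * (1:2000) / 40)
  expect_equal(as.integer(embedding_dimension(voltage_series(xs, 1),
                                              delay = 10, max_dim = 6)), 2L)
  set.seed(55)
  expect_warning(
    d <- embedding_dimension(voltage_series(rnorm(1500), 1), delay = 1,
                             max_dim = 8),
    "never fell below")
  expect_equal(as.integer(d), 8L)
})

test_that("false nearest neighbours recover the Lorenz attractor dimension", {
  skip_if_not_installed("deSolve")
  lorenz <- function(t, y, p)
    list(c(10 * (y[2] - y[1]), y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  out <- deSolve::ode(c(1, 1, 20), seq(0, 120, by = 0.03), lorenz, NULL)
  x <- out[-(1:500), 2]   # drop transient
  vs <- voltage_series(x, 1 / 0.03)
  tau <- as.integer(ami_delay(vs, max_lag = 50))
  d <- as.integer(embedding_dimension(vs, delay = tau, max_dim = 8))
  expect_equal(d, 3L)
})

test_that("sphericity separates isotropic clouds from degenerate ones", {
  set.seed(56)
  cloud <- matrix(rnorm(3e4), ncol = 3)
  s <- sphericity(cloud)
  expect_gt(s$sphericity, 0.95)
  expect_lte(s$sphericity, 1)

  th <- seq(0, 2 * pi, length.out = 400)
  circ <- cbind(cos(th), sin(th), 0)
  s2 <- sphericity(circ)
  expect_lt(s2$sphericity, 1e-10)
  expect_equal(s2$extents[3], 0, tolerance = 1e-12)

  line <- cbind(1:100, 2 * (1:100), -0.5 * (1:100))
  s3 <- sphericity(line)
  expect_lt(s3$extents[2] / s3$extents[1], 1e-10)
  expect_lt(s3$extents[3] / s3$extents[1], 1e-10)

  expect_error(sphericity(matrix(1, 10, 3)), "degenerate")
})

test_that("sphericity is invariant under rotation and scaling", {
  set.seed(57)
  cloud <- matrix(rnorm(900), ncol = 3) %*% diag(c(3, 2, 1))
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  s0 <- sphericity(cloud)$sphericity
  expect_equal(sphericity(cloud %*% qr_q)$sphericity, s0, tolerance = 1e-9)
  expect_equal(sphericity(cloud * 11.3)$sphericity, s0, tolerance = 1e-9)
})
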