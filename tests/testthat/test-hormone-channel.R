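channel <- hormone_channel_params()

test_that("the Green's function is a normalized off-origin heat kernel", {
  expect_error(green_function(5, 0, 4800), "t > 0")
  # off-origin initial condition: density vanishes as t -> 0+
  expect_lt(green_function(5, 1e-6, 4800), 1e-300)
  # radial quadrature of the kernel integrates to 1 at several times
  for (t in c(0.01, 0.5, 3)) {
    total <- integrate(function(r) 4 * pi * r^2 * green_function(r, t, 4800),
                       0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("Brownian walkers reproduce the Green's density", {
  set.seed(202)
  n <- 1e5; D <- 4800; t1 <- 1
  # 20-step random walk, per-axis step variance 2 D dt
  steps <- 20; sdv <- sqrt(2 * D * t1 / steps)
  pos <- matrix(0, n, 3)
  for (s in seq_len(steps)) pos <- pos + matrix(rnorm(3 * n, 0, sdv), n, 3)
  r <- sqrt(rowSums(pos^2))
  edges <- seq(20, 200, by = 30)
  for (i in seq_len(length(edges) - 1)) {
    expected <- n * integrate(function(x)
      4 * pi * x^2 * green_function(x, t1, D), edges[i], edges[i + 1],
      rel.tol = 1e-9)$value
    observed <- sum(r >= edges[i] & r < edges[i + 1])
    expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1)
  }
})

test_that("concentration superposes per-event kernels with degradation", {
  g <- time_grid(40, dt = 0.01)
  sched <- encode_ook("1011", 5000, 10)
  tr <- concentration_at(sched, 5, g, channel)
  expect_equal(count_waves(tr, 0.01 * max(tr$values), 2), 3)

  empty <- concentration_at(encode_ook("0000", 5000, 10), 5, g, channel)
  expect_true(all(empty$values == 0))

  # pointwise linearity in Q0 and additivity over schedules
  tr2 <- concentration_at(encode_ook("1011", 10000, 10), 5, g, channel)
  expect_equal(tr2$values, 2 * tr$values, tolerance = 1e-12)

  a <- concentration_at(encode_ook("1000", 5000, 10), 5, g, channel)
  b <- concentration_at(encode_ook("0011", 5000, 10), 5, g, channel)
  expect_equal(a$values + b$values, tr$values, tolerance = 1e-12)

  # before the first event the trace is exactly zero
  late <- concentration_at(encode_ook("0011", 5000, 10), 5, g, channel)
  expect_true(all(late$values[g$times <= 20] == 0))
})

test_that("slot absorption probabilities behave like the quadrature defines", {
  u <- absorption_probability(0:7, 10, 5, channel)
  expect_true(all(u >= 0))
  expect_true(all(diff(u) < 0))          # decay with slot offset
  expect_lt(u[8] / u[1], 1e-4)
  expect_lte(sum(u), 1)

  # fixed-step trapezoid oracle; the slot-0 integrand peaks on the
  # millisecond scale, so that slot needs a much finer step
  for (n in 0:2) {
    ref <- trapz_oracle(function(t)
      green_function(5, pmax(t, 1e-12), channel$D_H) * exp(-channel$iota * t),
      n * 10, (n + 1) * 10, n = if (n == 0) 2e6 else 2e4) *
      channel$capture_efficiency
    expect_equal(u[n + 1], ref, tolerance = 1e-6)
  }

  # faster degradation suppresses late capture relative to early capture
  ratios <- vapply(c(0.2, 1, 5), function(iota) {
    ch <- hormone_channel_params(iota = iota,
                                 capture_efficiency = channel$capture_efficiency)
    ui <- absorption_probability(0:1, 10, 5, ch)
    ui[2] / ui[1]
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("capture efficiency calibration hits its target detection rate", {
  u0 <- absorption_probability(0, 10, 5, channel)
  expect_equal(1 - (1 - u0)^5000, 0.5, tolerance = 1e-6)
  # Q0 dependence: more molecules, higher slot detection
  det <- vapply(c(1000, 5000, 10000), function(q)
    slot_detection_probs(1, 10, 5, q, channel), numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("hormonal delay grows with distance and slot length", {
  d_grid <- c(2, 5, 10, 18)
  om_d <- vapply(d_grid, hormonal_delay, numeric(1), T = 10, D_H = 4800)
  expect_true(all(diff(om_d) > 0))

  T_grid <- c(2, 5, 10, 20)
  om_T <- vapply(T_grid, function(T) hormonal_delay(5, T, 4800), numeric(1))
  expect_true(all(diff(om_T) > 0))

  # trapezoid oracle after substituting w = s^2, which removes the
  # 1/sqrt(w) endpoint singularity of the weight
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  f <- function(w) erf(sqrt(25 / (4 * 4800 * w))) / sqrt(8 * pi * 4800 * w)
  den <- trapz_oracle(function(s) 2 * s * f(s^2), 1e-12, sqrt(10), n = 2e5)
  num <- trapz_oracle(function(s) 2 * s^3 * f(s^2), 1e-12, sqrt(10), n = 2e5)
  expect_equal(hormonal_delay(5, 10, 4800), num / den, tolerance = 1e-3)
})
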