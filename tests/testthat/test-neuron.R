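fp <- firing_params()

test_that("membrane potential is the linear kernel response to flux", {
  g <- time_grid(5, dt = 0.01)
  zero <- trace(g, rep(0, grid_length(g)), "flux")
  V0 <- membrane_potential(list(zero, zero), params = fp, grid = g)
  expect_true(all(V0$values == fp$V_r))

  flux <- trace(g, exp(-(g$times - 1)^2), "flux")
  V1 <- membrane_potential(list(flux), params = fp, grid = g)
  V2 <- membrane_potential(list(trace(g, 2 * flux$values, "flux")),
                           params = fp, grid = g)
  expect_equal(V2$values - fp$V_r, 2 * (V1$values - fp$V_r),
               tolerance = 1e-12)
  # response to a sum of fluxes equals the sum of responses
  Vs <- membrane_potential(list(flux, flux), params = fp, grid = g)
  expect_equal(Vs$values - fp$V_r, 2 * (V1$values - fp$V_r),
               tolerance = 1e-12)

  # FFT convolution against the O(n^2) direct sum
  kern <- fp$kernel_gain * exp(-g$times / fp$kernel_tau) / fp$kernel_tau
  ref <- fp$V_r + brute_conv(flux$values, kern, g$dt)
  expect_equal(V1$values, ref, tolerance = 1e-9)
})

test_that("the firing rate is a logistic map of the potential", {
  g <- time_grid(2, dt = 1)
  low <- firing_rate(trace(g, rep(fp$theta1 - 30, 3), "mV"), fp)
  expect_lt(max(low$values), 1e-10 * fp$lambda_max)
  mid <- firing_rate(trace(g, rep(fp$theta1, 3), "mV"), fp)
  expect_equal(mid$values, rep(fp$lambda_max / 2, 3))
  vv <- seq(-80, -20, by = 1)
  gg <- time_grid(60, dt = 1)
  lam <- firing_rate(trace(gg, vv, "mV"), fp)$values
  expect_true(all(diff(lam) > 0))
})

test_that("thinned spike trains have Poisson statistics", {
  g <- time_grid(10, dt = 0.01)
  rng <- rng_handle(17)
  empty <- generate_spikes(trace(g, rep(0, grid_length(g)), "Hz"), rng)
  expect_length(empty, 0)

  const <- trace(g, rep(20, grid_length(g)), "Hz")
  counts <- vapply(1:500, function(i)
    length(generate_spikes(const, rng_handle(i), label = "poisson-test")),
    numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 500))
  # index of dispersion of a Poisson count is 1
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.2)

  # time-rescaling: transformed intervals of an inhomogeneous train are
  # unit-rate exponential (aggregate KS over replicates)
  lam <- 10 + 8 * sin(2 * pi * g$times / 3)
  rate <- trace(g, lam, "Hz")
  Lam <- cumsum(c(0, (lam[-1] + lam[-length(lam)]) / 2 * g$dt))
  iv <- unlist(lapply(1:50, function(i) {
    sp <- generate_spikes(rate, rng_handle(i), label = "rescale")
    diff(approx(g$times, Lam, xout = sp)$y)
  }))
  ks <- suppressWarnings(ks.test(iv, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("the cable series matches its single-mode closed form", {
  ax <- axon_params()
  t <- c(0, 0.002, 0.02, 0.2)
  x <- c(0, 10, 43.2)
  got <- cable_solution(function(xx) cos(pi * xx / ax$L_N), ax, x, t)
  tau_m <- ax$gamma_m * ax$gamma_c * 1e-3
  tau_d <- ax$L_N^2 * ax$gamma_l * ax$gamma_c * 1e-3
  ref <- outer(exp(-t / tau_m) * exp(-pi^2 * t / tau_d), cos(pi * x / ax$L_N))
  expect_equal(got, ref, tolerance = 1e-12)
  # all modes decay: the solution vanishes at large time
  late <- cable_solution(proximal_bump(ax), ax, x, 50 * tau_m)
  expect_lt(max(abs(late)), 1e-12)
})

test_that("the cable series agrees with an explicit finite-difference solver", {
  ax <- axon_params(n_modes = 128)
  t_out <- c(0.005, 0.02, 0.05)
  fd <- fd_cable(proximal_bump(ax), ax, t_out)
  ser <- cable_solution(proximal_bump(ax), ax, fd$x, t_out)
  scale <- max(abs(fd$v))
  expect_lt(max(abs(ser - fd$v)) / scale, 0.01)
})

test_that("doubling the mode count leaves the truncated series unchanged", {
  t <- c(0.001, 0.01, 0.1)
  x <- seq(0, 43.2, length.out = 9)
  a64 <- cable_solution(proximal_bump(axon_params()), axon_params(n_modes = 64),
                        x, t)
  a128 <- cable_solution(proximal_bump(axon_params()),
                         axon_params(n_modes = 128), x, t)
  expect_lt(max(abs(a64 - a128)), 1e-6)
})

test_that("axonal delay is the terminal time-to-peak and grows with length", {
  ax <- axon_params()
  pure <- axonal_delay(ax, function(x) cos(pi * x / ax$L_N))
  expect_equal(pure$omega_ax, 0)
  expect_true(pure$peak_at_zero)

  om <- vapply(c(20, 43.2, 80), function(L) {
    a <- axon_params(L_N = L)
    axonal_delay(a, proximal_bump(a))$omega_ax
  }, numeric(1))
  expect_true(all(om > 0))
  expect_true(all(diff(om) > 0))

  # refinement agrees with a brute-force dense scan to grid resolution
  d <- axonal_delay(ax, proximal_bump(ax))
  tt <- seq(0, 2, length.out = 8001)
  v <- abs(cable_solution(proximal_bump(ax), ax, ax$L_N, tt))
  expect_lt(abs(d$omega_ax - tt[which.max(v)]), 2 * diff(tt[1:2]))
})

test_that("spike propagation is a rigid shift by the axonal delay", {
  ax <- axon_params()
  expect_length(propagate_spike_train(numeric(0), ax, omega_ax = 0.1), 0)
  sp <- c(0.2, 0.9, 1.31, 5)
  out <- propagate_spike_train(sp, ax, omega_ax = 0.25)
  expect_equal(diff(as.numeric(out)), diff(sp))
  expect_equal(as.numeric(out) - sp, rep(0.25, 4))
  auto <- propagate_spike_train(sp, ax)
  expect_equal(as.numeric(auto)[1] - sp[1],
               axonal_delay(ax, proximal_bump(ax))$omega_ax)
})
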