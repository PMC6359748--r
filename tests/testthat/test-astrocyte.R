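ap <- astrocyte_params()

test_that("calcium fluxes hit their closed-form special cases", {
  # zero driving force: ER and cytoplasm at the same level
  st <- astrocyte_state(C_CY = 0.5, C_ER = 0.5, h = 0.7)
  fl <- calcium_fluxes(st, C_IP3 = 0.4, ap)
  expect_equal(fl$U_chan, 0)
  expect_equal(fl$U_leak, 0)

  # pump at half saturation: C_CY = b3 gives v_pump / 2
  st2 <- astrocyte_state(C_CY = ap$b3, C_ER = 10, h = 0.7)
  expect_equal(calcium_fluxes(st2, 0.4, ap)$U_pump, 0.45)

  # gate fully open at rest: C_IP3 = 0, C_CY = 0 makes a3 = 1
  st3 <- astrocyte_state(C_CY = 0, C_ER = 10, h = 0.7)
  expect_equal(calcium_fluxes(st3, 0, ap)$a3, 1)
})

test_that("the as-printed system conserves C_CY - a1 C_ER", {
  g <- time_grid(100, dt = 0.02)
  ip3 <- trace(g, rep(0.5, grid_length(g)), "uM")
  res <- simulate_astrocyte(ip3, params = ap, grid = g,
                            convention = "as_printed")
  cons <- res$states$C_CY - ap$a1 * res$states$C_ER
  expect_lt(max(abs(cons - cons[1])), 1e-6)
  expect_true(all(res$states$h >= 0 & res$states$h <= 1))
})

test_that("the store-conserving convention oscillates and self-converges", {
  g <- time_grid(60, dt = 0.02)
  ip3 <- trace(g, rep(0.5, grid_length(g)), "uM")
  res <- simulate_astrocyte(ip3, params = ap, grid = g)
  ca <- res$ca_trace
  # threshold from the post-transient amplitude (the onset spike is larger
  # than the steady oscillation)
  late <- ca$values[g$times > 10]
  thr <- min(late) + 0.5 * diff(range(late))
  n_peaks <- count_waves(ca, thr, 2)
  expect_gte(n_peaks, 3)
  expect_true(all(res$states$h >= 0 & res$states$h <= 1))

  # total calcium conserved in this convention
  tot <- res$states$C_CY + ap$a1 * res$states$C_ER
  expect_lt(max(abs(tot - tot[1])), 1e-6)

  # grid halving: period (mean peak spacing) reproducible
  g2 <- time_grid(60, dt = 0.01)
  res2 <- simulate_astrocyte(trace(g2, rep(0.5, grid_length(g2)), "uM"),
                             params = ap, grid = g2)
  peak_times <- function(r) {
    v <- r$ca_trace$values
    tt <- r$ca_trace$grid$times
    i <- which(diff(sign(diff(v))) == -2) + 1
    tt[i][v[i] > thr]
  }
  p1 <- mean(diff(peak_times(res)))
  p2 <- mean(diff(peak_times(res2)))
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("no stimulus means monotone decay to a pump-limited floor", {
  g <- time_grid(60, dt = 0.02)
  ip3 <- trace(g, rep(0, grid_length(g)), "uM")
  res <- simulate_astrocyte(ip3, params = ap, grid = g)
  v <- res$ca_trace$values
  expect_lt(min(diff(v)), 1e-6)              # decaying
  expect_lt(diff(range(v[g$times > 40])), 1e-3)  # settled
  expect_lt(v[length(v)], 0.1)
  expect_equal(count_waves(res$ca_trace, 0.3, 2), 0)
})

test_that("the oscillation regime scan brackets a contiguous IP3 interval", {
  grid_ip3 <- seq(0.2, 1.0, by = 0.1)
  sc <- scan_oscillation_regime(ap, ip3_grid = grid_ip3)
  expect_false(is.na(sc$ip3_low))
  expect_lt(sc$ip3_low, sc$ip3_high)
  # contiguity of the oscillatory set
  on <- which(sc$oscillating)
  expect_equal(on, seq(min(on), max(on)))
  # below the interval: steady low Ca; above: steady high Ca
  g <- time_grid(150, dt = 0.02)
  lo <- simulate_astrocyte(trace(g, rep(0.15, grid_length(g)), "uM"),
                           params = ap, grid = g)
  hi <- simulate_astrocyte(trace(g, rep(1.1, grid_length(g)), "uM"),
                           params = ap, grid = g)
  late <- g$times > 100
  expect_lt(diff(range(lo$ca_trace$values[late])), 0.01)
  expect_lt(diff(range(hi$ca_trace$values[late])), 0.01)
  expect_lt(mean(lo$ca_trace$values[late]), 0.15)
  expect_gt(mean(hi$ca_trace$values[late]), 0.35)
})

test_that("oscillation frequency is non-decreasing across the IP3 window", {
  g <- time_grid(150, dt = 0.02)
  freq <- vapply(c(0.42, 0.55, 0.7), function(ip3) {
    r <- simulate_astrocyte(trace(g, rep(ip3, grid_length(g)), "uM"),
                            params = ap, grid = g)
    v <- r$ca_trace$values[g$times > 50]
    thr <- min(v) + 0.5 * diff(range(v))
    sub <- trace(time_grid(length(v) * 0.02 - 0.02, dt = 0.02), v)
    count_waves(sub, thr, 1) / 100
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
})

test_that("hormone-to-IP3 coupling is a saturating Hill curve", {
  g <- time_grid(4, dt = 1)
  coup <- ip3_coupling(K_half = 2e-5)
  mk <- function(v) trace(g, rep(v, 5), "molecules/um^3")
  expect_equal(hormone_to_ip3(mk(0), coup)$values, rep(0.1, 5))
  expect_equal(hormone_to_ip3(mk(1e3), coup)$values, rep(0.9, 5),
               tolerance = 1e-6)
  expect_equal(hormone_to_ip3(mk(2e-5), coup)$values, rep(0.5, 5))
  expect_error(hormone_to_ip3(mk(1), ip3_coupling()), "calibrated")
})

test_that("boundary flux lags the cytoplasmic signal, less so at high D_Ca", {
  g <- time_grid(30, dt = 0.01)
  pulse <- trace(g, exp(-(g$times - 5)^2 / 2), "uM")
  lag <- vapply(c(5, 20, 80), function(D) {
    p <- astrocyte_params(D_Ca = D)
    fl <- calcium_flux_to_neuron(pulse, p)
    g$times[which.max(fl$values)] - 5
  }, numeric(1))
  expect_true(all(lag > 0))
  expect_true(all(diff(lag) < 0))

  # linearity and the zero case
  p <- astrocyte_params()
  z <- calcium_flux_to_neuron(trace(g, rep(0, grid_length(g)), "uM"), p)
  expect_true(all(z$values == 0))
  f1 <- calcium_flux_to_neuron(pulse, p)
  f2 <- calcium_flux_to_neuron(trace(g, 2 * pulse$values, "uM"), p)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-10)
})

test_that("the calcium relay delay is found by bisection on the cumulative integral", {
  g <- time_grid(20, dt = 0.01)
  osc <- trace(g, 0.2 + 0.1 * sin(g$times), "uM")
  # absorbed identical to the (single) astrocyte variation: zero delay
  same <- calcium_delay(list(osc), osc, T = 10)
  expect_equal(same$omega, 0)
  expect_true(same$reached)

  # a slowed copy needs a strictly positive delay; bisection agrees with a
  # linear scan over the same cumulative-variation series
  slowed <- trace(g, 0.2 + 0.1 * sin(pmax(g$times - 3, 0)), "uM")
  got <- calcium_delay(list(osc), slowed, T = 10)
  expect_gt(got$omega, 0)
  cum <- c(0, cumsum(abs(diff(slowed$values))))
  goal <- max(c(0, cumsum(abs(diff(osc$values[g$times <= 10])))))
  idx <- which(cum >= goal)[1]
  expect_equal(got$omega, max(g$times[idx] - 10, 0), tolerance = 1e-9)

  # unreachable target is flagged
  tiny <- trace(g, rep(0, grid_length(g)), "uM")
  miss <- calcium_delay(list(osc), tiny, T = 10)
  expect_false(miss$reached)
})
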