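pools <- vesicle_pool_params()

test_that("the slot-average firing rate is a trapezoid mean", {
  g <- time_grid(10, dt = 0.01)
  expect_equal(mean_firing_rate(trace(g, rep(20, grid_length(g)), "Hz"), 10),
               20)
  tri <- 40 * (1 - abs(g$times - 5) / 5)
  expect_equal(mean_firing_rate(trace(g, tri, "Hz"), 10), 20,
               tolerance = 1e-9)
  g2 <- time_grid(10, dt = 0.001)
  tri2 <- 40 * (1 - abs(g2$times - 5) / 5)
  expect_equal(mean_firing_rate(trace(g, tri, "Hz"), 10),
               mean_firing_rate(trace(g2, tri2, "Hz"), 10),
               tolerance = 1e-6)
})

test_that("the vesicle release probability law has the stated shape", {
  expect_equal(release_probability(0, pools), 0)
  p_by_pool <- vapply(c(3, 5, 8, 10), function(N)
    release_probability(20, vesicle_pool_params(N_RRP = N)), numeric(1))
  expect_true(all(diff(p_by_pool) < 0))
  # small-argument regime matches the linear reading within 5%
  pp <- vesicle_pool_params(N_RRP = 8, p_v = 0.4, T_ref = 0.01)
  lin <- 0.4 * 15 * 0.01 / 8
  expect_lt(lin, 0.1)
  expect_lt(abs(release_probability(15, pp) - lin) / lin, 0.05)
})

test_that("release simulation respects pools, refill and the per-spike law", {
  rng <- rng_handle(9)
  none <- simulate_release(numeric(0), pools, rng)
  expect_length(none$release_times, 0)
  expect_equal(unname(none$counters[c("RRP", "RP")]),
               c(pools$N_RRP, pools$N_RP))

  # integer bookkeeping is exact: starting stock moves only through
  # refills and releases
  sp <- seq(0.01, 20, by = 0.04)
  res <- simulate_release(sp, pools, rng, p_release = 0.5)
  cnt <- res$counters
  expect_equal(unname(cnt[["RRP"]]),
               pools$N_RRP + cnt[["refills"]] - cnt[["releases"]])
  expect_equal(unname(cnt[["RP"]]), pools$N_RP - cnt[["refills"]])
  expect_true(all(res$occupancy$RRP >= 0 & res$occupancy$RP >= 0))

  # slow refill starves the pool; fast refill keeps occupancy up
  occ <- vapply(c(0.04, 0.01), function(tf) {
    reps <- vapply(1:100, function(i) {
      p <- vesicle_pool_params(N_RRP = 8, N_RP = 10000, tau_f = tf)
      r <- simulate_release(sp, p, rng_handle(i), p_release = 0.9)
      mean(r$occupancy$RRP[r$occupancy$time > 5])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_gt(occ[2], occ[1] + 1)

  # with pools never depleted the per-spike release fraction matches the law
  big <- vesicle_pool_params(N_RRP = 500, N_RP = 10000, tau_f = 0.001)
  frac <- vapply(1:40, function(i) {
    r <- simulate_release(sp, big, rng_handle(i), p_release = 0.35)
    length(r$release_times) / length(sp)
  }, numeric(1))
  n_tot <- 40 * length(sp)
  expect_lt(abs(mean(frac) - 0.35), 3 * sqrt(0.35 * 0.65 / n_tot))
})

test_that("release-stage error probabilities follow the printed power law", {
  expect_equal(release_error_probs(3, 1), c(bit1 = 0, bit0 = 1))
  expect_equal(release_error_probs(1, 0.5), c(bit1 = 0.5, bit0 = 0.5))
  # all-or-none enumeration oracle: fraction of k-trial batches with every
  # trial releasing
  set.seed(55)
  k <- 4; P <- 0.7; n <- 1e4
  allrel <- mean(vapply(1:n, function(i) all(runif(k) < P), logical(1)))
  pe <- release_error_probs(k, P)
  se <- 3 * sqrt(P^k * (1 - P^k) / n)
  expect_lt(abs(pe[["bit0"]] - allrel), se)
  expect_lt(abs(pe[["bit1"]] - (1 - allrel)), se)
})

test_that("the queue simulator reproduces M/M/1/K blocking", {
  rng <- rng_handle(11)
  for (rho in c(0.5, 2)) {
    qp <- queue_params(tau_b = rho / 0.02, K = 5, service_mean = 0.02,
                       service_dist = "exponential", batch_dist = "single")
    qs <- queue_simulate(qp, horizon = 10, rng, min_arrivals = 1e4)
    expect_lt(abs(qs$P_blo - mm1k_blocking(rho, 5)), 3 * qs$P_blo_se)
    # customer balance is exact at the horizon
    expect_equal(unname(qs$counters[["arrived"]]),
                 unname(qs$counters[["accepted"]] + qs$counters[["blocked"]]))
  }
})

test_that("queue obeys Little's law and loads monotonically", {
  rng <- rng_handle(5)
  lq_err <- c(); pblo <- c(); omega <- c()
  for (tb in c(5, 15, 30)) {
    qp <- queue_params(sigma = 0.5, tau_b = tb, K = 20, service_mean = 0.01)
    qs <- queue_simulate(qp, horizon = 10, rng, min_arrivals = 2e4)
    lam_eff <- qs$counters[["accepted"]] / qs$horizon
    lq_err <- c(lq_err, abs(qs$mean_queue_length - lam_eff * qs$omega))
    pblo <- c(pblo, qs$P_blo)
    omega <- c(omega, qs$omega)
  }
  expect_lt(max(lq_err), 0.01)
  expect_true(all(diff(pblo) >= 0))     # blocking non-decreasing in load
  expect_true(all(diff(omega) > 0))     # waiting grows with load
})

test_that("the alpha-function waveform superposes with Gamma amplitudes", {
  psp <- postsynaptic_params(G_max = 2, t_p = 0.02)
  g <- time_grid(1, dt = 0.001)
  y1 <- psp_waveform(0.1, psp, g, q = 1)
  expect_equal(max(y1$values), 2, tolerance = 1e-6)
  expect_equal(g$times[which.max(y1$values)], 0.1 + 0.02, tolerance = 1e-3)
  expect_equal(alpha_function(0, psp), 0)
  expect_lt(alpha_function(1, psp), 1e-12)
  expect_true(all(y1$values[g$times <= 0.1] == 0))

  # exact superposition
  y2 <- psp_waveform(0.4, psp, g, q = 1)
  both <- psp_waveform(c(0.1, 0.4), psp, g, q = 1)
  expect_equal(both$values, y1$values + y2$values, tolerance = 1e-12)

  # drawn amplitudes are reproducible under the seed
  rng <- rng_handle(2)
  a <- psp_waveform(c(0.1, 0.4), psp, g, rng)
  b <- psp_waveform(c(0.1, 0.4), psp, g, rng_handle(2))
  expect_identical(a$values, b$values)
})
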