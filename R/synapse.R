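# Synaptic stage: vesicle pools and stochastic release, release-stage bit
# error probabilities, batched-arrival finite-capacity neurotransmitter
# queue (Mx/G/1/K), postsynaptic waveform synthesis.

#' Vesicle pool parameters
#'
#' @param N_RRP readily releasable pool size (vesicles)
#' @param N_RP reserve pool size (vesicles)
#' @param tau_f mean RP-to-RRP refill time per vesicle, s
#' @param p_v per-vesicle release probability scale
#' @param T_ref normalization window of the release-probability law, s
#' @return object of class `mc_pool_params`
#' @export
vesicle_pool_params <- function(N_RRP = 8, N_RP = 60, tau_f = 0.03,
                                p_v = 0.4, T_ref = 0.01) {
  stopifnot(N_RRP >= 1, N_RP >= 0, tau_f > 0, p_v > 0, p_v <= 1, T_ref > 0)
  structure(as.list(environment()), class = "mc_pool_params")
}

#' Neurotransmitter queue parameters (Mx/G/1/K)
#'
#' Batches arrive after exponential inter-arrival times with rate
#' `sigma * lambda_b` (= tau_b); batch sizes are geometric with parameter
#' `sigma` (mean mu_b = 1/sigma), so the customer arrival intensity is
#' lambda_b = mu_b * tau_b. One receptor serves customers with service
#' distribution G, the system holds at most K customers.
#'
#' @param sigma geometric batch-size parameter in (0, 1]
#' @param tau_b batch arrival rate, 1/s
#' @param K receptor capacity (customers in system)
#' @param service_mean mean service (absorption) time, s
#' @param service_dist "exponential", "deterministic" or "gamma"
#' @param gamma_shape shape when `service_dist = "gamma"`
#' @param acceptance "partial" (admit the fitting head of a blocked batch)
#'   or "whole" (block entire batches that do not fit)
#' @param batch_dist "geometric" or "single" (unit batches; makes the model
#'   M/G/1/K)
#' @return object of class `mc_queue_params`
#' @export
queue_params <- function(sigma = 0.5, tau_b = 10, K = 10, service_mean = 0.02,
                         service_dist = c("exponential", "deterministic",
                                          "gamma"),
                         gamma_shape = 2,
                         acceptance = c("partial", "whole"),
                         batch_dist = c("geometric", "single")) {
  service_dist <- match.arg(service_dist)
  acceptance <- match.arg(acceptance)
  batch_dist <- match.arg(batch_dist)
  stopifnot(sigma > 0, sigma <= 1, K >= 1, service_mean > 0, tau_b > 0)
  p <- list(sigma = sigma, tau_b = tau_b, K = as.integer(K),
            service_mean = service_mean, service_dist = service_dist,
            gamma_shape = gamma_shape, acceptance = acceptance,
            batch_dist = batch_dist)
  p$mu_b <- if (batch_dist == "single") 1 else 1 / sigma
  p$lambda_b <- p$mu_b * tau_b
  structure(p, class = "mc_queue_params")
}

#' Postsynaptic response parameters
#'
#' The unitary postsynaptic waveform is the alpha function
#' F(t) = G_max (t/t_p) exp(1 - t/t_p); per-event amplitudes are jittered by
#' i.i.d. Gamma(q_shape, scale = q_scale) factors (default mean 1).
#'
#' @param G_max peak amplitude (arbitrary potential units)
#' @param t_p time to peak, s
#' @param q_shape,q_scale Gamma amplitude-jitter parameters
#' @return object of class `mc_psp_params`
#' @export
postsynaptic_params <- function(G_max = 1, t_p = 0.005, q_shape = 16,
                                q_scale = 1 / 16) {
  stopifnot(G_max > 0, t_p > 0, q_shape > 0, q_scale > 0)
  structure(as.list(environment()), class = "mc_psp_params")
}

#' Slot-average firing rate
#'
#' Trapezoid mean of the rate trace over [t0, t0 + T].
#' @param rate rate [trace()], Hz
#' @param T averaging window, s
#' @param from window start, s (default trace start)
#' @return lambda-bar, Hz
#' @export
mean_firing_rate <- function(rate, T, from = NULL) {
  stopifnot(T > 0)
  if (is.null(from)) from <- rate$grid$t0
  trace_integral(rate, from = from, to = from + T) / T
}

#' Per-vesicle release probability
#'
#' P_rele = 1 - exp(-p_v lambda_bar T_ref / N_RRP): saturating in the firing
#' rate, decreasing in the pool size, and linear
#' (~ p_v lambda_bar T_ref / N_RRP) for small arguments.
#'
#' @param lambda_bar mean firing rate, Hz
#' @param pools [vesicle_pool_params()]
#' @return probability in [0, 1]
#' @export
release_probability <- function(lambda_bar, pools) {
  stopifnot(lambda_bar >= 0)
  p <- 1 - exp(-pools$p_v * lambda_bar * pools$T_ref / pools$N_RRP)
  min(max(p, 0), 1)
}

#' Simulate vesicle release over a spike train
#'
#' Each spike releases one vesicle with probability `p_release` while the
#' RRP is nonempty; between spikes the RP refills the RRP as a Poisson
#' process with rate 1/tau_f (one vesicle per event) while vacancies and
#' reserve remain.
#'
#' @param spikes spike times, s (sorted)
#' @param pools [vesicle_pool_params()]
#' @param rng [rng_handle()]
#' @param p_release per-spike release probability; default
#'   [release_probability()] at the train's empirical rate
#' @param label stream label, default "release"
#' @return list: `release_times`, `occupancy` (data.frame time, RRP, RP at
#'   spike times), and integer `counters` (spikes, releases, refills)
#' @export
simulate_release <- function(spikes, pools, rng, p_release = NULL,
                             label = "release") {
  times <- as.numeric(spikes)
  if (is.null(p_release)) {
    dur <- if (length(times) > 1) diff(range(times)) else 1
    p_release <- release_probability(length(times) / max(dur, 1e-9), pools)
  }
  n_rrp <- pools$N_RRP
  n_rp <- pools$N_RP
  rel <- numeric(0)
  occ <- matrix(0, nrow = length(times), ncol = 2)
  refills <- 0L
  with_stream(rng, label, {
    t_prev <- if (length(times)) times[1] else 0
    for (j in seq_along(times)) {
      gap <- times[j] - t_prev
      if (gap > 0 && n_rp > 0 && n_rrp < pools$N_RRP) {
        k <- rpois(1, gap / pools$tau_f)
        k <- min(k, pools$N_RRP - n_rrp, n_rp)
        n_rrp <- n_rrp + k; n_rp <- n_rp - k; refills <- refills + k
      }
      if (n_rrp > 0 && runif(1) < p_release) {
        n_rrp <- n_rrp - 1L
        rel <- c(rel, times[j])
      }
      occ[j, ] <- c(n_rrp, n_rp)
      t_prev <- times[j]
    }
  })
  list(release_times = structure(rel, class = "mc_spikes"),
       occupancy = data.frame(time = times, RRP = occ[, 1], RP = occ[, 2]),
       counters = c(spikes = length(times), releases = length(rel),
                    refills = refills,
                    RRP = if (nrow(occ)) occ[nrow(occ), 1] else pools$N_RRP,
                    RP = if (nrow(occ)) occ[nrow(occ), 2] else pools$N_RP))
}

#' Release-stage bit error probabilities
#'
#' For a slot with `k_i` action-potential spikes and per-vesicle release
#' probability `P_rele`: the "1" error is 1 - P_rele^k_i and the "0" error
#' is P_rele^k_i. `k_i = 0` with a transmitted "1" is an upstream miss and
#' is not described by these expressions.
#'
#' @param k_i spike count in the slot (>= 0)
#' @param P_rele per-vesicle release probability
#' @return named vector c(bit1 = ..., bit0 = ...)
#' @export
release_error_probs <- function(k_i, P_rele) {
  stopifnot(k_i >= 0, P_rele >= 0, P_rele <= 1)
  c(bit1 = 1 - P_rele^k_i, bit0 = P_rele^k_i)
}

draw_service <- function(n, params) {
  switch(params$service_dist,
         exponential = rexp(n, rate = 1 / params$service_mean),
         deterministic = rep(params$service_mean, n),
         gamma = rgamma(n, shape = params$gamma_shape,
                        scale = params$service_mean / params$gamma_shape))
}

#' Discrete-event simulation of the neurotransmitter queue
#'
#' Batched Poisson arrivals, single server, capacity K, FIFO. Returns the
#' customer-average blocking probability, the mean waiting time before
#' absorption starts, Monte-Carlo standard errors and occupancy statistics.
#' The horizon is extended automatically until at least `min_arrivals`
#' customers have arrived.
#'
#' @param params [queue_params()]
#' @param horizon requested simulated time, s
#' @param rng [rng_handle()]
#' @param min_arrivals minimum number of customer arrivals
#' @param label stream label, default "queue"
#' @return list with `P_blo`, `P_blo_se`, `omega` (mean wait, s),
#'   `omega_se`, `utilization`, `mean_queue_length`, `counters`
#' @export
queue_simulate <- function(params, horizon = 10, rng, min_arrivals = 1e4,
                           label = "queue") {
  batch_rate <- if (params$batch_dist == "single") params$tau_b
                else params$sigma * params$lambda_b  # = tau_b
  need_t <- min_arrivals / (batch_rate * params$mu_b)
  horizon <- max(horizon, 1.05 * need_t)
  with_stream(rng, label, {
    n_batches <- rpois(1, batch_rate * horizon * 1.1) + 10
    at <- cumsum(rexp(n_batches, batch_rate))
    at <- at[at <= horizon]
    n_batches <- length(at)
    bs <- if (params$batch_dist == "single") rep(1L, n_batches)
          else rgeom(n_batches, params$sigma) + 1L
    # expand to customers
    ct <- rep(at, bs)
    n_cust <- length(ct)
    sv <- draw_service(n_cust, params)
    dep <- numeric(n_cust)      # departure times of accepted customers
    start <- numeric(n_cust)
    accepted <- logical(n_cust)
    n_acc <- 0L
    n_dep_seen <- 0L            # departures before current arrival time
    j <- 1L
    for (b in seq_len(n_batches)) {
      t_arr <- at[b]
      # count departures up to t_arr (dep[1..n_acc] is nondecreasing)
      while (n_dep_seen < n_acc && dep[n_dep_seen + 1L] <= t_arr)
        n_dep_seen <- n_dep_seen + 1L
      in_sys <- n_acc - n_dep_seen
      free <- params$K - in_sys
      take <- if (params$acceptance == "partial") min(bs[b], max(free, 0L))
              else if (bs[b] <= free) bs[b] else 0L
      for (m in seq_len(bs[b])) {
        if (m <= take) {
          n_acc <- n_acc + 1L
          accepted[j] <- TRUE
          start[n_acc] <- if (n_acc == 1L) t_arr else max(t_arr, dep[n_acc - 1L])
          dep[n_acc] <- start[n_acc] + sv[j]
        }
        j <- j + 1L
      }
    }
    start <- start[seq_len(n_acc)]
    dep <- dep[seq_len(n_acc)]
    waits <- start - ct[accepted]
    blocked <- n_cust - n_acc
    p_blo <- blocked / n_cust
    busy <- sum(pmin(dep, horizon) - pmin(start, horizon))
    lq <- sum(pmin(start, horizon) - pmin(ct[accepted], horizon)) / horizon
    # batch-means standard errors: blocking and waiting are autocorrelated
    # (bursts while the buffer is full), so binomial/iid SEs are too small
    bm_se <- function(x, nb = 50) {
      if (length(x) < 2 * nb) return(stats::sd(x) / sqrt(length(x)))
      m <- vapply(split(x, cut(seq_along(x), nb, labels = FALSE)), mean,
                  numeric(1))
      stats::sd(m) / sqrt(nb)
    }
    list(P_blo = p_blo,
         P_blo_se = bm_se(as.numeric(!accepted)),
         omega = mean(waits),
         omega_se = bm_se(waits),
         utilization = busy / horizon,
         mean_queue_length = lq,
         counters = c(arrived = n_cust, accepted = n_acc, blocked = blocked,
                      served_by_horizon = sum(dep <= horizon)),
         horizon = horizon)
  })
}

#' Closed-form M/M/1/K blocking probability
#'
#' Reference formula used to cross-check the simulator with unit batches and
#' exponential service: P_blo = rho^K (1 - rho) / (1 - rho^(K+1)) (and
#' 1/(K+1) at rho = 1).
#'
#' @param rho offered load (arrival rate x mean service time)
#' @param K system capacity
#' @return blocking probability
#' @export
mm1k_blocking <- function(rho, K) {
  if (abs(rho - 1) < 1e-12) return(1 / (K + 1))
  rho^K * (1 - rho) / (1 - rho^(K + 1))
}

#' Alpha-function value
#' @param t time since release, s (vectorized; 0 for t < 0)
#' @param params [postsynaptic_params()]
#' @return waveform values
#' @export
alpha_function <- function(t, params) {
  v <- ifelse(t >= 0, params$G_max * (t / params$t_p) * exp(1 - t / params$t_p), 0)
  v[!is.finite(v)] <- 0
  v
}

#' Postsynaptic waveform from release events
#'
#' y(t) = sum_j q_j F(t - t_j) with the alpha function F and i.i.d. Gamma
#' amplitude factors q_j (fix `q` to a constant for deterministic synthesis).
#'
#' @param release_times event times, s
#' @param params [postsynaptic_params()]
#' @param grid [time_grid()]
#' @param rng [rng_handle()] (unused when `q` is supplied)
#' @param q fixed amplitude factor(s), or `NULL` to draw Gamma jitter
#' @param label stream label, default "amplitude"
#' @return waveform [trace()]
#' @export
psp_waveform <- function(release_times, params, grid, rng = NULL, q = NULL,
                         label = "amplitude") {
  tt <- grid$times
  nr <- length(release_times)
  if (is.null(q)) {
    if (is.null(rng)) stop("supply rng or fixed q")
    q <- with_stream(rng, label,
                     rgamma(nr, shape = params$q_shape, scale = params$q_scale))
  } else if (length(q) == 1) q <- rep(q, nr)
  v <- numeric(length(tt))
  # alpha function support: (t/tp) e^(1-t/tp) < 1e-12 beyond ~35 tp
  span <- ceiling(35 * params$t_p / grid$dt)
  for (j in seq_len(nr)) {
    i0 <- max(1L, ceiling((release_times[j] - grid$t0) / grid$dt) + 1L)
    i1 <- min(length(tt), i0 + span)
    if (i0 > length(tt)) next
    idx <- i0:i1
    v[idx] <- v[idx] + q[j] * alpha_function(tt[idx] - release_times[j], params)
  }
  trace(grid, v, units = "arbitrary")
}
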