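# Amplify-and-forward firing (linear-response membrane, smooth thresholded
# Poisson spike generation) and passive axonal cable propagation.

#' Firing-stage parameters
#'
#' The membrane responds linearly to Ca2+ influx (amplify-and-forward: the
#' relay scales, never decodes); spikes are generated by an inhomogeneous
#' Poisson process whose rate is a logistic function of the membrane
#' potential around the firing threshold theta1 -- a smooth bridge between
#' the hard threshold and the observed Poisson statistics (the hard
#' threshold is recovered as `rate_slope` grows).
#'
#' @param V_r resting membrane potential, mV
#' @param theta1 firing threshold, mV
#' @param kernel_tau time constant of the membrane response kernel nu, s
#' @param kernel_gain kernel amplitude, mV per unit flux
#' @param lambda_max saturating firing rate, Hz
#' @param rate_slope logistic steepness, 1/mV
#' @return object of class `mc_firing_params`
#' @export
firing_params <- function(V_r = -70, theta1 = -55, kernel_tau = 1,
                          kernel_gain = 40, lambda_max = 25,
                          rate_slope = 1) {
  stopifnot(lambda_max > 0, kernel_tau > 0, kernel_gain >= 0, rate_slope > 0)
  structure(as.list(environment()), class = "mc_firing_params")
}

#' Axon cable parameters
#'
#' The gamma products are read as effective time constants in milliseconds:
#' the membrane leak constant is `gamma_m * gamma_c` ms and the axial
#' diffusion constant is `L_N^2 * gamma_l * gamma_c` ms.
#'
#' @param gamma_m membrane resistance, MOhm
#' @param gamma_l longitudinal resistance, MOhm
#' @param gamma_c membrane capacitance, mF/cm^2
#' @param L_N axon length, um
#' @param n_modes series truncation order
#' @param N_N number of neurons chained at the output
#' @return object of class `mc_axon_params`
#' @export
axon_params <- function(gamma_m = 64.1, gamma_l = 8, gamma_c = 1,
                        L_N = 43.2, n_modes = 64, N_N = 1) {
  stopifnot(gamma_m > 0, gamma_l > 0, gamma_c > 0, L_N > 0, n_modes >= 1,
            N_N >= 1)
  structure(as.list(environment()), class = "mc_axon_params")
}

axon_tau_m <- function(params) params$gamma_m * params$gamma_c * 1e-3
axon_tau_diff <- function(params)
  params$L_N^2 * params$gamma_l * params$gamma_c * 1e-3

#' Membrane potential from astrocytic Ca2+ fluxes
#'
#' V(t) = V_r + sum_i integral nu(s) A_i(t - s) ds with the exponential
#' response kernel nu(s) = kernel_gain exp(-s/tau)/tau. Each flux is gated
#' to zero before its onset time.
#'
#' @param fluxes list of flux traces, one per contributing astrocyte
#' @param t_on onset times (s), one per flux
#' @param params [firing_params()]
#' @param grid shared [time_grid()]
#' @return membrane potential [trace()], mV
#' @export
membrane_potential <- function(fluxes, t_on = NULL, params, grid) {
  if (is.null(t_on)) t_on <- rep(grid$t0, length(fluxes))
  stopifnot(length(t_on) == length(fluxes))
  tt <- grid$times
  kern <- params$kernel_gain * exp(-(tt - grid$t0) / params$kernel_tau) /
    params$kernel_tau
  n <- length(tt)
  acc <- numeric(n)
  for (i in seq_along(fluxes)) {
    f <- fluxes[[i]]
    if (!same_grid(f$grid, grid)) stop("flux trace not on the run grid")
    v <- f$values
    v[tt < t_on[i]] <- 0
    acc <- acc + fast_conv(v, kern)
  }
  trace(grid, params$V_r + acc * grid$dt, units = "mV")
}

#' Instantaneous firing rate from the membrane potential
#'
#' lambda(t) = lambda_max / (1 + exp(-rate_slope (V - theta1))).
#'
#' @param V membrane potential [trace()]
#' @param params [firing_params()]
#' @return rate [trace()], Hz
#' @export
firing_rate <- function(V, params) {
  stopifnot(inherits(V, "mc_trace"))
  lam <- params$lambda_max /
    (1 + exp(-params$rate_slope * (V$values - params$theta1)))
  trace(V$grid, lam, units = "Hz")
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Homogeneous candidates at the trace maximum rate are thinned by the
#' ratio rate(t)/max rate (rate linearly interpolated between grid points).
#'
#' @param rate nonnegative rate [trace()], Hz
#' @param rng [rng_handle()]
#' @param label stream label, default "firing"
#' @return sorted numeric vector of spike times, class `mc_spikes`
#' @export
generate_spikes <- function(rate, rng, label = "firing") {
  stopifnot(inherits(rate, "mc_trace"))
  if (any(rate$values < 0)) stop("rate must be nonnegative")
  lmax <- max(rate$values)
  g <- rate$grid
  if (lmax <= 0) return(structure(numeric(0), class = "mc_spikes"))
  rf <- approxfun(g$times, rate$values, rule = 2)
  times <- with_stream(rng, label, {
    n_cand <- rpois(1, lmax * g$duration)
    cand <- sort(runif(n_cand, g$t0, g$t0 + g$duration))
    keep <- runif(n_cand) < rf(cand) / lmax
    cand[keep]
  })
  structure(times, class = "mc_spikes")
}

cosine_coefficients <- function(V0_profile, L, n_modes, n_quad = 4096) {
  x <- seq(0, L, length.out = n_quad + 1)
  v0 <- V0_profile(x)
  w <- rep(1, n_quad + 1); w[c(1, n_quad + 1)] <- 0.5   # trapezoid weights
  dx <- L / n_quad
  vapply(0:n_modes, function(i) {
    (2 / L) * sum(w * v0 * cos(pi * i * x / L)) * dx
  }, numeric(1))
}

sine_coefficients <- function(V0_profile, L, n_modes, n_quad = 4096) {
  x <- seq(0, L, length.out = n_quad + 1)
  v0 <- V0_profile(x)
  w <- rep(1, n_quad + 1); w[c(1, n_quad + 1)] <- 0.5
  dx <- L / n_quad
  vapply(seq_len(n_modes), function(i) {
    (2 / L) * sum(w * v0 * sin(pi * i * x / L)) * dx
  }, numeric(1))
}

#' Fourier-series solution of the passive axonal cable
#'
#' Truncated separation-of-variables series
#' V(x,t) = exp(-t/tau_m) sum_i zeta_i exp(-pi^2 i^2 t / tau_diff)
#' basis_i(x), with the Fourier coefficients obtained by trapezoid
#' quadrature of the initial profile. The default cosine basis is the
#' sealed-end (Neumann) expansion and includes the i = 0 mean mode, which a
#' general initial profile requires (zero-mean profiles reduce to the pure
#' i >= 1 sum); `basis = "sine"` gives the variant consistent with a
#' grounded left end.
#'
#' @param V0_profile function of x (um) giving the initial potential (mV)
#' @param params [axon_params()]
#' @param x positions, um, in [0, L_N]
#' @param t times, s (>= 0)
#' @param basis `"cosine"` (default, as the series is printed) or `"sine"`
#' @return matrix of potentials, length(t) rows by length(x) columns
#' @export
cable_solution <- function(V0_profile, params, x, t,
                           basis = c("cosine", "sine")) {
  basis <- match.arg(basis)
  stopifnot(all(x >= 0), all(x <= params$L_N), all(t >= 0))
  L <- params$L_N
  i <- if (basis == "cosine") 0:params$n_modes else seq_len(params$n_modes)
  zeta <- if (basis == "cosine") cosine_coefficients(V0_profile, L, params$n_modes)
          else sine_coefficients(V0_profile, L, params$n_modes)
  if (basis == "cosine") zeta[1] <- zeta[1] / 2    # mean mode
  sp <- if (basis == "cosine") cos(outer(x, i) * pi / L)
        else sin(outer(x, i) * pi / L)          # length(x) x n_modes
  decay <- exp(-outer(t, pi^2 * i^2) / axon_tau_diff(params))  # t x modes
  leak <- exp(-t / axon_tau_m(params))
  out <- (decay %*% (zeta * t(sp))) * leak
  dimnames(out) <- NULL
  out
}

#' Axonal transmission delay (time-to-peak at the terminal)
#'
#' Evaluates the cable solution at `x` (default the far end) on a dense time
#' grid and refines the maximum with golden-section/parabolic search.
#'
#' @param params [axon_params()]
#' @param V0_profile initial potential profile, function of x (um)
#' @param x evaluation position, um (default L_N)
#' @param t_max scan horizon, s; default five leak time constants
#' @param basis see [cable_solution()]
#' @return list with `omega_ax` (s) and `peak_at_zero` flag (TRUE when the
#'   terminal potential only decays, so the delay is 0)
#' @export
axonal_delay <- function(params, V0_profile, x = params$L_N, t_max = NULL,
                         basis = "cosine") {
  if (is.null(t_max))
    t_max <- 5 * max(axon_tau_m(params), axon_tau_diff(params) / pi^2)
  tt <- seq(0, t_max, length.out = 2001)
  # peak of the potential magnitude (modes can arrive with either sign)
  v <- abs(cable_solution(V0_profile, params, x = x, t = tt,
                          basis = basis)[, 1])
  i <- which.max(v)
  if (i == 1) return(list(omega_ax = 0, peak_at_zero = TRUE))
  lo <- tt[max(i - 1, 1)]; hi <- tt[min(i + 1, length(tt))]
  opt <- optimize(function(s)
    abs(cable_solution(V0_profile, params, x = x, t = s, basis = basis)[1, 1]),
    interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(omega_ax = opt$maximum, peak_at_zero = FALSE)
}

#' Propagate a spike train along the axon
#'
#' Spike timing is shifted by the axonal delay; the stereotyped waveform and
#' the inter-spike intervals are preserved.
#'
#' @param spikes spike times (s)
#' @param params [axon_params()]
#' @param omega_ax precomputed delay (s); when `NULL`, computed from a
#'   proximal bump profile via [axonal_delay()]
#' @return shifted spike times, class `mc_spikes`
#' @export
propagate_spike_train <- function(spikes, params, omega_ax = NULL) {
  if (is.null(omega_ax))
    omega_ax <- axonal_delay(params, proximal_bump(params))$omega_ax
  structure(as.numeric(spikes) + omega_ax, class = "mc_spikes")
}

#' Proximal initial-potential bump for delay estimation
#'
#' Gaussian bump centred at the soma end of the axon (x = 0) with width a
#' tenth of the axon length.
#' @param params [axon_params()]
#' @return function of x
#' @export
proximal_bump <- function(params) {
  L <- params$L_N
  function(x) exp(-(x / (0.1 * L))^2 / 2)
}
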