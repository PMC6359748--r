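# IP3-gated Ca2+ oscillations per astrocyte (Li-Rinzel-type two-pool model),
# hormone-to-IP3 coupling, intracellular Ca2+ diffusion to the neuron
# boundary, and the Ca2+ relay delay.

#' Astrocyte Ca2+ model parameters
#'
#' Defaults are the published constant set for the IP3-receptor-gated
#' two-pool oscillator: channel/leak/pump rates, the six binding constants
#' b1..b6, the cytoplasmic Ca2+ diffusion coefficient and the ER-to-boundary
#' distance.
#'
#' @param a1 ER-to-cytoplasm volume ratio, unitless
#' @param v_chan max IP3-gated channel flux rate, 1/s
#' @param v_leak max leak flux rate, 1/s
#' @param v_pump max pump flux rate, uM/s
#' @param b1,b2,b3,b4,b5 binding constants, uM
#' @param b6 inactivation-gate rate constant, 1/(uM s)
#' @param D_Ca cytoplasmic Ca2+ diffusion coefficient, um^2/s
#' @param d_ER_B ER-to-boundary distance, um
#' @param C_total total calcium (cytoplasm + a1-weighted ER), uM; sets the
#'   ER initial condition in the mass-conserving convention
#' @param uptake_efficiency fraction of cytoplasmic Ca2+ variation that the
#'   neuron eventually absorbs per astrocyte (sets the boundary-flux gain)
#' @return object of class `mc_astro_params`
#' @export
astrocyte_params <- function(a1 = 0.185, v_chan = 6, v_leak = 0.11,
                             v_pump = 0.9, b1 = 0.13, b2 = 0.08234, b3 = 0.1,
                             b4 = 0.9434, b5 = 1.049, b6 = 0.2,
                             D_Ca = 20, d_ER_B = 10, C_total = 2,
                             uptake_efficiency = 0.8) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) stop("all astrocyte parameters must be positive")
  structure(p, class = "mc_astro_params")
}

#' Astrocyte state (cytoplasmic Ca2+, ER Ca2+, gate)
#' @param C_CY cytoplasmic Ca2+ concentration, uM (>= 0)
#' @param C_ER ER Ca2+ concentration, uM (>= 0)
#' @param h IP3-receptor inactivation gate in [0, 1]
#' @return named numeric vector of class `mc_astro_state`
#' @export
astrocyte_state <- function(C_CY, C_ER, h) {
  stopifnot(C_CY >= 0, C_ER >= 0, h >= 0, h <= 1)
  structure(c(C_CY = C_CY, C_ER = C_ER, h = h), class = "mc_astro_state")
}

#' Resting astrocyte state for given parameters
#'
#' C_CY = 0.1 uM, ER set from the configured total calcium, gate at its
#' steady value a3 evaluated at rest.
#' @param params [astrocyte_params()]
#' @param C_IP3 resting IP3 concentration, uM
#' @return an [astrocyte_state()]
#' @export
resting_state <- function(params, C_IP3 = 0.1) {
  C_CY <- 0.1
  C_ER <- (params$C_total - C_CY) / params$a1
  fl <- calcium_fluxes(astrocyte_state(C_CY, C_ER, 0.5), C_IP3, params)
  astrocyte_state(C_CY, C_ER, fl$a3)
}

#' Ca2+ fluxes and gate coefficients
#'
#' Channel flux gated by IP3 binding, Ca2+ activation and the inactivation
#' gate h (each cubed); linear leak; Hill-2 pump. Also exposes the gate
#' steady value a3, its time constant a2 and the lumped constant b_f used by
#' the h dynamics.
#'
#' @param state an [astrocyte_state()]
#' @param C_IP3 IP3 concentration, uM
#' @param params [astrocyte_params()]
#' @return list with U_chan, U_leak, U_pump (uM/s), a2 (s), a3, b_f (uM)
#' @export
calcium_fluxes <- function(state, C_IP3, params) {
  C <- state[["C_CY"]]; CER <- state[["C_ER"]]; h <- state[["h"]]
  p <- params
  m <- C_IP3 / (C_IP3 + p$b1)
  n <- C / (C + p$b2)
  U_chan <- p$v_chan * m^3 * n^3 * h^3 * (CER - C)
  U_leak <- p$v_leak * (CER - C)
  U_pump <- p$v_pump * C^2 / (C^2 + p$b3^2)
  b_f <- p$b5 * (C_IP3 + p$b1) / (C_IP3 + p$b4)
  list(U_chan = U_chan, U_leak = U_leak, U_pump = U_pump,
       a2 = 1 / (p$b6 * (b_f + C)), a3 = b_f / (b_f + C), b_f = b_f)
}

astro_deriv <- function(t, y, parms) {
  # flux expressions inlined (hot path of the stiff integrator)
  p <- parms$p
  C <- max(y[[1]], 0); CER <- max(y[[2]], 0); h <- min(max(y[[3]], 0), 1)
  ip3 <- parms$ip3(t)
  m <- ip3 / (ip3 + p$b1)
  nn <- C / (C + p$b2)
  U_chan <- p$v_chan * m^3 * nn^3 * h^3 * (CER - C)
  U_leak <- p$v_leak * (CER - C)
  U_pump <- p$v_pump * C^2 / (C^2 + p$b3^2)
  b_f <- p$b5 * (ip3 + p$b1) / (ip3 + p$b4)
  a2 <- 1 / (p$b6 * (b_f + C)); a3 <- b_f / (b_f + C)
  dC <- p$a1 * (U_chan + U_leak) - U_pump
  dER <- if (parms$convention == "as_printed") {
    U_chan + U_leak - U_pump / p$a1
  } else {
    -dC / p$a1   # mass conservation: C_CY + a1 C_ER constant
  }
  list(c(dC, dER, (a3 - y[[3]]) / a2))
}

#' Integrate the astrocyte Ca2+ ODE system under a driven IP3 trace
#'
#' Stiff adaptive integration (lsoda, rtol 1e-8 / atol 1e-10) of the
#' cytoplasmic Ca2+, ER Ca2+ and gate equations with C_IP3(t) interpolated
#' from `ip3_trace`.
#'
#' The `convention` argument selects the ER sign handling: `"as_printed"`
#' makes ER and cytoplasm rise together (their a1-weighted difference is a
#' conserved quantity), `"li_rinzel"` (default) conserves total calcium
#' C_CY + a1 C_ER so the ER acts as a store and sustained oscillations are
#' possible.
#'
#' @param ip3_trace IP3 concentration [trace()] (uM) on the run grid
#' @param init initial [astrocyte_state()]; default [resting_state()]
#' @param params [astrocyte_params()]
#' @param grid the run [time_grid()]
#' @param convention `"li_rinzel"` or `"as_printed"`
#' @return list with `ca_trace` (cytoplasmic Ca2+, uM) and `states`
#'   (data.frame time, C_CY, C_ER, h)
#' @export
simulate_astrocyte <- function(ip3_trace, init = NULL, params, grid,
                               convention = c("li_rinzel", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(ip3_trace, "mc_trace"))
  if (!same_grid(ip3_trace$grid, grid))
    stop("ip3_trace must live on the run grid")
  if (is.null(init)) init <- resting_state(params, C_IP3 = ip3_trace$values[1])
  ip3f <- approxfun(grid$times, ip3_trace$values, rule = 2)
  out <- deSolve::ode(y = unclass(init), times = grid$times,
                      func = astro_deriv,
                      parms = list(p = params, ip3 = ip3f,
                                   convention = convention),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0)
    stop("astrocyte ODE integration failed; last state: ",
         paste(round(out[nrow(out), -1], 6), collapse = ", "))
  states <- as.data.frame(out)
  names(states) <- c("time", "C_CY", "C_ER", "h")
  list(ca_trace = trace(grid, states$C_CY, units = "uM"), states = states)
}

count_ca_peaks <- function(ca, after = 0, min_amplitude = 0.02,
                           min_separation = 1) {
  keep <- ca$grid$times >= after
  v <- ca$values[keep]
  if (diff(range(v)) < min_amplitude) return(0L)
  sub <- trace(time_grid(duration = (sum(keep) - 1) * ca$grid$dt,
                         dt = ca$grid$dt), v)
  count_waves(sub, threshold = min(v) + 0.5 * diff(range(v)),
              min_separation = min_separation)
}

#' Scan constant-IP3 levels for sustained Ca2+ oscillation
#'
#' Runs the ODE at each IP3 level for `duration` seconds and counts Ca2+
#' peaks after a `transient`; a level is oscillatory when at least
#' `min_peaks` remain. Returns the boundaries of the oscillatory interval.
#'
#' @param params [astrocyte_params()]
#' @param convention see [simulate_astrocyte()]
#' @param ip3_grid ordered IP3 levels to probe, uM
#' @param duration,transient run length and discarded transient, s
#' @param min_peaks minimum post-transient peak count
#' @return list with `ip3_low`, `ip3_high` (NA when no oscillatory point) and
#'   the logical `oscillating` vector over `ip3_grid`
#' @export
scan_oscillation_regime <- function(params,
                                    convention = c("li_rinzel", "as_printed"),
                                    ip3_grid = seq(0.1, 1.0, by = 0.05),
                                    duration = 150, transient = 50,
                                    min_peaks = 2) {
  convention <- match.arg(convention)
  if (is.unsorted(ip3_grid)) stop("ip3_grid must be ordered")
  grid <- time_grid(duration, dt = 0.02)
  osc <- vapply(ip3_grid, function(ip3) {
    res <- simulate_astrocyte(trace(grid, rep(ip3, grid_length(grid)), "uM"),
                              params = params, grid = grid,
                              convention = convention)
    count_ca_peaks(res$ca_trace, after = transient) >= min_peaks
  }, logical(1))
  if (!any(osc)) {
    return(list(ip3_low = NA_real_, ip3_high = NA_real_, oscillating = osc))
  }
  list(ip3_low = min(ip3_grid[osc]), ip3_high = max(ip3_grid[osc]),
       oscillating = osc)
}

#' Hormone-to-IP3 coupling parameters
#'
#' Monotone saturating (Hill) transduction of extracellular hormone
#' concentration into intracellular IP3, standing in for G-protein-coupled
#' receptor signaling.
#'
#' @param ip3_base resting IP3, uM
#' @param ip3_max saturating IP3, uM
#' @param K_half hormone concentration at the half-way IP3 level,
#'   molecules/um^3 (`NULL` until calibrated, see [calibrate_ip3_coupling()])
#' @param hill_n Hill exponent (>= 1)
#' @return object of class `mc_ip3_coupling`
#' @export
ip3_coupling <- function(ip3_base = 0.1, ip3_max = 0.9, K_half = NULL,
                         hill_n = 2) {
  stopifnot(ip3_max > ip3_base, ip3_base >= 0, hill_n >= 1)
  if (!is.null(K_half)) stopifnot(K_half > 0)
  structure(list(ip3_base = ip3_base, ip3_max = ip3_max, K_half = K_half,
                 hill_n = hill_n), class = "mc_ip3_coupling")
}

#' Calibrate the hormone-to-IP3 half-saturation point
#'
#' Sets K_half to the mid-slot hormone concentration of a single "1" pulse
#' at the median astrocyte distance, so that a typical pulse drives IP3 into
#' the middle of its range (inside the oscillatory window for the default
#' base/max levels).
#'
#' @param coupling an [ip3_coupling()]
#' @param channel [hormone_channel_params()]
#' @param d reference distance, um (median astrocyte distance)
#' @param T slot length, s
#' @param Q0 molecules per bit
#' @return the coupling with K_half filled in
#' @export
calibrate_ip3_coupling <- function(coupling, channel, d, T, Q0) {
  t_mid <- T / 2
  c_mid <- Q0 * green_function(d, t_mid, channel$D_H) *
    exp(-channel$iota * t_mid)
  coupling$K_half <- c_mid
  coupling
}

#' Map a hormone concentration trace to an IP3 trace
#'
#' C_IP3(t) = base + (max - base) * C^n / (C^n + K^n).
#'
#' @param hormone_trace hormone concentration [trace()]
#' @param coupling calibrated [ip3_coupling()]
#' @return IP3 [trace()] in uM
#' @export
hormone_to_ip3 <- function(hormone_trace, coupling) {
  stopifnot(inherits(hormone_trace, "mc_trace"))
  if (is.null(coupling$K_half))
    stop("coupling is not calibrated (K_half is NULL)")
  ch <- hormone_trace$values
  n <- coupling$hill_n
  v <- coupling$ip3_base + (coupling$ip3_max - coupling$ip3_base) *
    ch^n / (ch^n + coupling$K_half^n)
  trace(hormone_trace$grid, v, units = "uM")
}

#' Ca2+ flux arriving at the neuron boundary
#'
#' Convolves the cytoplasmic Ca2+ trace with the 3-D diffusion Green's
#' kernel at the ER-to-boundary distance. The gain defaults to
#' `uptake_efficiency / integral(kernel)`, i.e. the neuron eventually
#' absorbs `uptake_efficiency` of the astrocyte-side signal.
#'
#' @param ca_trace cytoplasmic Ca2+ [trace()]
#' @param params [astrocyte_params()]
#' @param gain multiplicative flux gain; `NULL` for the default above
#' @return flux [trace()] (arbitrary concentration-flux units)
#' @export
calcium_flux_to_neuron <- function(ca_trace, params, gain = NULL) {
  stopifnot(inherits(ca_trace, "mc_trace"))
  g <- ca_trace$grid
  tt <- g$times - g$t0
  kern <- c(0, green_function(params$d_ER_B, tt[-1], params$D_Ca))
  if (is.null(gain)) {
    # steady-state kernel mass: integral of the 3-D kernel over time
    mass <- 1 / (4 * pi * params$D_Ca * params$d_ER_B)
    gain <- params$uptake_efficiency / mass
  }
  v <- fast_conv(ca_trace$values, kern) * g$dt
  trace(g, pmax(v * gain, 0), units = "flux")
}

total_variation <- function(values) c(0, cumsum(abs(diff(values))))

#' Ca2+ relay delay
#'
#' Smallest Omega >= 0 such that the cumulative variation of the absorbed
#' neuron-side signal over [0, T + Omega] reaches the astrocyte-side target
#' variation over [0, T]. With `target = "per_astrocyte"` (default) the
#' target is one relayed signal's worth -- the mean per-astrocyte variation
#' -- so that absorption from several astrocytes shortens the delay; with
#' `"summed"` the target is the literal sum over astrocytes.
#'
#' @param astro_ca_traces list of cytoplasmic Ca2+ traces (common grid)
#' @param neuron_absorbed absorbed-signal [trace()] on the same grid
#' @param T slot length, s
#' @param target `"per_astrocyte"` or `"summed"`
#' @return list with `omega` (s), `reached` (logical; FALSE means the grid
#'   ended before the target was met and `omega` is the grid end)
#' @export
calcium_delay <- function(astro_ca_traces, neuron_absorbed, T,
                          target = c("per_astrocyte", "summed")) {
  target <- match.arg(target)
  g <- neuron_absorbed$grid
  for (a in astro_ca_traces)
    if (!same_grid(a$grid, g)) stop("traces must share one grid")
  tt <- g$times
  in_slot <- tt <= g$t0 + T + 1e-12
  tv_astro <- vapply(astro_ca_traces,
                     function(a) max(total_variation(a$values[in_slot])),
                     numeric(1))
  goal <- if (target == "summed") sum(tv_astro) else mean(tv_astro)
  cum_n <- total_variation(neuron_absorbed$values)
  idx <- bisect_first_geq(cum_n, goal)
  if (is.na(idx)) {
    return(list(omega = tt[length(tt)] - (g$t0 + T), reached = FALSE))
  }
  list(omega = max(tt[idx] - (g$t0 + T), 0), reached = TRUE)
}

# first index with x[i] >= goal on a nondecreasing vector, by bisection
bisect_first_geq <- function(x, goal) {
  n <- length(x)
  if (x[n] < goal) return(NA_integer_)
  lo <- 1L; hi <- n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (x[mid] >= goal) hi <- mid else lo <- mid + 1L
  }
  hi
}
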