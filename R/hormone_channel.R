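# Passive-diffusion hormone channel: free-space Green's function,
# concentration superposition, slot absorption probabilities, hormonal delay.

#' Hormone channel parameters
#'
#' @param D_H hormone diffusion coefficient, um^2/s (4.8 um^2/ms = 4800)
#' @param iota first-order degradation rate of hormone molecules, 1/s; the
#'   molecular life expectancy is exponential with mean 1/iota
#' @param distances Tx-to-astrocyte distances d_SA in um; if `NULL`, sampled
#'   later by the orchestrator uniformly in `distance_range`
#' @param distance_range range for random astrocyte placement, um
#' @param capture_efficiency per-molecule capture volume kappa (um^3) mapping
#'   the Green-function density integral to an absorption probability; `NULL`
#'   means calibrate with [calibrate_capture_efficiency()] defaults
#' @return object of class `mc_hormone_params`
#' @export
hormone_channel_params <- function(D_H = 4800, iota = 0.2, distances = NULL,
                                   distance_range = c(1, 20),
                                   capture_efficiency = NULL) {
  stopifnot(D_H > 0, iota >= 0)
  if (!is.null(distances) && any(distances <= 0))
    stop("astrocyte distances must be > 0")
  p <- list(D_H = D_H, iota = iota, distances = distances,
            distance_range = distance_range,
            capture_efficiency = capture_efficiency)
  class(p) <- "mc_hormone_params"
  if (is.null(p$capture_efficiency))
    p$capture_efficiency <- calibrate_capture_efficiency(p)
  p
}

#' Free-space 3-D diffusion Green's function
#'
#' Density (um^-3) at distance `d` and time `t` after a unit point release:
#' `(4 pi D t)^(-3/2) exp(-d^2 / (4 D t))`.
#'
#' @param d distance, um (>= 0)
#' @param t time since release, s (> 0; rejects t <= 0, the caller treats the
#'   off-origin limit as 0)
#' @param D_H diffusion coefficient, um^2/s
#' @return density in um^-3, vectorized over `d` and `t`
#' @export
green_function <- function(d, t, D_H) {
  if (any(t <= 0)) stop("green_function requires t > 0")
  if (any(d < 0)) stop("distance must be >= 0")
  (4 * pi * D_H * t)^(-1.5) * exp(-d^2 / (4 * D_H * t))
}

#' Hormone concentration trace at one astrocyte
#'
#' Superposition of per-event Green's functions with a multiplicative
#' degradation survival factor `exp(-iota * (t - t_event))`; zero before the
#' first event.
#'
#' @param schedule release events from [encode_ook()]
#' @param d Tx-astrocyte distance, um (> 0)
#' @param grid shared [time_grid()]
#' @param params [hormone_channel_params()]
#' @return an [trace()] in molecules/um^3
#' @export
concentration_at <- function(schedule, d, grid, params) {
  stopifnot(inherits(grid, "mc_grid"), d > 0)
  tt <- grid$times
  v <- numeric(length(tt))
  for (k in seq_len(nrow(schedule))) {
    dtk <- tt - schedule$time[k]
    live <- dtk > 0
    v[live] <- v[live] + schedule$quantity[k] *
      green_function(d, dtk[live], params$D_H) * exp(-params$iota * dtk[live])
  }
  trace(grid, v, units = "molecules/um^3")
}

raw_slot_integral <- function(n, T, d, params) {
  # per-molecule density integral over slot offset n, with survival factor
  # (inner integral of Eq-style life expectancy resolved as exp(-iota t))
  vapply(n, function(ni) {
    r <- tryCatch(
      integrate(function(t) green_function(d, t, params$D_H) *
                  exp(-params$iota * t),
                lower = ni * T, upper = (ni + 1) * T,
                rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L),
      error = function(e) stop("absorption quadrature failed (n=", ni,
                               ", d=", d, "): ", conditionMessage(e)))
    r$value
  }, numeric(1))
}

#' Calibrate the per-molecule capture efficiency
#'
#' Chooses kappa (um^3) so that the slot-0 detection probability -- at least
#' one of `Q0` released molecules absorbed -- equals `target` at the
#' reference geometry (d = 5 um, T = 10 s).
#'
#' @param params [hormone_channel_params()] (capture efficiency ignored)
#' @param d,T reference distance (um) and slot length (s)
#' @param Q0 reference number of released molecules
#' @param target desired slot-0 detection probability
#' @return kappa, um^3
#' @export
calibrate_capture_efficiency <- function(params, d = 5, T = 10, Q0 = 5000,
                                         target = 0.5) {
  raw0 <- raw_slot_integral(0, T, d, params)
  # small per-molecule probability q with 1-(1-q)^Q0 = target
  q <- 1 - (1 - target)^(1 / Q0)
  q / raw0
}

#' Per-molecule slot absorption probabilities u_n
#'
#' u_n is the probability that a molecule released at the start of slot 0
#' is absorbed by an astrocyte at distance `d` during slot `n`: the slot
#' integral of the Green's density times the degradation survival factor,
#' mapped to a probability by the capture volume kappa. If the raw
#' probabilities ever summed past 1 they are rescaled (capture cannot exceed
#' certainty).
#'
#' @param n slot offsets (vector of integers >= 0)
#' @param T slot length, s
#' @param d distance, um
#' @param params [hormone_channel_params()]
#' @return numeric vector of per-molecule probabilities
#' @export
absorption_probability <- function(n, T, d, params) {
  stopifnot(all(n >= 0), T > 0, d > 0)
  u <- params$capture_efficiency * raw_slot_integral(n, T, d, params)
  s <- sum(u)
  if (s > 1) u <- u / s
  u
}

#' Slot detection probabilities for a Q0-molecule release
#'
#' Probability that at least one of `Q0` independently diffusing molecules
#' is absorbed during slot offset n, by any of the listed astrocytes.
#'
#' @param Nb number of slots
#' @param T slot length, s
#' @param distances astrocyte distances, um
#' @param Q0 molecules per "1" bit
#' @param params [hormone_channel_params()]
#' @return vector u of length Nb (offsets 0..Nb-1)
#' @export
slot_detection_probs <- function(Nb, T, distances, Q0, params) {
  per <- vapply(distances, function(d) {
    u <- absorption_probability(0:(Nb - 1), T, d, params)
    1 - (1 - pmin(u, 1))^Q0
  }, numeric(Nb))
  per <- matrix(per, nrow = Nb)
  1 - apply(1 - per, 1, prod)
}

#' Mean hormonal propagation delay over one slot
#'
#' Weights candidate delays omega in (0, T] by
#' f(omega) = erf(sqrt(d^2/(4 D omega))) / sqrt(8 pi D omega), normalized on
#' (0, T], and returns the weighted mean delay.
#'
#' @param d Tx-astrocyte distance, um
#' @param T slot length, s
#' @param D_H diffusion coefficient, um^2/s
#' @return Omega_H in seconds
#' @export
hormonal_delay <- function(d, T, D_H) {
  stopifnot(d > 0, T > 0, D_H > 0)
  f <- function(w) erf(sqrt(d^2 / (4 * D_H * w))) / sqrt(8 * pi * D_H * w)
  z <- integrate(f, 0, T, rel.tol = 1e-9, abs.tol = 0)$value
  m <- integrate(function(w) w * f(w), 0, T, rel.tol = 1e-9, abs.tol = 0)$value
  m / z
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
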