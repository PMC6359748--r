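# End-to-end bit-error probabilities, binary channel transition assembly
# over the hormone -> Ca2+ -> spikes Markov chain, mutual information and
# capacity, and total transmission delay.

#' Binary entropy, base 2
#' @param x probability (vectorized)
#' @return -x log2 x - (1-x) log2(1-x), with 0 log 0 = 0
#' @export
binary_entropy <- function(x) {
  stopifnot(all(x >= 0), all(x <= 1))
  h <- function(v) ifelse(v > 0, -v * log2(v), 0)
  h(x) + h(1 - x)
}

#' Neural-stage bit error probabilities
#'
#' Combines the vesicle-release errors Pe1 and decoding errors Pe2 into the
#' neural transition errors, with the transmit probability p weighting both
#' terms of each expression:
#' P(1|0) = (1-p)(Pe1_0 (1-Pe2_1) + (1-Pe1_0) Pe2_0),
#' P(0|1) = p    (Pe1_1 (1-Pe2_0) + (1-Pe1_1) Pe2_1).
#'
#' @param p probability of transmitting "1"
#' @param pe1 named vector c(bit1=, bit0=) from [release_error_probs()]
#' @param pe2 list/vector with Pe2_bit0 and Pe2_bit1
#' @return named vector c(p10 = P(1|0), p01 = P(0|1))
#' @export
neural_bit_error <- function(p, pe1, pe2) {
  pe2_0 <- if (!is.null(pe2$Pe2_bit0)) pe2$Pe2_bit0 else pe2[["bit0"]]
  pe2_1 <- if (!is.null(pe2$Pe2_bit1)) pe2$Pe2_bit1 else pe2[["bit1"]]
  vals <- c(p, pe1[["bit1"]], pe1[["bit0"]], pe2_0, pe2_1)
  stopifnot(all(vals >= 0), all(vals <= 1))
  p10 <- (1 - p) * (pe1[["bit0"]] * (1 - pe2_1) +
                      (1 - pe1[["bit0"]]) * pe2_0)
  p01 <- p * (pe1[["bit1"]] * (1 - pe2_0) +
                (1 - pe1[["bit1"]]) * pe2_1)
  c(p10 = p10, p01 = p01)
}

#' Hormone relay transition probabilities
#'
#' With slot absorption probabilities u_0..u_{Nb-1} and transmit probability
#' p: P_i(1) = prod_{i=1..Nb-1} (1 - p u_i) is the probability that no
#' interfering earlier release is absorbed in the slot, and
#' Q_i(1) = 1 - (1 - u_0) P_i(1) the probability that the slot's own release
#' or an interferer is absorbed.
#'
#' @param p transmit probability
#' @param u vector of slot absorption/detection probabilities (offset 0 first)
#' @param Nb number of slots (defaults to length(u))
#' @return named vector c(P1 = P_i(1), Q1 = Q_i(1))
#' @export
hormone_relay_probs <- function(p, u, Nb = length(u)) {
  stopifnot(all(u >= 0), all(u <= 1), p >= 0, p <= 1, Nb >= 1,
            length(u) >= Nb)
  tail_u <- if (Nb >= 2) u[2:Nb] else numeric(0)
  P1 <- prod(1 - p * tail_u)
  c(P1 = P1, Q1 = 1 - (1 - u[1]) * P1)
}

#' Binary relay channel description
#'
#' Transition probabilities of the Markov chain X -> Y -> Z:
#' `y1_given_x0`, `y1_given_x1` (hormone/Ca2+ relay) and `z1_given_y0`,
#' `z0_given_y1` (neural stage).
#'
#' @param y1_given_x0,y1_given_x1,z1_given_y0,z0_given_y1 probabilities
#' @return object of class `mc_channel`
#' @export
channel_probs <- function(y1_given_x0, y1_given_x1, z1_given_y0,
                          z0_given_y1) {
  v <- c(y1_given_x0, y1_given_x1, z1_given_y0, z0_given_y1)
  stopifnot(all(v >= 0), all(v <= 1))
  structure(list(y1_given_x0 = y1_given_x0, y1_given_x1 = y1_given_x1,
                 z1_given_y0 = z1_given_y0, z0_given_y1 = z0_given_y1),
            class = "mc_channel")
}

#' Full joint distribution over (X, Y, Z)
#'
#' Assembled from P(X), P(Y|X) and P(Z|Y) under the Markov assumption that
#' given Y, X carries no further information about Z.
#'
#' @param p transmit probability P(X=1)
#' @param channel an [channel_probs()]
#' @return 2x2x2 array, dimensions (X, Y, Z), states (0, 1)
#' @export
channel_joint <- function(p, channel) {
  py1 <- c(channel$y1_given_x0, channel$y1_given_x1)
  pz1 <- c(channel$z1_given_y0, 1 - channel$z0_given_y1)
  jt <- array(0, c(2, 2, 2), dimnames = list(X = 0:1, Y = 0:1, Z = 0:1))
  for (x in 0:1) for (y in 0:1) for (z in 0:1) {
    px <- if (x == 1) p else 1 - p
    py <- if (y == 1) py1[x + 1] else 1 - py1[x + 1]
    pz <- if (z == 1) pz1[y + 1] else 1 - pz1[y + 1]
    jt[x + 1, y + 1, z + 1] <- px * py * pz
  }
  jt
}

entropy_bits <- function(pv) {
  pv <- pv[pv > 0]
  -sum(pv * log2(pv))
}

mi_of_margin <- function(m2) {
  entropy_bits(rowSums(m2)) + entropy_bits(colSums(m2)) - entropy_bits(c(m2))
}

#' Per-slot mutual information I(X;Z)
#'
#' Computed from the (X, Y, Z) joint. `decompose = TRUE` instead evaluates
#' the chain decomposition I(X;Y) - I(X;Y|Z) (which equals I(X;Z) for the
#' Markov chain); the two routes cross-check each other.
#'
#' @param p transmit probability
#' @param channel an [channel_probs()]
#' @param decompose use the entropy-decomposition route
#' @return mutual information in bits
#' @export
mutual_information <- function(p, channel, decompose = FALSE) {
  jt <- channel_joint(p, channel)
  if (!decompose) return(mi_of_margin(apply(jt, c(1, 3), sum)))
  ixy <- mi_of_margin(apply(jt, c(1, 2), sum))
  # I(X;Y|Z) = sum_z P(z) I(X;Y | Z=z)
  ixy_z <- 0
  for (z in 1:2) {
    pz <- sum(jt[, , z])
    if (pz > 0) ixy_z <- ixy_z + pz * mi_of_margin(jt[, , z] / pz)
  }
  ixy - ixy_z
}

#' I(X;Y) of the relay stage alone
#' @inheritParams mutual_information
#' @return bits
#' @export
relay_mutual_information <- function(p, channel) {
  jt <- channel_joint(p, channel)
  mi_of_margin(apply(jt, c(1, 2), sum))
}

#' Channel capacity over the transmit probability
#'
#' Maximizes the per-slot mutual information over p by grid search with
#' golden-section refinement around the best grid point.
#'
#' @param channel_fn function p -> [channel_probs()] (the transition
#'   probabilities may themselves depend on p through interference)
#' @param grid p values to scan
#' @return list with `C` (bits/slot) and `p_star`
#' @export
capacity <- function(channel_fn, grid = seq(0.01, 0.99, by = 0.01)) {
  f <- function(p) mutual_information(p, channel_fn(p))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  if (opt$objective >= vals[i]) list(C = opt$objective, p_star = opt$maximum)
  else list(C = vals[i], p_star = grid[i])
}

# ---- analytic chain capacity ------------------------------------------------

#' Steady-state effective per-spike release probability
#'
#' Mean RRP occupancy n-bar solves the balance between binomial release
#' demand lambda (1 - (1-p_v)^n) and per-vacancy refill (N_RRP - n)/tau_f;
#' the effective per-spike release probability is 1 - (1-p_v)^n-bar.
#' Grows with the pool size, shrinks with the refill time and (weakly) with
#' the firing rate.
#'
#' @param lambda_bar firing rate, Hz
#' @param pools [vesicle_pool_params()]
#' @return probability
#' @export
effective_release_probability <- function(lambda_bar, pools) {
  pv <- pools$p_v; N <- pools$N_RRP; tf <- pools$tau_f
  f <- function(n) lambda_bar * (1 - (1 - pv)^n) - (N - n) / tf
  nbar <- if (f(N) <= 0) N else uniroot(f, c(0, N), tol = 1e-10)$root
  1 - (1 - pv)^nbar
}

#' Analytic decoding error probabilities
#'
#' Poisson-count model of the decoder: a slot decodes "1" when the KS test
#' passes and the spike count reaches theta3 T. For "1" slots the pass
#' probability is 1 - alpha (test level); "0" slots carry too few spikes for
#' the test to reject.
#'
#' @param lambda1,lambda0 effective decoded rates for "1" and "0" slots, Hz
#' @param theta3 rate threshold, Hz
#' @param T slot length, s
#' @param alpha KS level
#' @return list with Pe2_bit0, Pe2_bit1
#' @export
decode_error_analytic <- function(lambda1, lambda0, theta3, T,
                                  alpha = 0.05) {
  kthr <- ceiling(theta3 * T)
  list(Pe2_bit0 = 1 - ppois(kthr - 1, lambda0 * T),
       Pe2_bit1 = alpha + (1 - alpha) * ppois(kthr - 1, lambda1 * T))
}

#' Analytic chain capacity for one parameter point
#'
#' Assembles the X -> Y -> Z transition probabilities from the hormone
#' channel (slot detection probabilities across the astrocyte population),
#' the vesicle stage (release errors at the effective per-spike release
#' probability, with spike exponent k = lambda-bar T_k over the release
#' assessment window) and the decoder (Poisson count model), then maximizes
#' mutual information over p.
#'
#' @param Q0 molecules per "1" bit
#' @param lambda_bar neural firing rate, Hz
#' @param distances astrocyte distances, um (length M_A)
#' @param pools [vesicle_pool_params()]
#' @param channel [hormone_channel_params()]
#' @param T slot length, s
#' @param Nb number of slots in the frame
#' @param T_k release assessment window, s
#' @param theta3_frac decoder threshold as a fraction of lambda_bar
#' @param lambda0_frac residual "0"-slot rate as a fraction of lambda_bar
#' @param alpha KS level
#' @return list with `C`, `p_star`, `u`, `P_eff`, `pe1`, `pe2`
#' @export
chain_capacity <- function(Q0 = 5000, lambda_bar = 20,
                           distances = c(5, 10, 15),
                           pools = vesicle_pool_params(),
                           channel = hormone_channel_params(),
                           T = 10, Nb = 8, T_k = 0.05,
                           theta3_frac = 0.5, lambda0_frac = 0.05,
                           alpha = 0.05) {
  u <- slot_detection_probs(Nb, T, distances, Q0, channel)
  P_eff <- effective_release_probability(lambda_bar, pools)
  k <- lambda_bar * T_k
  pe1 <- c(bit1 = 1 - P_eff^k, bit0 = P_eff^k)
  pe2 <- decode_error_analytic(lambda_bar, lambda0_frac * lambda_bar,
                               theta3_frac * lambda_bar, T, alpha)
  channel_fn <- function(p) {
    hv <- hormone_relay_probs(p, u, Nb)
    ne <- neural_bit_error(p, pe1, pe2)
    channel_probs(y1_given_x0 = 1 - hv[["P1"]], y1_given_x1 = hv[["Q1"]],
                  z1_given_y0 = ne[["p10"]], z0_given_y1 = ne[["p01"]])
  }
  cp <- capacity(channel_fn)
  c(cp, list(u = u, P_eff = P_eff, pe1 = pe1, pe2 = pe2))
}

# ---- delay ------------------------------------------------------------------

#' Total transmission delay report
#'
#' Omega = Omega_H + Omega_Ca + Omega_N with the neural term
#' Omega_N = N_N (omega + Omega_Ax): queueing wait plus axonal delay per
#' neuron hop.
#'
#' @param omega_H hormonal diffusion delay, s
#' @param omega_Ca calcium relay delay, s
#' @param omega_Ax axonal delay, s
#' @param omega_queue mean neurotransmitter queueing wait, s
#' @param N_N number of chained neurons
#' @return list of class `mc_delay_report` with all components and
#'   `omega_total`
#' @export
total_delay <- function(omega_H, omega_Ca, omega_Ax, omega_queue, N_N = 1) {
  v <- c(omega_H, omega_Ca, omega_Ax, omega_queue)
  if (any(v < 0)) stop("delay components must be >= 0")
  stopifnot(N_N >= 1)
  omega_N <- N_N * (omega_queue + omega_Ax)
  structure(list(omega_H = omega_H, omega_Ca = omega_Ca,
                 omega_Ax = omega_Ax, omega_queue = omega_queue,
                 omega_N = omega_N, N_N = N_N,
                 omega_total = omega_H + omega_Ca + omega_N),
            class = "mc_delay_report")
}

#' @export
print.mc_delay_report <- function(x, ...) {
  cat("<mc_delay_report>\n")
  cat(sprintf("  hormonal  Omega_H  = %.4g s\n", x$omega_H))
  cat(sprintf("  calcium   Omega_Ca = %.4g s\n", x$omega_Ca))
  cat(sprintf("  neural    Omega_N  = %.4g s (%d x (queue %.4g + axon %.4g))\n",
              x$omega_N, x$N_N, x$omega_queue, x$omega_Ax))
  cat(sprintf("  total     Omega    = %.4g s\n", x$omega_total))
  invisible(x)
}
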