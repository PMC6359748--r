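# Receiver: sample the postsynaptic waveform, re-estimate spike times,
# test Poissonness of the inter-spike intervals (KS), estimate the rate by
# maximum likelihood, and decide each bit.

#' Decoder parameters
#'
#' @param tau_s sampling interval, s (must be >= the grid dt)
#' @param N_sam samples per waveform window (even); the spike detector uses
#'   a centred rolling mean of N_sam samples
#' @param theta2 spike-presence threshold on the windowed sample mean; when
#'   `NULL`, defaults to 0.2 G_max at decode time
#' @param theta3 rate threshold, Hz; when `NULL`, defaults to half the
#'   nominal firing rate at decode time
#' @param alpha KS significance level
#' @param invert_threshold restore the literal low-mean-implies-spike
#'   criterion (off by default: postsynaptic amplitudes are positive, so
#'   spikes are where the windowed mean exceeds theta2)
#' @param literal_ks scale the KS statistic by the slot index rather than
#'   the conventional sqrt(sample size)
#' @return object of class `mc_decoder_params`
#' @export
decoder_params <- function(tau_s = 0.005, N_sam = 4, theta2 = NULL,
                           theta3 = NULL, alpha = 0.05,
                           invert_threshold = FALSE, literal_ks = FALSE) {
  stopifnot(tau_s > 0, N_sam >= 2, N_sam %% 2 == 0, alpha > 0, alpha < 1)
  if (!is.null(theta3)) stopifnot(theta3 >= 0)
  structure(as.list(environment()), class = "mc_decoder_params")
}

#' Sample a waveform at the decoder interval
#'
#' Values of the trace at multiples of tau_s (nearest grid point).
#'
#' @param y waveform [trace()]
#' @param params [decoder_params()]
#' @return data.frame with columns `time`, `value`
#' @export
sample_waveform <- function(y, params) {
  stopifnot(inherits(y, "mc_trace"))
  g <- y$grid
  if (params$tau_s < g$dt - 1e-12)
    stop("tau_s must be >= the grid dt")
  st <- seq(g$t0, g$t0 + g$duration, by = params$tau_s)
  idx <- round((st - g$t0) / g$dt) + 1
  idx <- pmin(pmax(idx, 1), grid_length(g))
  data.frame(time = g$times[idx], value = y$values[idx])
}

#' Detect spikes in sampled waveform values
#'
#' A centred rolling mean over `N_sam` samples is compared against theta2;
#' each maximal run of supra-threshold samples yields one spike at the
#' position of its largest sample. Runs are separated by at least one
#' sub-threshold sample, so detections are at least tau_s apart.
#'
#' @param samples data.frame from [sample_waveform()]
#' @param params [decoder_params()]
#' @param G_max reference amplitude for the default theta2
#' @return estimated spike times, class `mc_spikes`
#' @export
detect_spikes <- function(samples, params, G_max = 1) {
  v <- samples$value
  n <- length(v)
  theta2 <- if (is.null(params$theta2)) 0.2 * G_max else params$theta2
  k <- params$N_sam
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  win_mean <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  above <- if (params$invert_threshold) win_mean < theta2
           else win_mean > theta2
  if (!any(above)) return(structure(numeric(0), class = "mc_spikes"))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- numeric(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    out <- c(out, samples$time[seg[which.max(v[seg])]])
  }
  structure(out, class = "mc_spikes")
}

# Kolmogorov distribution upper quantile: P(K <= k_alpha) = 1 - alpha
kolmogorov_quantile <- function(alpha) {
  surv <- function(x) {
    k <- 1:100
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  }
  uniroot(function(x) surv(x) - alpha, c(0.2, 3), tol = 1e-10)$root
}

#' KS test of slot Poissonness with MLE rate
#'
#' The slot rate is estimated as lambda' = count / T (Poisson MLE); the
#' inter-spike intervals are compared against Exp(lambda') with a one-sample
#' KS statistic. Poissonness is accepted when the scaled statistic
#' sqrt(m) K_m stays below the Kolmogorov critical value at level alpha
#' (with the estimated rate this is conservative: true rejection rates run
#' below alpha). Fewer than 2 spikes makes the test vacuous (pass, flagged).
#'
#' @param est_spikes estimated spike times, s
#' @param slot c(start, T): slot start and length, s
#' @param params [decoder_params()]
#' @return list: `statistic` (raw KS distance), `scaled`, `critical`,
#'   `passes`, `lambda_mle` (Hz), `n` (spikes in slot), `vacuous`
#' @export
ks_poisson_test <- function(est_spikes, slot, params) {
  start <- slot[1]; T <- slot[2]
  stopifnot(T > 0)
  tt <- as.numeric(est_spikes)
  tt <- tt[tt >= start & tt < start + T]
  n <- length(tt)
  lambda <- n / T
  if (n < 2) {
    return(list(statistic = NA_real_, scaled = NA_real_,
                critical = kolmogorov_quantile(params$alpha),
                passes = TRUE, lambda_mle = lambda, n = n, vacuous = TRUE))
  }
  iv <- diff(sort(tt))
  m <- length(iv)
  fx <- sort(stats::pexp(iv, rate = lambda))
  d <- max(pmax(seq_len(m) / m - fx, fx - (seq_len(m) - 1) / m))
  scale_factor <- if (params$literal_ks) m else sqrt(m)
  crit <- kolmogorov_quantile(params$alpha)
  list(statistic = d, scaled = scale_factor * d, critical = crit,
       passes = scale_factor * d <= crit, lambda_mle = lambda, n = n,
       vacuous = FALSE)
}

#' Decode one slot to a bit
#'
#' "1" iff Poissonness is not rejected and the MLE rate reaches theta3.
#'
#' @param est_spikes estimated spike times
#' @param slot c(start, T)
#' @param params [decoder_params()]
#' @param theta3 rate threshold override, Hz
#' @return list: `bit`, `lambda_mle`, `ks` (the [ks_poisson_test()] result)
#' @export
decode_bit <- function(est_spikes, slot, params, theta3 = NULL) {
  if (is.null(theta3)) theta3 <- params$theta3
  if (is.null(theta3)) stop("theta3 must be set (decoder_params or argument)")
  ks <- ks_poisson_test(est_spikes, slot, params)
  list(bit = as.integer(ks$passes && ks$lambda_mle >= theta3),
       lambda_mle = ks$lambda_mle, ks = ks)
}

#' Monte-Carlo decoding error probabilities of the synapse + decoder stages
#'
#' Simulates `n_reps` independent slots carrying "1" (Poisson spikes at
#' `lambda1`) and "0" (rate `lambda0`), passes them through vesicle release,
#' postsynaptic synthesis and the decoder, and reports
#' P(decode 1 | sent 0) and P(decode 0 | sent 1) with binomial standard
#' errors.
#'
#' @param lambda1,lambda0 slot firing rates for "1" and "0" bits, Hz
#' @param T slot length, s
#' @param pools [vesicle_pool_params()]
#' @param psp [postsynaptic_params()]
#' @param dec [decoder_params()] with theta3 set
#' @param p_release per-spike release probability; default
#'   [release_probability()] at lambda1
#' @param n_reps replicates per bit value (>= 100)
#' @param rng [rng_handle()]
#' @param dt simulation grid step, s
#' @return list with `Pe2_bit0`, `Pe2_bit1` and standard errors
#' @export
decode_error_probs <- function(lambda1, lambda0, T, pools, psp, dec,
                               p_release = NULL, n_reps = 200, rng,
                               dt = 0.005) {
  stopifnot(n_reps >= 100)
  if (is.null(p_release)) p_release <- release_probability(lambda1, pools)
  grid <- time_grid(T, dt = dt)
  one <- function(lam, i, sent) {
    sub <- rng_handle(stream_seed(rng$seed, paste0("pe2-", sent, "-", i)))
    rate <- trace(grid, rep(lam, grid_length(grid)), "Hz")
    sp <- generate_spikes(rate, sub, label = "spikes")
    rel <- simulate_release(sp, pools, sub, p_release = p_release)
    y <- psp_waveform(rel$release_times, psp, grid, sub)
    est <- detect_spikes(sample_waveform(y, dec), dec, G_max = psp$G_max)
    decode_bit(est, c(0, T), dec)$bit
  }
  d1 <- vapply(seq_len(n_reps), function(i) one(lambda1, i, "1"), numeric(1))
  d0 <- vapply(seq_len(n_reps), function(i) one(lambda0, i, "0"), numeric(1))
  pe1 <- mean(d1 == 0)   # sent 1, decoded 0
  pe0 <- mean(d0 == 1)   # sent 0, decoded 1
  list(Pe2_bit0 = pe0, Pe2_bit1 = pe1,
       Pe2_bit0_se = sqrt(pe0 * (1 - pe0) / n_reps),
       Pe2_bit1_se = sqrt(pe1 * (1 - pe1) / n_reps))
}
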