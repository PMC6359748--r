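#' mcchain: chain molecular-communication simulator
#'
#' Binary information is on-off keyed onto hormone release, diffuses to
#' astrocytes, is relayed through IP3-gated Ca2+ oscillations into neural
#' spike trains, crosses an axon and a chemical synapse, and is decoded from
#' the postsynaptic waveform. The package also carries the analytic channel
#' capacity and transmission-delay layer for parameter sweeps.
#'
#' Internal unit system: seconds, micrometres, micromolar, millivolts.
#' Diffusion coefficients quoted in um^2/ms are converted once at parameter
#' construction (4.8 um^2/ms = 4800 um^2/s).
#'
#' @keywords internal
#' @importFrom stats approx approxfun convolve dgamma integrate ks.test
#'   optimize ppois rbinom rexp rgamma rgeom rpois runif uniroot
#' @importFrom utils modifyList write.table
"_PACKAGE"

# ---- time grid and traces ---------------------------------------------------

#' Uniform simulation time grid
#'
#' All traces of one run share a single grid; stage outputs are checked
#' against it by identity of (t0, duration, dt).
#'
#' @param duration total length in seconds; must be an integer multiple of dt
#' @param dt step in seconds
#' @param t0 start time in seconds
#' @return an object of class `mc_grid` with fields `t0`, `duration`, `dt`
#'   and the sampled `times` (length `duration/dt + 1`)
#' @export
time_grid <- function(duration, dt = 0.01, t0 = 0) {
  stopifnot(dt > 0, duration > 0)
  n <- duration / dt
  if (abs(n - round(n)) > 1e-8)
    stop("duration must be an integer multiple of dt")
  n <- round(n)
  structure(list(t0 = t0, duration = duration, dt = dt,
                 times = t0 + dt * (0:n)),
            class = "mc_grid")
}

#' Number of samples on a time grid
#' @param grid an [time_grid()] object
#' @return integer, `duration/dt + 1`
#' @export
grid_length <- function(grid) length(grid$times)

same_grid <- function(a, b) {
  isTRUE(all.equal(a$t0, b$t0)) && isTRUE(all.equal(a$duration, b$duration)) &&
    isTRUE(all.equal(a$dt, b$dt))
}

#' Uniformly sampled trace on a time grid
#'
#' @param grid an [time_grid()] object
#' @param values numeric vector, one value per grid time
#' @param units unit tag ("uM", "mV", "molecules/um^3", "Hz", "arbitrary")
#' @return an object of class `mc_trace`
#' @export
trace <- function(grid, values, units = "arbitrary") {
  stopifnot(inherits(grid, "mc_grid"))
  if (length(values) != grid_length(grid))
    stop("trace length must equal duration/dt + 1")
  if (!all(is.finite(values))) stop("trace values must be finite")
  structure(list(grid = grid, values = as.numeric(values), units = units),
            class = "mc_trace")
}

#' @export
print.mc_trace <- function(x, ...) {
  cat(sprintf("<mc_trace> %d samples over %.4g s (dt = %.4g s), units: %s\n",
              grid_length(x$grid), x$grid$duration, x$grid$dt, x$units))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.mc_grid <- function(x, ...) {
  cat(sprintf("<mc_grid> t0 = %g s, duration = %g s, dt = %g s (%d samples)\n",
              x$t0, x$duration, x$dt, grid_length(x)))
  invisible(x)
}

# ---- bits and OOK encoding --------------------------------------------------

#' Binary information sequence
#'
#' @param bits vector coercible to 0/1 symbols (integer vector or a string
#'   such as "1011")
#' @param p probability of transmitting "1" (kept as metadata for generated
#'   sequences)
#' @return integer vector of class `mc_bits` with attribute `p`
#' @export
bit_sequence <- function(bits, p = NA_real_) {
  if (is.character(bits) && length(bits) == 1)
    bits <- as.integer(strsplit(bits, "")[[1]])
  bits <- as.integer(bits)
  if (length(bits) == 0) stop("bit sequence must be nonempty")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("bits must be binary symbols in {0,1}")
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must lie in [0,1]")
  structure(bits, p = p, class = "mc_bits")
}

#' On-off keying of a bit sequence into hormone release events
#'
#' Each "1" bit in slot i releases `Q0` molecules as an impulse at time
#' `i * T`; "0" bits release nothing. Impulses are kept as exact (time,
#' quantity) events rather than grid spikes so the diffusion channel can
#' superpose Green's functions exactly.
#'
#' @param bits a [bit_sequence()] (or anything it accepts)
#' @param Q0 molecules released per "1" bit, > 0
#' @param T slot length in seconds, > 0
#' @return data.frame of class `mc_schedule` with columns `time`, `quantity`
#' @examples
#' encode_ook("1011", Q0 = 5000, T = 10)
#' @export
encode_ook <- function(bits, Q0, T) {
  stopifnot(Q0 > 0, T > 0)
  bits <- bit_sequence(bits)
  i <- which(bits == 1L) - 1L
  sched <- data.frame(time = i * T, quantity = rep(Q0, length(i)))
  class(sched) <- c("mc_schedule", "data.frame")
  sched
}

release_schedule <- function(times, quantities) {
  if (length(times) && (any(diff(times) <= 0)))
    stop("release times must be strictly increasing")
  if (any(quantities <= 0)) stop("release quantities must be > 0")
  sched <- data.frame(time = times, quantity = quantities)
  class(sched) <- c("mc_schedule", "data.frame")
  sched
}

# ---- trace utilities --------------------------------------------------------

#' Count well-separated waves (local maxima) in a trace
#'
#' A wave is a local maximum whose height exceeds `threshold`; maxima closer
#' than `min_separation` are merged, keeping the highest.
#'
#' @param x an [trace()] object
#' @param threshold absolute height threshold, same units as the trace
#' @param min_separation minimum distance between counted maxima, seconds
#' @return integer count of waves
#' @export
count_waves <- function(x, threshold, min_separation) {
  stopifnot(inherits(x, "mc_trace"))
  if (threshold < 0) stop("threshold must be >= 0")
  if (min_separation < x$grid$dt) stop("min_separation must be >= dt")
  v <- x$values
  n <- length(v)
  if (n < 3) return(0L)
  # local maxima; ">= " on the right edge tolerates flat-topped peaks
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] > threshold]
  if (!length(cand)) return(0L)
  # greedy merge by descending height
  ord <- cand[order(v[cand], decreasing = TRUE)]
  tt <- x$grid$times
  kept <- numeric(0)
  for (i in ord) {
    if (!length(kept) || all(abs(tt[i] - kept) >= min_separation))
      kept <- c(kept, tt[i])
  }
  length(kept)
}

#' Trapezoid integral of a trace
#' @param x an [trace()] object
#' @param from,to integration limits in seconds (defaults: whole grid)
#' @return numeric integral value
#' @export
trace_integral <- function(x, from = NULL, to = NULL) {
  stopifnot(inherits(x, "mc_trace"))
  tt <- x$grid$times
  v <- x$values
  if (!is.null(from) || !is.null(to)) {
    from <- if (is.null(from)) tt[1] else from
    to <- if (is.null(to)) tt[length(tt)] else to
    keep <- tt >= from - 1e-12 & tt <= to + 1e-12
    tt <- tt[keep]; v <- v[keep]
  }
  if (length(tt) < 2) return(0)
  sum((v[-1] + v[-length(v)]) / 2 * diff(tt))
}

# ---- reproducible random streams --------------------------------------------

#' Root random-number handle with labelled substreams
#'
#' One root seed spawns independent, reproducible streams per stage
#' ("firing", "release", "queue", "amplitude", ...): the substream seed is a
#' polynomial hash of the label folded into the root seed, so the same
#' (seed, label) pair always yields the same draws regardless of what other
#' stages consumed.
#'
#' @param seed integer root seed
#' @return object of class `mc_rng`
#' @export
rng_handle <- function(seed) {
  structure(list(seed = as.integer(seed)), class = "mc_rng")
}

stream_seed <- function(seed, label) {
  h <- 17
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 2654435 + h) %% 2147483629)
}

#' Evaluate code under a labelled random stream
#'
#' Saves and restores the global RNG state, so stage draws do not interfere.
#'
#' @param rng an [rng_handle()]
#' @param label stream label (text)
#' @param code expression to evaluate
#' @return value of `code`
#' @export
with_stream <- function(rng, label, code) {
  stopifnot(inherits(rng, "mc_rng"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(rng$seed, label))
  code
}

#' Draw a Bernoulli bit sequence
#'
#' @param n number of bits
#' @param p probability of "1"
#' @param rng an [rng_handle()]
#' @param label stream label, default "bits"
#' @return a [bit_sequence()]
#' @export
random_bits <- function(n, p, rng, label = "bits") {
  stopifnot(n >= 1, p >= 0, p <= 1)
  bits <- with_stream(rng, label, rbinom(n, 1L, p))
  bit_sequence(bits, p = p)
}

# ---- plain-text export ------------------------------------------------------

#' Write a trace as two-column delimited text
#'
#' One-line header names the units; columns are time (s) and value.
#' @param x an [trace()] object
#' @param path output file
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "mc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_s\tvalue_%s", gsub("[^A-Za-z0-9/^_.-]", "", x$units)), con)
  write.table(data.frame(time = x$grid$times, value = x$values), con,
              sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a spike train as one event time per line
#' @param times numeric spike times (seconds)
#' @param path output file
#' @export
write_spike_train <- function(times, path) {
  writeLines(c("# spike_time_s", format(times, digits = 12)), path)
  invisible(path)
}

# linear convolution of two equal-grid signals via zero-padded FFT
# (padded to a highly composite length: stats::convolve uses the raw
# length, which can hit slow FFT sizes)
fast_conv <- function(x, kern) {
  n <- length(x)
  m <- stats::nextn(2L * n, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(m - n)))
  kf <- stats::fft(c(kern, numeric(m - length(kern))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / m
}
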