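# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: brute-force sums, fixed-step quadrature,
# explicit finite differences, and direct distribution enumeration.

# fixed-step trapezoid quadrature at caller-chosen resolution
trapz_oracle <- function(f, lower, upper, n = 20000) {
  x <- seq(lower, upper, length.out = n + 1)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2) * (upper - lower) / n
}

# O(n^2) direct convolution sum: (f * k)[i] = dt * sum_j k[j] f[i - j + 1]
brute_conv <- function(f, kern, dt) {
  n <- length(f)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    out[i] <- sum(kern[j] * f[i - j + 1]) * dt
  }
  out
}

# explicit finite-difference solver of the cable equation
# Vt = -V / tau_m + D_ax Vxx with sealed (Neumann) ends
fd_cable <- function(V0_profile, params, t_out, nx = 200) {
  tau_m <- params$gamma_m * params$gamma_c * 1e-3
  tau_diff <- params$L_N^2 * params$gamma_l * params$gamma_c * 1e-3
  D_ax <- params$L_N^2 / tau_diff
  dx <- params$L_N / nx
  x <- seq(0, params$L_N, by = dx)
  v <- V0_profile(x)
  dt <- 0.2 * dx^2 / D_ax
  t_now <- 0
  out <- matrix(NA_real_, nrow = length(t_out), ncol = length(x))
  for (k in seq_along(t_out)) {
    while (t_now < t_out[k] - 1e-12) {
      step <- min(dt, t_out[k] - t_now)
      vl <- c(v[2], v[1:nx])               # left neighbour (reflect at 0)
      vr <- c(v[2:(nx + 1)], v[nx])        # right neighbour (reflect at L)
      lap <- (vl - 2 * v + vr) / dx^2
      v <- v + step * (-v / tau_m + D_ax * lap)
      t_now <- t_now + step
    }
    out[k, ] <- v
  }
  list(x = x, v = out)
}

# mutual information of a 2x2 joint by direct definition
mi_table_oracle <- function(m2) {
  px <- rowSums(m2); pz <- colSums(m2)
  s <- 0
  for (i in 1:2) for (j in 1:2)
    if (m2[i, j] > 0) s <- s + m2[i, j] * log2(m2[i, j] / (px[i] * pz[j]))
  s
}

# assemble the (X,Z) table of the two-stage binary relay channel by
# explicit enumeration over Y
xz_table_oracle <- function(p, ch) {
  py1 <- c(ch$y1_given_x0, ch$y1_given_x1)
  pz1 <- c(ch$z1_given_y0, 1 - ch$z0_given_y1)
  m <- matrix(0, 2, 2)
  for (x in 0:1) for (y in 0:1) for (z in 0:1) {
    pr <- (if (x == 1) p else 1 - p) *
      (if (y == 1) py1[x + 1] else 1 - py1[x + 1]) *
      (if (z == 1) pz1[y + 1] else 1 - pz1[y + 1])
    m[x + 1, z + 1] <- m[x + 1, z + 1] + pr
  }
  m
}

# cache for expensive chain runs shared between test files
.chain_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.chain_cache[[key]])) .chain_cache[[key]] <- maker()
  .chain_cache[[key]]
}

run_fig4_1011 <- function() cached_run("fig4_1011", function()
  run_chain(chain_config(bits = "1011", seed = 7, distances = c(5, 10, 15),
                         profile = "high_snr"), compute_delay = FALSE))

run_fig4_1111 <- function() cached_run("fig4_1111", function()
  run_chain(chain_config(bits = "1111", seed = 7, distances = c(5, 10, 15),
                         profile = "high_snr"), compute_delay = FALSE))
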