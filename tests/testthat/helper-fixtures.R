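# Shared fixtures and independent oracles, built in code at test time.

# decaying positive random kernel; well-conditioned lower-triangular H
rand_kernel <- function(support, delay = 0L, dt = 0.1, seed = 1L,
                        normalize = TRUE) {
  set.seed(seed)
  body <- stats::runif(support - delay, 0.2, 1) * exp(-(seq_len(support - delay) - 1) / 3)
  impulse_response(c(rep(0, delay), body), dt = dt, normalize = normalize,
                   n0_delay = delay)
}

# brute-force causal convolution: direct double loop over the defining sum
conv_oracle <- function(u, hh) {
  N <- length(u)
  y <- numeric(N)
  for (k in seq_len(N)) {
    for (j in seq_len(min(k, length(hh)))) {
      y[k] <- y[k] + hh[j] * u[k - j + 1L]
    }
  }
  y
}

# explicit normal-equations Tikhonov solve via small-matrix inversion
tikhonov_oracle <- function(yv, h, gamma, reg_kind) {
  N <- length(yv)
  H <- as.matrix(convolution_operator(h, N))
  Q <- build_regularizer(reg_kind, N)
  solve(crossprod(H) + gamma * crossprod(Q), crossprod(H, yv))[, 1L]
}

# dense single-window reconstruction map M = L (L'H'HL)^-1 L'H'
dr_M_oracle <- function(h, N, m) {
  H <- as.matrix(convolution_operator(h, N))
  L <- as.matrix(build_projection(N, m))
  G <- H %*% L
  L %*% solve(crossprod(G), t(G))
}

# lower shift matrix: (P y) moves entries down one slot, zero-filling the top
shift_down_matrix <- function(N) {
  P <- matrix(0, N, N)
  P[cbind(2:N, 1:(N - 1L))] <- 1
  P
}

# averaged reconstruction map assembled explicitly from shifted copies of M
dr_Mbar_oracle <- function(h, N, m) {
  M <- dr_M_oracle(h, N, m)
  P <- shift_down_matrix(N)
  acc <- matrix(0, N, N)
  Pk <- diag(N)
  for (k in seq_len(m)) {
    acc <- acc + t(Pk) %*% M %*% Pk
    Pk <- P %*% Pk
  }
  acc / m
}

# literal shift-solve-shift-average loop with dense least squares
dr_shiftloop_oracle <- function(yv, h, m) {
  N <- length(yv)
  H <- as.matrix(convolution_operator(h, N))
  L <- as.matrix(build_projection(N, m))
  G <- H %*% L
  acc <- numeric(N)
  for (k in seq_len(m)) {
    yk <- if (k == 1L) yv else c(rep(0, k - 1L), yv[seq_len(N - k + 1L)])
    u <- as.numeric(L %*% qr.solve(G, yk))
    if (k > 1L) u <- c(u[k:N], rep(0, k - 1L))
    acc <- acc + u
  }
  acc / m
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-300)

total_variation <- function(x) sum(abs(diff(x)))

# small noiseless pulse-train instance used across solver tests; the pulse
# train is placed (and if needed sped up) to fit inside the record
pulse_instance <- function(N = 2000L, support = 30L, delay = 0L, dt = 0.1,
                           frequency = 0.5, noise = 0, seed = 1L) {
  h <- rand_kernel(support, delay = delay, dt = dt, seed = seed)
  span <- N * dt
  cfg <- pulse_train_config(frequency = max(frequency, 2.8 / span),
                            start_time = 0.1 * span)
  u <- synth_pulse_train(cfg, N, dt)
  y <- forward_convolve(u, h)
  if (noise > 0) y <- add_noise(y, noise, seed = seed + 1000L)
  list(u = u, y = y, h = h)
}

# kernel whose mass decays slowly across its whole support, so the look-ahead
# overlap genuinely matters in the sequential scheme
slow_kernel <- function(support = 30L, dt = 0.1, seed = 2L) {
  set.seed(seed)
  impulse_response(stats::runif(support, 0.5, 1) * exp(-(seq_len(support) - 1) / 15),
                   dt = dt, normalize = TRUE)
}
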