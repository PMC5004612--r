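#' Uniformly sampled signal
#'
#' Container for a uniformly sampled time series. Sample \code{k} (0-based)
#' represents the average of the underlying continuous signal over the
#' half-open interval \code{[t0 + k*dt, t0 + (k+1)*dt)}.
#'
#' @param values numeric vector of samples (non-empty, finite).
#' @param dt sampling interval in seconds (strictly positive).
#' @param t0 time of the first sample in seconds.
#' @return An object of class \code{"resp_ts"}: a list with elements
#'   \code{values}, \code{dt} and \code{t0}.
#' @examples
#' y <- resp_ts(sin(seq(0, 2 * pi, length.out = 50)), dt = 0.1)
#' length(y$values)
#' @export
resp_ts <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  structure(list(values = values, dt = dt, t0 = t0), class = "resp_ts")
}

#' @export
print.resp_ts <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("Uniform time series: %d samples at dt = %g s (%.6g s total), t0 = %g s\n",
              n, x$dt, n * x$dt, x$t0))
  cat("values: ", paste(signif(utils::head(x$values, 6), 5), collapse = ", "),
      if (n > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.resp_ts <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param x a \code{resp_ts}.
#' @return numeric vector of sample times (left edge of each sampling bin).
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "resp_ts"))
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

# coerce numeric / resp_ts to plain values, checking dt compatibility
.ts_values <- function(x, dt = NULL) {
  if (inherits(x, "resp_ts")) {
    if (!is.null(dt) && abs(x$dt - dt) > 1e-8 * dt)
      stop("sampling-interval mismatch: series dt = ", x$dt, ", expected ", dt)
    x$values
  } else {
    as.numeric(x)
  }
}

#' Discrete impulse response of a linear measurement system
#'
#' The finite-support kernel \code{h} holds, per sampling bin, the integral of
#' the continuous impulse response over that bin. A transport delay appears as
#' leading zeros: \code{n0_delay} counts them. Leading samples whose magnitude
#' is at most \code{zero_tol * max(abs(h))} are treated as baseline noise,
#' forced to exact zero, and counted into the delay.
#'
#' @param h numeric kernel weights, one per sampling bin.
#' @param dt sampling interval, seconds.
#' @param normalize if \code{TRUE}, scale so that \code{sum(h) == 1} (a
#'   unit-area kernel conserves total signal).
#' @param n0_delay optional explicit count of leading zero samples; when
#'   \code{NULL} it is detected with \code{zero_tol}.
#' @param zero_tol relative threshold for delay detection.
#' @return An object of class \code{"impulse_response"} with elements
#'   \code{h}, \code{dt}, \code{n0_delay}, \code{support_len}.
#' @seealso [discretize_impulse_response()] to build one from a recorded
#'   calibration pulse, [synth_impulse_response()] for a synthetic chamber
#'   washout kernel.
#' @export
impulse_response <- function(h, dt, normalize = FALSE, n0_delay = NULL,
                             zero_tol = 1e-3) {
  h <- as.numeric(h)
  if (length(h) == 0L || !all(is.finite(h))) stop("'h' must be non-empty and finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be positive")
  hmax <- max(abs(h))
  if (hmax == 0) stop("degenerate kernel: all-zero impulse response")
  if (is.null(n0_delay)) {
    below <- abs(h) <= zero_tol * hmax
    n0_delay <- if (all(below)) length(h) else which(!below)[1L] - 1L
  }
  n0_delay <- as.integer(n0_delay)
  if (n0_delay < 0L || n0_delay >= length(h))
    stop("'n0_delay' must be in [0, length(h) - 1]")
  if (n0_delay > 0L) h[seq_len(n0_delay)] <- 0
  if (normalize) {
    s <- sum(h)
    if (abs(s) < 1e-300) stop("degenerate kernel: zero total area, cannot normalize")
    h <- h / s
  }
  structure(list(h = h, dt = dt, n0_delay = n0_delay,
                 support_len = length(h)),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("Impulse response: support %d samples (%.4g s) at dt = %g s\n",
              x$support_len, x$support_len * x$dt, x$dt))
  cat(sprintf("  delay: %d samples (%.4g s); sum(h) = %.6g\n",
              x$n0_delay, x$n0_delay * x$dt, sum(x$h)))
  invisible(x)
}

#' Discretize a recorded calibration pulse into an impulse response
#'
#' Converts a recorded response to a short calibration injection into a
#' discrete kernel: each bin weight approximates the integral of the
#' continuous impulse response over one sampling interval. The rectangle rule
#' (\code{sample * dt}) is the default; a trapezoid variant averages
#' neighbouring samples before scaling. The kernel support ends where the
#' recording ends, so record until the signal has fully vanished.
#'
#' @param raw the recorded response: a \code{resp_ts}, or a two-column
#'   matrix/data frame (time, value) with a uniform time column.
#' @param normalize scale the kernel to unit sum (default \code{TRUE}).
#' @param method quadrature rule, \code{"rectangle"} or \code{"trapezoid"}.
#' @param zero_tol relative threshold below which leading samples count as
#'   transport delay.
#' @return An [impulse_response()].
#' @examples
#' raw <- resp_ts(exp(-(0:199) * 0.1 / 2), dt = 0.1)
#' h <- discretize_impulse_response(raw)
#' sum(h$h)
#' @export
discretize_impulse_response <- function(raw, normalize = TRUE,
                                        method = c("rectangle", "trapezoid"),
                                        zero_tol = 1e-3) {
  method <- match.arg(method)
  if (!inherits(raw, "resp_ts")) {
    raw <- as.matrix(raw)
    if (ncol(raw) < 2L) stop("'raw' needs two columns: time and value")
    tt <- raw[, 1L]
    steps <- diff(tt)
    if (length(steps) == 0L) stop("'raw' needs at least two samples")
    dt <- stats::median(steps)
    if (any(abs(steps - dt) > 1e-6 * dt))
      stop("non-uniform sampling in 'raw': time steps deviate from dt = ", dt)
    raw <- resp_ts(raw[, 2L], dt = dt, t0 = tt[1L])
  }
  v <- raw$values
  if (max(abs(v)) == 0) stop("degenerate kernel: recorded response is all zero")
  h <- switch(method,
    rectangle = v * raw$dt,
    trapezoid = c((v[-length(v)] + v[-1L]) / 2, v[length(v)]) * raw$dt)
  impulse_response(h, dt = raw$dt, normalize = normalize, zero_tol = zero_tol)
}

#' Lower-triangular Toeplitz forward convolution operator
#'
#' Builds the causal forward map H with (0-based) entries
#' \code{H[i, j] = h[i - j]} for \code{0 <= i - j < support_len} and zero
#' otherwise, so that \code{H \%*\% u} is the discrete convolution of the
#' input with the kernel, truncated to \code{N} samples. A dense realization
#' is available up to \code{dense_cap}; matrix-free application through
#' [forward_convolve()] works for any \code{N}.
#'
#' @param h an [impulse_response()].
#' @param N output length (positive integer).
#' @param dense_cap largest N for which [as.matrix()] materializes the dense
#'   operator.
#' @return An object of class \code{"conv_op"}.
#' @examples
#' h <- impulse_response(c(1, 0.5), dt = 1)
#' H <- as.matrix(convolution_operator(h, 3))
#' H[2, 1]  # == 0.5
#' @export
convolution_operator <- function(h, N, dense_cap = 20000L) {
  stopifnot(inherits(h, "impulse_response"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  structure(list(h = h, N = as.integer(N), dense_cap = as.integer(dense_cap)),
            class = "conv_op")
}

#' @export
as.matrix.conv_op <- function(x, ...) {
  N <- x$N
  if (N > x$dense_cap)
    stop("dense realization refused for N = ", N, " > cap ", x$dense_cap,
         "; use forward_convolve() (matrix-free) instead")
  hh <- x$h$h
  H <- matrix(0, N, N)
  for (j in seq_len(N)) {
    len <- min(length(hh), N - j + 1L)
    if (len > 0L) H[j:(j + len - 1L), j] <- hh[seq_len(len)]
  }
  H
}

#' @export
print.conv_op <- function(x, ...) {
  cat(sprintf("Convolution operator: %d x %d lower-triangular Toeplitz, kernel support %d\n",
              x$N, x$N, x$h$support_len))
  invisible(x)
}

#' Apply the forward convolution model
#'
#' Computes the causal discrete convolution \code{y(k) = sum_j h(j) u(k - j)},
#' with inputs before time zero assumed zero, truncated to the input length.
#' This is the matrix-free equivalent of multiplying by the dense operator of
#' [convolution_operator()].
#'
#' @param u input signal: a \code{resp_ts} (its \code{dt} must match the
#'   kernel's) or a plain numeric vector.
#' @param h an [impulse_response()].
#' @return A signal of the same length and type as \code{u}.
#' @examples
#' h <- impulse_response(c(0.6, 0.3, 0.1), dt = 0.1)
#' forward_convolve(c(1, rep(0, 4)), h)  # reproduces the kernel
#' @export
forward_convolve <- function(u, h) {
  stopifnot(inherits(h, "impulse_response"))
  uv <- .ts_values(u, dt = h$dt)
  N <- length(uv)
  s <- h$support_len
  if (s == 1L) {
    y <- h$h * uv
  } else {
    padded <- c(rep(0, s - 1L), uv)
    y <- as.numeric(stats::filter(padded, h$h, method = "convolution", sides = 1L))
    y <- y[s:(s + N - 1L)]
  }
  if (inherits(u, "resp_ts")) resp_ts(y, dt = u$dt, t0 = u$t0) else y
}

#' Roughness-penalty (regularization) operators
#'
#' Penalty matrix Q used in Tikhonov-type objectives
#' \code{||H u - y||^2 + gamma ||Q u||^2}. All three choices are
#' lower-triangular Toeplitz: the identity penalizes solution size, the first
#' difference (first column \code{(1, -1, 0, ...)}) penalizes slope, and the
#' second difference (first column \code{(1, -2, 1, 0, ...)}) penalizes
#' curvature. Second differences give the smoothest solutions; switch to
#' first differences when sharp input transitions must survive.
#'
#' @param kind one of \code{"second_difference"}, \code{"first_difference"},
#'   \code{"identity"}.
#' @param N solution length; at least 2 for first and 3 for second
#'   differences.
#' @return A dense \code{N x N} penalty matrix.
#' @export
build_regularizer <- function(kind = c("second_difference", "first_difference",
                                       "identity"), N) {
  kind <- match.arg(kind)
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 1)
    stop("'N' must be a positive integer")
  col1 <- switch(kind,
    identity = 1,
    first_difference = c(1, -1),
    second_difference = c(1, -2, 1))
  if (N < length(col1))
    stop("N = ", N, " too small for '", kind, "' (needs N >= ", length(col1), ")")
  Q <- matrix(0, N, N)
  for (j in seq_len(N)) {
    len <- min(length(col1), N - j + 1L)
    Q[j:(j + len - 1L), j] <- col1[seq_len(len)]
  }
  Q
}

#' Regularizer specification
#'
#' Bundles the penalty-operator kind with its weight for passing through the
#' solver interfaces.
#'
#' @param kind penalty kind, see [build_regularizer()].
#' @param gamma nonnegative regularization weight.
#' @return A list of class \code{"regularizer_spec"}.
#' @export
regularizer_spec <- function(kind = c("second_difference", "first_difference",
                                      "identity"), gamma = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("'gamma' must be a single nonnegative number")
  structure(list(kind = kind, gamma = gamma), class = "regularizer_spec")
}
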