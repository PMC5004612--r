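#' Flow-through respirometry chamber configuration
#'
#' Parameters of the synthetic chamber model used by
#' [synth_impulse_response()]. A well-mixed chamber of volume V (ml) flushed
#' at flow rate F (ml/min) washes out injected gas as a first-order
#' exponential with time constant \code{tau_w = V/F} (converted to seconds),
#' reaching the analyzer after a transport delay.
#'
#' @param volume chamber volume, ml (positive). Default 28 ml.
#' @param flow inlet flow rate, ml/min (positive). Default 500 ml/min.
#' @param delay transport delay from chamber to analyzer, seconds
#'   (nonnegative).
#' @param dt sampling interval, seconds. Default 0.1 s (10 Hz).
#' @param support_duration kernel truncation horizon, seconds; defaults to
#'   \code{delay + 8 * tau_w}. A horizon below \code{5 * tau_w} triggers a
#'   truncation warning.
#' @return list of class \code{"chamber_config"}, including the derived
#'   washout time constant \code{tau_w} in seconds.
#' @export
chamber_config <- function(volume = 28, flow = 500, delay = 1.5, dt = 0.1,
                           support_duration = NULL) {
  if (volume <= 0) stop("'volume' must be positive")
  if (flow <= 0) stop("'flow' must be positive")
  if (delay < 0) stop("'delay' must be nonnegative")
  if (dt <= 0) stop("'dt' must be positive")
  tau_w <- volume / flow * 60  # minutes -> seconds
  if (is.null(support_duration)) support_duration <- delay + 8 * tau_w
  if (support_duration < 5 * tau_w)
    warning("support_duration = ", support_duration, " s truncates the kernel ",
            "before 5 washout time constants (", signif(5 * tau_w, 4), " s)")
  structure(list(volume = volume, flow = flow, delay = delay, dt = dt,
                 support_duration = support_duration, tau_w = tau_w),
            class = "chamber_config")
}

#' Synthetic chamber washout impulse response
#'
#' Delayed first-order washout kernel for a well-mixed chamber: the continuous
#' impulse response is \code{(1/tau_w) exp(-(t - delay)/tau_w)} for
#' \code{t >= delay} and zero before. Each discrete weight is the exact
#' integral of that density over one sampling bin, and the kernel is
#' normalized to unit sum so totals are conserved. This is a synthetic
#' stand-in for a measured calibration-pulse recording; use
#' [discretize_impulse_response()] for measured kernels.
#'
#' @param cfg a [chamber_config()].
#' @return An [impulse_response()] with \code{n0_delay = round(delay/dt)}.
#' @examples
#' h <- synth_impulse_response(chamber_config(flow = 500))
#' sum(h$h)
#' @export
synth_impulse_response <- function(cfg) {
  stopifnot(inherits(cfg, "chamber_config"))
  dt <- cfg$dt; tau <- cfg$tau_w; d <- cfg$delay
  K <- as.integer(ceiling(cfg$support_duration / dt))
  k <- seq_len(K) - 1L
  a <- pmax(k * dt, d)
  b <- (k + 1) * dt
  hk <- ifelse(b <= d, 0, exp(-(a - d) / tau) - exp(-(b - d) / tau))
  impulse_response(hk, dt = dt, normalize = TRUE,
                   n0_delay = min(as.integer(round(d / dt)), K - 1L))
}

#' Rectangular pulse-train configuration
#'
#' @param frequency pulse repetition rate, Hz (positive).
#' @param n_pulses number of pulses (nonnegative integer). Default 3.
#' @param amplitude pulse height in input units.
#' @param duty fraction of each period the pulse is on, in (0, 1); at
#'   \code{duty = 0.5} a 1 Hz train has 0.5 s pulses.
#' @param start_time time of the first pulse's onset, seconds.
#' @return list of class \code{"pulse_train_config"}.
#' @export
pulse_train_config <- function(frequency, n_pulses = 3L, amplitude = 1,
                               duty = 0.5, start_time = 10) {
  if (frequency <= 0) stop("'frequency' must be positive")
  if (n_pulses < 0 || n_pulses != round(n_pulses)) stop("'n_pulses' must be a nonnegative integer")
  if (duty <= 0 || (duty >= 1 && n_pulses > 1))
    stop("'duty' must lie in (0, 1): consecutive pulses would touch or overlap")
  if (start_time < 0) stop("'start_time' must be nonnegative")
  structure(list(frequency = frequency, n_pulses = as.integer(n_pulses),
                 amplitude = amplitude, duty = duty, start_time = start_time),
            class = "pulse_train_config")
}

#' Generate a rectangular pulse-train input signal
#'
#' @param cfg a [pulse_train_config()].
#' @param N total signal length in samples.
#' @param dt sampling interval, seconds.
#' @return A [resp_ts()] of length \code{N}: \code{amplitude} while a pulse
#'   is on, zero elsewhere.
#' @export
synth_pulse_train <- function(cfg, N, dt) {
  stopifnot(inherits(cfg, "pulse_train_config"))
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer")
  v <- numeric(N)
  if (cfg$n_pulses > 0L) {
    period <- 1 / cfg$frequency
    last_end <- cfg$start_time + (cfg$n_pulses - 1L) * period + cfg$duty * period
    if (last_end > N * dt)
      stop("pulse train extends to ", signif(last_end, 6), " s, beyond the ",
           signif(N * dt, 6), " s signal")
    tt <- (seq_len(N) - 1L) * dt
    eps <- 1e-9 * dt
    for (i in seq_len(cfg$n_pulses) - 1L) {
      on <- cfg$start_time + i * period
      v[tt >= on - eps & tt < on + cfg$duty * period - eps] <- cfg$amplitude
    }
  }
  resp_ts(v, dt = dt)
}

#' Add calibrated Gaussian measurement noise
#'
#' Adds zero-mean normally distributed noise with standard deviation
#' \code{level/100} times a reference amplitude of the clean signal: its peak
#' absolute value (default, matching how analyzer noise is quoted against
#' full signal excursion) or its root-mean-square.
#'
#' @param y clean signal (\code{resp_ts} or numeric).
#' @param level noise level in percent (nonnegative).
#' @param seed optional integer seed for reproducible noise.
#' @param reference \code{"peak"} or \code{"rms"}.
#' @return Signal of the same type and length as \code{y}.
#' @export
add_noise <- function(y, level, seed = NULL, reference = c("peak", "rms")) {
  reference <- match.arg(reference)
  if (level < 0) stop("'level' must be nonnegative")
  yv <- .ts_values(y)
  if (level == 0) return(y)
  ref <- switch(reference,
                peak = max(abs(yv)),
                rms = sqrt(mean(yv^2)))
  if (!is.null(seed)) set.seed(seed)
  noisy <- yv + stats::rnorm(length(yv), sd = level / 100 * ref)
  if (inherits(y, "resp_ts")) resp_ts(noisy, dt = y$dt, t0 = y$t0) else noisy
}

#' Synthetic validation benchmark suite
#'
#' Generates the full factorial grid of synthetic respirometry experiments:
#' for each inlet flow rate a chamber washout kernel, for each pulse
#' frequency a three-pulse rectangular input (duty 0.5), the clean output by
#' forward convolution, and for each noise level a noisy output. The default
#' grid is flows of 250 and 500 ml/min, frequencies 0.1, 0.2, 0.5, 1 and
#' 2 Hz, and noise levels 0.01, 0.1, 1, 2, 5 and 10 percent (60 instances)
#' at 10 Hz sampling. The \code{"full"} preset spans one hour (36,000
#' samples); the \code{"reduced"} desk-scale preset spans 10 minutes (6,000
#' samples).
#'
#' @param flows inlet flow rates, ml/min.
#' @param frequencies pulse frequencies, Hz.
#' @param noise_levels noise levels, percent.
#' @param seed master seed; per-instance seeds are derived from it
#'   deterministically.
#' @param preset \code{"reduced"} (600 s) or \code{"full"} (3600 s);
#'   overridden by \code{duration}.
#' @param duration optional experiment duration in seconds.
#' @param dt sampling interval, seconds.
#' @param volume chamber volume, ml.
#' @param delay chamber-to-analyzer transport delay, seconds.
#' @return list of class \code{"benchmark_suite"}: each element a list with
#'   \code{u_true}, \code{y_clean}, \code{y_noisy}, \code{h}, \code{flow},
#'   \code{frequency}, \code{noise_level}, \code{seed}.
#' @export
make_benchmark_suite <- function(flows = c(250, 500),
                                 frequencies = c(0.1, 0.2, 0.5, 1, 2),
                                 noise_levels = c(0.01, 0.1, 1, 2, 5, 10),
                                 seed = 1L,
                                 preset = c("reduced", "full"),
                                 duration = NULL, dt = 0.1,
                                 volume = 28, delay = 1.5) {
  preset <- match.arg(preset)
  if (is.null(duration)) duration <- switch(preset, reduced = 600, full = 3600)
  N <- as.integer(round(duration / dt))
  out <- list()
  idx <- 0L
  for (flow in flows) {
    h <- synth_impulse_response(chamber_config(volume = volume, flow = flow,
                                               delay = delay, dt = dt))
    for (freq in frequencies) {
      u <- synth_pulse_train(pulse_train_config(frequency = freq), N, dt)
      y_clean <- forward_convolve(u, h)
      for (lev in noise_levels) {
        idx <- idx + 1L
        inst_seed <- (as.integer(seed) %% 100000L) * 10007L + idx
        out[[idx]] <- list(u_true = u, y_clean = y_clean,
                           y_noisy = add_noise(y_clean, lev, seed = inst_seed),
                           h = h, flow = flow, frequency = freq,
                           noise_level = lev, seed = inst_seed)
      }
    }
  }
  structure(out, class = "benchmark_suite",
            grid = list(flows = flows, frequencies = frequencies,
                        noise_levels = noise_levels, N = N, dt = dt))
}

#' @export
print.benchmark_suite <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Benchmark suite: %d instances (%d flows x %d frequencies x %d noise levels), N = %d at dt = %g s\n",
              length(x), length(g$flows), length(g$frequencies),
              length(g$noise_levels), g$N, g$dt))
  invisible(x)
}
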