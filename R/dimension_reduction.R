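#' Piecewise-constant projection operator
#'
#' The dimension-reduction method assumes the input is constant over windows
#' of \code{m} consecutive samples. That assumption is encoded by the
#' block-indicator matrix L (\code{N x n}, \code{n = N/m}): entry
#' \code{(i, j)} is 1 when sample \code{i} falls in window \code{j}, else 0.
#' Columns of L are orthogonal with squared norm \code{m}, so the projection
#' constrains the solution to a well-conditioned low-dimensional subspace.
#' When \code{m} does not divide \code{N}, the length is padded up to the
#' next multiple of \code{m} and the padding recorded.
#'
#' @param N signal length (positive integer).
#' @param m window width in samples (positive integer). \code{m = 1} leaves
#'   the problem unprojected.
#' @return An object of class \code{"projection"} with elements \code{N},
#'   \code{m}, \code{n} (number of windows), \code{N_pad}, \code{pad};
#'   \code{as.matrix()} materializes the dense \code{N_pad x n} indicator.
#' @export
build_projection <- function(N, m) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  N <- as.integer(N); m <- as.integer(m)
  n <- as.integer(ceiling(N / m))
  N_pad <- n * m
  structure(list(N = N, m = m, n = n, N_pad = N_pad, pad = N_pad - N),
            class = "projection")
}

#' @export
as.matrix.projection <- function(x, ...) {
  L <- matrix(0, x$N_pad, x$n)
  L[cbind(seq_len(x$N_pad), rep(seq_len(x$n), each = x$m))] <- 1
  L
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("Projection: %d samples -> %d windows of m = %d (padding %d)\n",
              x$N, x$n, x$m, x$pad))
  invisible(x)
}

# Projected forward operator G = H L, assembled directly from its band
# structure: every column is the m-sample running sum of the kernel, placed
# at offset (j-1)*m. Equals the dense product H %*% L.
.dr_G <- function(h, N_pad, m) {
  hh <- h$h
  s <- length(hh)
  svec <- numeric(s + m - 1L)
  for (l in 0:(m - 1L)) svec[(1L + l):(s + l)] <- svec[(1L + l):(s + l)] + hh
  n <- N_pad %/% m
  G <- matrix(0, N_pad, n)
  for (j in seq_len(n)) {
    start <- (j - 1L) * m + 1L
    len <- min(length(svec), N_pad - start + 1L)
    if (len > 0L) G[start:(start + len - 1L), j] <- svec[seq_len(len)]
  }
  G
}

# Factory for the projected block solver. Returns a function(y_block) that
# runs the (optionally averaged / ridge-regularized) projected solve; the QR
# factorization is computed once per block size and reused for all shifts
# and blocks.
.dr_factory <- function(h, m, gamma, reg_kind, averaging,
                        rank_tol = 1e-10) {
  force(h); force(m); force(gamma); force(reg_kind); force(averaging)
  function(L) {
    proj <- build_projection(L, m)
    G <- .dr_G(h, proj$N_pad, m)
    n <- proj$n
    if (gamma == 0) {
      sv <- svd(G, nu = 0, nv = 0)$d
      rank <- sum(sv > rank_tol * sv[1L])
      if (rank < n)
        stop("projected operator HL is rank-deficient (rank ", rank, " < ", n,
             "); remedies: trim the transport delay with eliminate_delay(), ",
             "or set gamma > 0 for a ridge-stabilized solve")
      qrG <- qr(G, LAPACK = TRUE)
      solvefun <- function(b) qr.coef(qrG, b)
    } else {
      Qn <- build_regularizer(reg_kind, n)
      qrA <- qr(rbind(G, sqrt(gamma) * Qn), LAPACK = TRUE)
      zero <- rep(0, n)
      solvefun <- function(b) qr.coef(qrA, c(b, zero))
    }
    Np <- proj$N_pad
    K <- if (averaging) m else 1L
    function(yb) {
      ypad <- c(yb, rep(0, proj$pad))
      acc <- numeric(Np)
      for (k in seq_len(K)) {
        # shift data down by k-1 (zeros enter at the top: outputs before
        # time zero are zero), solve, shift the estimate back up
        yk <- if (k == 1L) ypad else c(rep(0, k - 1L), ypad[seq_len(Np - k + 1L)])
        uk <- rep(solvefun(yk), each = m)
        if (k > 1L) uk <- c(uk[k:Np], rep(0, k - 1L))
        acc <- acc + uk
      }
      (acc / K)[seq_len(L)]
    }
  }
}

.dr_wrap <- function(y, h, u, flagged, m, gamma, reg_kind, averaging,
                     diagnostics) {
  yv <- .ts_values(y, dt = h$dt)
  resid <- sqrt(sum((forward_convolve(u, h) - yv)^2))
  u_hat <- if (inherits(y, "resp_ts")) resp_ts(u, dt = y$dt, t0 = y$t0)
           else resp_ts(u, dt = h$dt)
  list(u_hat = u_hat, m = m, gamma = gamma, reg_kind = reg_kind,
       averaging = averaging, residual = resid, flagged = flagged,
       diagnostics = diagnostics)
}

.dr_flag_tail <- function(N, h) {
  flagged <- logical(N)
  flagged[(N - min(h$support_len, N) + 1L):N] <- TRUE
  flagged
}

#' Dimension-reduction deconvolution, single-window solve
#'
#' Solves the projected least-squares problem \code{min ||H L v - y||} under
#' the assumption that \code{m} consecutive input samples are equal, then
#' lifts back: \code{u = L v}. The projection shrinks the system by a factor
#' of \code{m} and removes the near-singularity of H, but the estimate is
#' piecewise constant and cannot track changes within a window — see
#' [dr_solve_averaged()] for the sliding-average refinement.
#'
#' @param y measured output: \code{resp_ts} or numeric vector.
#' @param h system [impulse_response()].
#' @param m window width in samples.
#' @param gamma optional nonnegative ridge weight; \code{gamma > 0} switches
#'   to the regularized projected solve of [dr_solve_regularized()].
#' @param reg_kind penalty kind for the regularized variant (built at the
#'   projected dimension \code{n}).
#' @return A list with \code{u_hat}, \code{m}, \code{gamma}, \code{residual},
#'   \code{flagged} (trailing kernel-support estimates are low-confidence)
#'   and \code{diagnostics}.
#' @export
dr_solve_single <- function(y, h, m, gamma = 0, reg_kind = "identity") {
  stopifnot(inherits(h, "impulse_response"))
  yv <- .ts_values(y, dt = h$dt)
  N <- length(yv)
  u <- .dr_factory(h, m, gamma, reg_kind, averaging = FALSE)(N)(yv)
  .dr_wrap(y, h, u, .dr_flag_tail(N, h), m, gamma, reg_kind, FALSE,
           list(n_blocks = 1L))
}

#' Dimension-reduction deconvolution with sliding-average reconstruction
#'
#' The single-window estimate is piecewise constant with artificial jumps at
#' window boundaries. To restore temporal resolution, the window grid is slid
#' \code{m} times in increments of one sample: for each shift k the data are
#' shifted down by k-1 (zero-filled, since outputs before time zero are
#' zero), solved, and the estimate shifted back up; the final estimate is the
#' mean of the \code{m} aligned solutions. The trailing kernel-support
#' estimates lack the look-ahead data to be reliable and are flagged.
#'
#' @inheritParams dr_solve_single
#' @return As [dr_solve_single()].
#' @export
dr_solve_averaged <- function(y, h, m, gamma = 0, reg_kind = "identity") {
  stopifnot(inherits(h, "impulse_response"))
  yv <- .ts_values(y, dt = h$dt)
  N <- length(yv)
  u <- .dr_factory(h, m, gamma, reg_kind, averaging = TRUE)(N)(yv)
  .dr_wrap(y, h, u, .dr_flag_tail(N, h), m, gamma, reg_kind, TRUE,
           list(n_blocks = 1L))
}

#' Ridge-regularized projected deconvolution
#'
#' Second remedy for a singular projected operator: add a penalty term to the
#' projected problem, solving
#' \code{v = (L'H'HL + gamma Q'Q)^-1 L'H' y} with Q built at the projected
#' dimension \code{n}, then lift and shift-average exactly as in
#' [dr_solve_averaged()]. Use when the kernel's transport delay makes
#' \code{HL} rank-deficient and trimming ([eliminate_delay()]) is not wanted.
#'
#' @inheritParams dr_solve_single
#' @param gamma positive ridge weight.
#' @param averaging apply the m-fold shift-and-average (default \code{TRUE}).
#' @return As [dr_solve_single()].
#' @export
dr_solve_regularized <- function(y, h, m, gamma, reg_kind = "identity",
                                 averaging = TRUE) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be positive; for an unregularized solve use dr_solve_single()")
  stopifnot(inherits(h, "impulse_response"))
  yv <- .ts_values(y, dt = h$dt)
  N <- length(yv)
  u <- .dr_factory(h, m, gamma, reg_kind, averaging = averaging)(N)(yv)
  .dr_wrap(y, h, u, .dr_flag_tail(N, h), m, gamma, reg_kind, averaging,
           list(n_blocks = 1L))
}

#' Sequential partitioned dimension-reduction deconvolution
#'
#' Combines the projection method with the partition-subtract-advance scheme
#' used by [tikhonov_solve_sequential()]: each cycle runs the (averaged)
#' projected solve on a block of \code{n + n_overlap} samples, accepts the
#' first \code{n} estimated inputs, subtracts their forward contribution from
#' the data ahead, and advances. The projected block operator is factorized
#' once per block size and reused.
#'
#' @inheritParams dr_solve_single
#' @param averaging apply the m-fold shift-and-average within each block.
#' @param plan a [partition_plan()].
#' @return As [dr_solve_single()], with block diagnostics.
#' @export
dr_solve_sequential <- function(y, h, m, gamma = 0, reg_kind = "identity",
                                averaging = TRUE, plan = partition_plan()) {
  stopifnot(inherits(h, "impulse_response"), inherits(plan, "partition_plan"))
  yv <- .ts_values(y, dt = h$dt)
  N <- length(yv)
  if (plan$n + plan$n_overlap > N) {
    message("block size ", plan$n + plan$n_overlap, " exceeds data length ", N,
            "; falling back to a single full solve")
    fit <- if (averaging) dr_solve_averaged(y, h, m, gamma, reg_kind)
           else dr_solve_single(y, h, m, gamma, reg_kind)
    return(fit)
  }
  out <- .sequential_loop(yv, h, plan,
                          .dr_factory(h, m, gamma, reg_kind, averaging))
  flagged <- out$flagged | .dr_flag_tail(N, h)
  fit <- .dr_wrap(y, h, out$u, flagged, m, gamma, reg_kind, averaging,
                  out$diagnostics)
  fit
}

#' Trim the transport delay from kernel and data
#'
#' First remedy for a singular projected operator. A flow-through system's
#' transport delay puts \code{n0_delay} zeros at the start of the impulse
#' response, hence zero rows (and trailing zero columns) in H that can make
#' \code{H'H} and \code{L'H'HL} singular. Dropping those leading zeros from
#' the kernel and the same number of leading samples from the output leaves
#' an equivalent, nonsingular system; the recovered inputs still align with
#' the original input time axis, and the recorded \code{offset} says how many
#' trailing inputs of the original axis are no longer estimable. This
#' modification does not change the solution on the common support.
#'
#' @param y measured output (\code{resp_ts} or numeric).
#' @param h system [impulse_response()] with \code{n0_delay > 0} (otherwise a
#'   no-op with a notice).
#' @return list with trimmed \code{y}, trimmed \code{h}, and integer
#'   \code{offset} (the number of samples removed).
#' @export
eliminate_delay <- function(y, h) {
  stopifnot(inherits(h, "impulse_response"))
  d <- h$n0_delay
  if (d == 0L) {
    message("kernel has no leading delay zeros; nothing to trim")
    return(list(y = y, h = h, offset = 0L))
  }
  yv <- .ts_values(y, dt = h$dt)
  if (length(yv) <= d) stop("output shorter than the delay; cannot trim")
  h2 <- impulse_response(h$h[-seq_len(d)], dt = h$dt, n0_delay = 0L)
  y2v <- yv[-seq_len(d)]
  y2 <- if (inherits(y, "resp_ts")) resp_ts(y2v, dt = y$dt, t0 = y$t0) else y2v
  list(y = y2, h = h2, offset = d)
}

#' Grid sweep for the window width m
#'
#' The window width trades noise resistance against temporal resolution and
#' is tuned per setup; useful values typically fall between 4 and 30.
#' Candidates are scored by Pearson correlation between recovered and true
#' input on a calibration pair; widths whose projected operator is singular
#' (at \code{gamma = 0}) score \code{NA}.
#'
#' @inheritParams sweep_gamma
#' @param ms integer grid of window widths (non-empty); default 1 to 32.
#' @param gamma ridge weight passed to the solver.
#' @param reg_kind penalty kind for the regularized variant.
#' @param averaging use the sliding-average reconstruction.
#' @return list with \code{best_m} and \code{table} (data frame of m,
#'   pearson_r).
#' @export
sweep_m <- function(y_cal, u_true_cal, h, ms = 1:32, gamma = 0,
                    reg_kind = "identity", averaging = TRUE, plan = NULL) {
  if (length(ms) == 0L) stop("'ms' must be a non-empty grid")
  u_true <- .ts_values(u_true_cal)
  scores <- vapply(ms, function(m) {
    fit <- tryCatch({
      if (is.null(plan)) {
        if (averaging) dr_solve_averaged(y_cal, h, m, gamma, reg_kind)
        else dr_solve_single(y_cal, h, m, gamma, reg_kind)
      } else {
        dr_solve_sequential(y_cal, h, m, gamma, reg_kind, averaging, plan)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) NA_real_
    else pearson_correlation(fit$u_hat$values, u_true)
  }, numeric(1))
  tab <- data.frame(m = ms, pearson_r = scores)
  if (all(is.na(scores))) stop("all window widths failed; projected operator singular everywhere")
  list(best_m = ms[which.max(scores)], table = tab)
}
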