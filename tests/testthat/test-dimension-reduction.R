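test_that("the block-indicator projection has orthogonal unit-window columns", {
  expect_equal(as.matrix(build_projection(5, 1)), diag(5))
  L <- as.matrix(build_projection(4, 2))
  expect_equal(L[, 1], c(1, 1, 0, 0))
  expect_equal(L[, 2], c(0, 0, 1, 1))
  for (cfg in list(c(12, 3), c(20, 4), c(17, 5))) {
    p <- build_projection(cfg[1], cfg[2])
    L <- as.matrix(p)
    expect_equal(crossprod(L), cfg[2] * diag(p$n))  # L'L = m I
    expect_equal(p$N_pad, p$n * cfg[2])
  }
  # padding recorded when m does not divide N
  expect_equal(build_projection(17, 5)$pad, 3L)
})

test_that("single-window solve matches the dense reconstruction-map oracle", {
  # m = 1 on an invertible system: exact inversion
  inst <- pulse_instance(N = 60, support = 6, frequency = 0.5)
  fit <- dr_solve_single(inst$y, inst$h, m = 1)
  expect_equal(fit$u_hat$values, inst$u$values, tolerance = 1e-10)

  # input constant on aligned windows of 4: projection contains the truth
  h <- rand_kernel(8, seed = 9)
  set.seed(9)
  u <- rep(stats::runif(10), each = 4)
  y <- forward_convolve(u, h)
  fit <- dr_solve_single(y, h, m = 4)
  expect_equal(fit$u_hat$values, u, tolerance = 1e-8)

  # dense assembly of the solve-and-lift map on a small instance
  h <- rand_kernel(7, seed = 10)
  set.seed(10); y <- stats::rnorm(24)
  M <- dr_M_oracle(h, 24, 3)
  fit <- dr_solve_single(y, h, m = 3)
  expect_lt(rel_err(fit$u_hat$values, as.numeric(M %*% y)), 1e-10)
})

test_that("averaged solve agrees three ways with the explicit averaged map", {
  h <- rand_kernel(8, seed = 12)
  set.seed(12); y <- stats::rnorm(60)
  m <- 5
  u_prod <- dr_solve_averaged(y, h, m = m)$u_hat$values
  u_mbar <- as.numeric(dr_Mbar_oracle(h, 60, m) %*% y)
  u_loop <- dr_shiftloop_oracle(y, h, m)
  expect_lt(rel_err(u_prod, u_mbar), 1e-10)
  expect_lt(rel_err(u_prod, u_loop), 1e-10)
  expect_lt(rel_err(u_mbar, u_loop), 1e-10)

  # m = 1 degenerates to the single-window solve
  expect_equal(dr_solve_averaged(y, h, m = 1)$u_hat$values,
               dr_solve_single(y, h, m = 1)$u_hat$values)
})

test_that("averaged solve recovers a noiseless pulse train", {
  inst <- pulse_instance(N = 1200, support = 25, frequency = 0.2)
  fit <- dr_solve_averaged(inst$y, inst$h, m = 2)
  expect_gte(pearson_correlation(fit$u_hat$values, inst$u$values,
                                 mask = fit$flagged), 0.99)
})

test_that("delay trimming removes the singularity without changing the solution", {
  d <- 6L
  h <- rand_kernel(12, delay = d, dt = 1, seed = 13)
  set.seed(13)
  u <- rep(stats::runif(8), each = 3)  # N = 24, m = 3
  y <- forward_convolve(u, h)

  tr <- eliminate_delay(y, h)
  expect_identical(tr$offset, d)
  expect_identical(tr$h$n0_delay, 0L)
  expect_equal(tr$h$h, h$h[-(1:d)])
  expect_length(tr$y, 24 - d)

  # untrimmed projected operator is singular at gamma = 0
  expect_error(dr_solve_single(y, h, m = 3), "rank-deficient")

  # ridge-stabilized untrimmed solve in the vanishing-penalty limit equals
  # the trimmed solve on the common support
  G <- as.matrix(convolution_operator(h, 24)) %*% as.matrix(build_projection(24, 3))
  g0 <- 1e-12 * norm(crossprod(G), "2")
  u_ridge <- dr_solve_regularized(y, h, m = 3, gamma = g0,
                                  reg_kind = "identity", averaging = FALSE)
  u_trim <- dr_solve_single(tr$y, tr$h, m = 3)
  expect_lt(max(abs(u_ridge$u_hat$values[1:(24 - d)] - u_trim$u_hat$values)),
            1e-6)

  # kernel without delay: no-op with a notice
  h0 <- rand_kernel(6, seed = 14)
  expect_message(out <- eliminate_delay(1:20, h0), "nothing to trim")
  expect_identical(out$offset, 0L)
})

test_that("ridge-regularized projected solve has the correct limits", {
  h <- rand_kernel(8, seed = 15)
  set.seed(15); y <- stats::rnorm(48)
  base <- dr_solve_single(y, h, m = 4)$u_hat$values
  G <- as.matrix(convolution_operator(h, 48)) %*% as.matrix(build_projection(48, 4))
  g0 <- 1e-12 * norm(crossprod(G), "2")
  near0 <- dr_solve_regularized(y, h, m = 4, gamma = g0,
                                averaging = FALSE)$u_hat$values
  expect_lt(max(abs(near0 - base)), 1e-6)

  big <- dr_solve_regularized(y, h, m = 4, gamma = 1e12 * norm(crossprod(G), "2"),
                              reg_kind = "identity")$u_hat$values
  expect_lt(sqrt(sum(big^2)), 1e-6 * sqrt(sum(y^2)))

  expect_error(dr_solve_regularized(y, h, m = 4, gamma = 0), "positive")
})

test_that("sequential projected solve is consistent with the single-shot solve", {
  inst <- pulse_instance(N = 600, support = 20, frequency = 0.5)
  single <- dr_solve_averaged(inst$y, inst$h, m = 4)
  seq1 <- dr_solve_sequential(inst$y, inst$h, m = 4,
                              plan = partition_plan(600, 40))
  expect_equal(seq1$u_hat$values, single$u_hat$values, tolerance = 1e-12)

  inst <- pulse_instance(N = 3000, support = 30, frequency = 0.5)
  full <- dr_solve_averaged(inst$y, inst$h, m = 4)
  blocked <- dr_solve_sequential(inst$y, inst$h, m = 4,
                                 plan = partition_plan(1440, 60))
  interior <- 31:2800
  expect_lt(rel_err(blocked$u_hat$values[interior],
                    full$u_hat$values[interior]), 0.02)

  # with noise, blocking costs almost nothing in recovery quality
  noisy <- pulse_instance(N = 3000, support = 30, frequency = 0.5, noise = 1,
                          seed = 17)
  f1 <- dr_solve_averaged(noisy$y, noisy$h, m = 4)
  f2 <- dr_solve_sequential(noisy$y, noisy$h, m = 4,
                            plan = partition_plan(1440, 60))
  mask <- f1$flagged | f2$flagged
  r_full <- pearson_correlation(f1$u_hat$values, noisy$u$values, mask = mask)
  r_seq <- pearson_correlation(f2$u_hat$values, noisy$u$values, mask = mask)
  expect_lt(abs(r_full - r_seq), 0.01)
})

test_that("projection restores rank and improves conditioning", {
  # delay-singular instance: H has zero rows, but HL regains full column rank
  # once the window exceeds the delay
  d <- 3L
  h <- rand_kernel(20, delay = d, seed = 18)
  for (N in c(80L, 120L)) {
    H <- as.matrix(convolution_operator(h, N))
    expect_lt(qr(H)$rank, N)
    for (m in c(4L, 8L)) {
      G <- H %*% as.matrix(build_projection(N, m))
      sv <- svd(G, nu = 0, nv = 0)$d
      expect_equal(sum(sv > 1e-10 * sv[1]), ncol(G))
    }
  }
  # conditioning: the projected normal matrix is never worse than the original
  h <- rand_kernel(16, seed = 19)
  H <- as.matrix(convolution_operator(h, 96))
  condA <- function(A) { s <- svd(A, nu = 0, nv = 0)$d; s[1] / s[length(s)] }
  c_orig <- condA(crossprod(H))
  for (m in c(2L, 4L, 8L)) {
    G <- H %*% as.matrix(build_projection(96, m))
    expect_lte(condA(crossprod(G)), c_orig)
  }
})

test_that("shift-averaging smooths the blocky single-window artifacts", {
  # input violating the piecewise-constant assumption within windows
  h <- rand_kernel(10, seed = 20)
  tt <- (0:199) * 0.1
  u <- sin(2 * pi * 0.25 * tt) + 0.5 * tt / 20
  y <- forward_convolve(u, h)
  single <- dr_solve_single(y, h, m = 8)$u_hat$values
  averaged <- dr_solve_averaged(y, h, m = 8)$u_hat$values
  expect_lt(total_variation(averaged[1:180]), total_variation(single[1:180]))
})

test_that("window-width sweep favors small m on clean data, larger on noisy", {
  one <- local({
    inst <- pulse_instance(N = 200, support = 10)
    sweep_m(inst$y, inst$u, inst$h, ms = 4)
  })
  expect_equal(one$best_m, 4)
  expect_error(sweep_m(1:10, 1:10, rand_kernel(5), integer(0)), "empty")

  clean <- pulse_instance(N = 400, support = 15, frequency = 0.5)
  noisy <- pulse_instance(N = 400, support = 15, frequency = 0.5, noise = 5,
                          seed = 21)
  ms <- c(1:6, 8, 12, 16)
  best_clean <- sweep_m(clean$y, clean$u, clean$h, ms = ms)$best_m
  best_noisy <- sweep_m(noisy$y, noisy$u, noisy$h, ms = ms)$best_m
  expect_lte(best_clean, 2)
  expect_gt(best_noisy, best_clean)
})
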