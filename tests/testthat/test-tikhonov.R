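test_that("full Tikhonov solve matches the closed-form limits", {
  # identity operator, no penalty: estimate reproduces the data exactly
  h <- impulse_response(1, dt = 1)
  y <- c(1, -2, 3, 0.5)
  fit <- tikhonov_solve_full(y, h, gamma = 0, reg_kind = "identity")
  expect_equal(fit$u_hat$values, y, tolerance = 1e-12)

  # penalty-dominated limit: huge gamma shrinks the solution to zero
  h <- rand_kernel(8, seed = 2)
  set.seed(2); y <- stats::rnorm(40)
  H <- as.matrix(convolution_operator(h, 40))
  g_big <- 1e12 * norm(crossprod(H), "2")
  fit <- tikhonov_solve_full(y, h, gamma = g_big, reg_kind = "identity")
  expect_lt(sqrt(sum(fit$u_hat$values^2)), 1e-6 * sqrt(sum(y^2)))
})

test_that("production solver agrees with the explicit normal-equations oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    N <- sample(30:100, 1)
    h <- rand_kernel(sample(5:20, 1), seed = seed)
    y <- stats::rnorm(N)
    for (kind in c("identity", "second_difference")) {
      gamma <- 10^stats::runif(1, -4, 0)
      fit <- tikhonov_solve_full(y, h, gamma, kind)
      expect_lt(rel_err(fit$u_hat$values, tikhonov_oracle(y, h, gamma, kind)),
                1e-8)
    }
  }
})

test_that("unregularized solves are refused on ill-conditioned operators", {
  h <- impulse_response(c(0, 0, 0, 1, 0.5), dt = 0.1, n0_delay = 3L)
  set.seed(1)
  expect_error(tikhonov_solve_full(stats::rnorm(50), h, gamma = 0),
               "condition")
})

test_that("single-block sequential plans reproduce the full solve", {
  inst <- pulse_instance(N = 300, support = 20, frequency = 0.2)
  full <- tikhonov_solve_full(inst$y, inst$h, gamma = 1e-4)
  seq1 <- tikhonov_solve_sequential(inst$y, inst$h, gamma = 1e-4,
                                    plan = partition_plan(300, 30))
  expect_equal(seq1$u_hat$values, full$u_hat$values, tolerance = 1e-10)
})

test_that("sequential recovery tracks the truth and converges to the full solve", {
  inst <- pulse_instance(N = 2000, support = 30, frequency = 0.5)
  fit <- tikhonov_solve_sequential(inst$y, inst$h, gamma = 1e-6,
                                   plan = partition_plan(100, 60))
  expect_gte(pearson_correlation(fit$u_hat$values, inst$u$values), 0.99)

  # multi-block vs full-data solve: a slowly decaying kernel makes the
  # look-ahead genuinely matter
  h <- slow_kernel(30)
  u <- synth_pulse_train(pulse_train_config(frequency = 0.5), 1000, 0.1)
  y <- forward_convolve(u, h)
  full <- tikhonov_solve_full(y, h, gamma = 1e-6)
  interior <- 31:900
  errs <- vapply(c(3, 29, 60), function(ov) {
    fit <- suppressWarnings(
      tikhonov_solve_sequential(y, h, gamma = 1e-6,
                                plan = partition_plan(150, ov)))
    rel_err(fit$u_hat$values[interior], full$u_hat$values[interior])
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  # agreement improves as the look-ahead grows toward and past the support
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("per-cycle residual bookkeeping matches the final residual blockwise", {
  inst <- pulse_instance(N = 800, support = 20, frequency = 0.5, noise = 1,
                         seed = 5)
  plan <- partition_plan(120, 40)
  fit <- tikhonov_solve_sequential(inst$y, inst$h, gamma = 1e-3, plan = plan)
  r_full <- inst$y$values - forward_convolve(fit$u_hat$values, inst$h)
  recorded <- fit$diagnostics$cycle_residuals
  pos <- 1L
  for (i in seq_along(recorded)) {
    n_acc <- if (i < length(recorded)) plan$n else length(r_full) - pos + 1L
    blk <- sqrt(sum(r_full[pos:(pos + n_acc - 1L)]^2))
    expect_equal(blk, recorded[i], tolerance = 1e-8)
    pos <- pos + n_acc
  }
})

test_that("larger gamma never increases the penalty norm of the solution", {
  inst <- pulse_instance(N = 120, support = 10, frequency = 0.5, noise = 2,
                         seed = 7)
  Q <- build_regularizer("second_difference", 120)
  norms <- vapply(10^seq(-8, 2, by = 1), function(g) {
    fit <- tikhonov_solve_full(inst$y, inst$h, g)
    sqrt(sum((Q %*% fit$u_hat$values)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8 * norms[-length(norms)]))
})

test_that("gamma sweep favors minimal smoothing on clean data, more on noisy", {
  one <- sweep_gamma(pulse_instance(N = 200)$y, pulse_instance(N = 200)$u,
                     pulse_instance(N = 200)$h, gammas = 0.5)
  expect_equal(one$best_gamma, 0.5)
  expect_error(sweep_gamma(1:10, 1:10, rand_kernel(5), numeric(0)), "empty")

  grid <- 10^seq(-8, 2, by = 2)
  clean <- pulse_instance(N = 400, support = 15, frequency = 0.5)
  noisy <- pulse_instance(N = 400, support = 15, frequency = 0.5, noise = 5,
                          seed = 11)
  best_clean <- sweep_gamma(clean$y, clean$u, clean$h, grid)$best_gamma
  best_noisy <- sweep_gamma(noisy$y, noisy$u, noisy$h, grid)$best_gamma
  expect_lte(best_clean, grid[2])
  expect_gt(best_noisy, best_clean)
})

test_that("a block larger than the data falls back to a single full solve", {
  inst <- pulse_instance(N = 200, support = 10)
  expect_message(
    fit <- tikhonov_solve_sequential(inst$y, inst$h, gamma = 1e-4,
                                     plan = partition_plan(300, 50)),
    "single full solve")
  full <- tikhonov_solve_full(inst$y, inst$h, gamma = 1e-4)
  expect_equal(fit$u_hat$values, full$u_hat$values)
  expect_true(any(fit$flagged))
})
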