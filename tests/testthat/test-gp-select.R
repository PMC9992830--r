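test_that("closed-form LOO equals brute-force refits with a fixed mean", {
  fx <- random_gp_fixture(n = 20, seed = 3)
  score <- loocv_score(fx$X, fx$y, fx$params)
  # oracle: n refits, holding the prior mean at the full-sample mean
  full_mean <- mean(fx$y)
  errs <- vapply(seq_len(20), function(i) {
    m <- fit_gp(fx$X[-i, ], fx$y[-i], fx$params, mean_offset = full_mean)
    pred <- gp_predict(m, fx$X[i, , drop = FALSE])
    (pred$mean[1, 1] - fx$y[i])^2
  }, numeric(1))
  expect_equal(score, mean(errs), tolerance = 1e-8)
})

test_that("LOO degenerate cases are well-posed", {
  fx <- random_gp_fixture(n = 10, seed = 4)
  # constant observations score 0 whatever the kernel
  expect_lt(loocv_score(fx$X, rep(2.5, 10), fx$params), 1e-10)
  # duplicated dataset with consistent values and positive nugget: finite
  X2 <- rbind(fx$X, fx$X)
  y2 <- c(fx$y, fx$y)
  expect_true(is.finite(loocv_score(X2, y2, fx$params)))
})

test_that("profiled MLE improves on the initial parameters", {
  fx <- random_gp_fixture(n = 40, seed = 5)
  init <- kernel_params(1e9, 1e9, 1e4, tau2 = 1, eta = 0.01)
  fit <- mle_kernel(fx$X, fx$y, init, n_starts = 3, seed = 1)
  ll_init <- gp_log_marginal(fx$X, fx$y, init)
  expect_gte(fit$loglik, ll_init)
  # reported loglik is consistent with direct evaluation at the optimum
  expect_equal(fit$loglik, gp_log_marginal(fx$X, fx$y, fit$params),
               tolerance = 1e-6)
})

test_that("profiled tau2 matches the jointly optimal tau2", {
  # at the returned (theta, g), tau2_hat must maximise the likelihood over
  # tau2 alone: perturbing it can only lower the log marginal
  fx <- random_gp_fixture(n = 30, seed = 6)
  init <- kernel_params(1e10, 1e10, 1e6, tau2 = 1, eta = 0.01)
  fit <- mle_kernel(fx$X, fx$y, init, n_starts = 2, seed = 2)
  p <- fit$params
  for (f in c(0.8, 1.25)) {
    pf <- kernel_params(p$theta_x, p$theta_y, p$theta_t,
                        tau2 = p$tau2 * f, eta = p$eta * f)
    expect_lte(gp_log_marginal(fx$X, fx$y, pf), fit$loglik + 1e-8)
  }
})

test_that("white noise drives the fitted nugget ratio to dominate", {
  set.seed(8)
  n <- 60
  X <- cbind(runif(n, 0, 1e6), runif(n, 0, 1e6), runif(n, -5000, 0))
  y <- rnorm(n)
  init <- kernel_params(1e10, 1e10, 1e6, tau2 = 1, eta = 0.1)
  expect_message(fit <- mle_kernel(X, y, init, n_starts = 3, seed = 3),
                 "noise-dominated|flat")
  expect_gte(fit$params$eta / fit$params$tau2, 1)
})

test_that("simulated data recover the generating lengthscales", {
  km <- 1000
  truth <- kernel_params((300 * km)^2, (300 * km)^2, 500^2, tau2 = 1,
                         eta = 0.05)
  set.seed(205)
  n <- 300
  X <- cbind(runif(n, 0, 1000 * km), runif(n, 0, 1000 * km),
             runif(n, 0, 2000))
  K <- mobfield:::kernel_matrix(X, X, truth, symmetric = TRUE)
  y <- drop(t(chol(K)) %*% rnorm(n))
  init <- kernel_params((100 * km)^2, (100 * km)^2, 100^2, 1, 0.01)
  fit <- mle_kernel(X, y, init, n_starts = 2, seed = 5)
  ratios <- sqrt(c(fit$params$theta_x / truth$theta_x,
                   fit$params$theta_y / truth$theta_y,
                   fit$params$theta_t / truth$theta_t))
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("the empirical variogram matches hand computation", {
  # 3-point fixture: pairwise space lags 100, 100, 200; all time lags 0
  X <- cbind(c(0, 100, 200), c(0, 0, 0), c(0, 0, 0))
  y <- c(0, 1, 3)
  vg <- empirical_variogram(X, y, space_breaks = c(0, 150, 300),
                            time_breaks = c(0, 10))
  # bin [0,150): pairs (1,2) and (2,3): gamma = mean(1, 4)/2 = 1.25
  expect_equal(vg$gamma[vg$space_lo == 0], 2.5 / 2)
  expect_equal(vg$n_pairs[vg$space_lo == 0], 2)
  # bin [150,300): pair (1,3): gamma = 9/2
  expect_equal(vg$gamma[vg$space_lo == 150], 4.5)

  # constant field: gamma 0 in every occupied bin
  vg0 <- empirical_variogram(X, rep(1, 3), c(0, 150, 300), c(0, 10))
  expect_true(all(vg0$gamma[vg0$n_pairs > 0] == 0))

  # empty bins appear with count 0 and missing gamma
  vg_empty <- empirical_variogram(X, y, c(0, 50, 300), c(0, 10))
  expect_equal(vg_empty$n_pairs[vg_empty$space_lo == 0], 0)
  expect_true(is.na(vg_empty$gamma[vg_empty$space_lo == 0]))
})

test_that("i.i.d. noise gives a flat variogram at the noise variance", {
  set.seed(19)
  n <- 400
  X <- cbind(runif(n, 0, 1e5), runif(n, 0, 1e5), runif(n, 0, 1000))
  v <- 0.7
  y <- rnorm(n, 0, sqrt(v))
  vg <- empirical_variogram(X, y, space_breaks = seq(0, 15e4, 5e4),
                            time_breaks = c(0, 1500))
  # under exchangeability every bin estimates the realized variance of y;
  # comparing to var(y) removes the global sampling fluctuation of the draw
  occupied <- vg$n_pairs > 500
  expect_true(all(abs(vg$gamma[occupied] - var(y)) / var(y) < 0.1))
  # and the pooled semivariance is within sampling error of the truth
  pooled <- sum(vg$gamma[occupied] * vg$n_pairs[occupied]) /
    sum(vg$n_pairs[occupied])
  expect_lt(abs(pooled - v) / v, 3 * sqrt(2 / n))
})
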