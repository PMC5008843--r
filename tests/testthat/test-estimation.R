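test_that("the empirical ARSE matches hand arithmetic and the exclusion rule", {
  # two estimates 1.1 and 0.9 of a scalar truth 1: ARSE = 10%
  est <- cbind(c(1.1, 0.9))
  res <- empirical_fi_from_estimates(est, 1, convergence_rule = function(e) TRUE)
  expect_equal(unname(res$arse), 10)

  est2 <- rbind(c(1.0, 0.1), c(1.1, 0.12), c(0.9, 0.095), c(5, 0.1))
  res2 <- empirical_fi_from_estimates(est2, c(1, 0.1))  # default: theta1 > 3 excluded
  expect_equal(res2$n_excluded, 1)
  expect_equal(res2$n_used, 3)
})

test_that("the empirical Fisher matrix recovers a known inverse covariance", {
  set.seed(77)
  A <- matrix(c(2, 0.6, 0.1, 0.6, 1.5, -0.3, 0.1, -0.3, 1), 3)
  Sigma <- crossprod(A)
  X <- matrix(rnorm(5000 * 3), 5000, 3) %*% chol(Sigma)
  X <- sweep(X, 2, c(10, 10, 10), "+")
  res <- empirical_fi_from_estimates(X, c(10, 10, 10),
                                     convergence_rule = function(e) TRUE)
  target <- solve(Sigma)
  err <- norm(res$fi$matrix - target, "F") / norm(target, "F")
  expect_lt(err, 0.05)
})

test_that("the exact objective recovers ID parameters from an off-truth start", {
  d <- equidistant_design(100, 1)
  ts <- gillespie_simulate(id_model$network, id_theta, 10, d, seed = 31)
  start <- parameter_point(c(0.5, 0.05), 10)
  fit <- estimate_parameters(id_model$network, timeseries(ts$values, d), start,
                             method = "exact_id", n_starts = 1,
                             lower = c(0.05, 0.005), upper = c(20, 2))
  expect_true(fit$converged)
  # within the asymptotic 99.9% marginal bands of the exact Fisher matrix
  s <- summarize_fi(fi_exact_id(id_theta, d, nu0 = 10))
  sd_ <- sqrt(diag(s$covariance))
  expect_lt(abs(fit$theta_hat[1] - 1), 3.3 * sd_[1] + 0.05)
  expect_lt(abs(fit$theta_hat[2] - 0.1), 3.3 * sd_[2] + 0.005)
})

test_that("mss estimation anchors on noise-free deterministic data", {
  d <- equidistant_design(12, 1)
  # "data" = the rate-equation solution at the true parameters
  mean_traj <- vapply(seq_len(12), function(i) {
    propagate_interval(id_model$network, id_theta, 10, d$times[i])$mean
  }, numeric(1))
  start <- parameter_point(c(1.4, 0.13), 10)
  fit <- estimate_parameters(id_model$network, timeseries(matrix(mean_traj), d),
                             start, method = "mss", n_starts = 1,
                             lower = c(0.1, 0.01), upper = c(10, 1))
  expect_true(fit$converged)
  # the fitted trajectory must match the data (theta1/theta2 pinned to 10)
  expect_equal(unname(fit$theta_hat[1] / fit$theta_hat[2]), 10, tolerance = 0.02)
})

test_that("ARSE is invariant under rescaling the parameter and the estimates", {
  est <- cbind(rnorm(40, 1, 0.1))
  a1 <- empirical_fi_from_estimates(est, 1, convergence_rule = function(e) TRUE)$arse
  a2 <- empirical_fi_from_estimates(est * 7, 7, convergence_rule = function(e) TRUE)$arse
  expect_equal(a1, a2)
})

test_that("benchmark and mss estimates have comparable accuracy on ID data", {
  d <- equidistant_design(30, 1)
  n_data <- 8
  devs <- matrix(NA_real_, n_data, 2 * 2)
  for (k in seq_len(n_data)) {
    ts <- gillespie_simulate(id_model$network, id_theta, 10, d, seed = 400 + k)
    obs <- timeseries(ts$values, d)
    start <- parameter_point(c(0.7, 0.07), 10)
    f1 <- estimate_parameters(id_model$network, obs, start, method = "mss",
                              n_starts = 1, lower = c(0.05, 0.005), upper = c(20, 2))
    f2 <- estimate_parameters(id_model$network, obs, start, method = "benchmark",
                              n_starts = 1, lower = c(0.05, 0.005), upper = c(20, 2))
    devs[k, ] <- c(abs(f1$theta_hat - id_theta), abs(f2$theta_hat - id_theta))
  }
  mad_mss <- apply(devs[, 1:2], 2, median)
  mad_bench <- apply(devs[, 3:4], 2, median)
  ratio <- mad_mss / pmax(mad_bench, 1e-8)
  expect_true(all(ratio > 0.2 & ratio < 5))
})
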