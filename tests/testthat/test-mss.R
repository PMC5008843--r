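# plain MVN log-density used as an oracle below
mvn_logdens <- function(x, mean, sigma) {
  R <- chol(sigma)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

test_that("state update reduces to the data under exact observation", {
  nu <- state_update(pred_mean = c(5, 8), pred_cov = diag(c(2, 3)),
                     obs = c(6.5, 7.2), meas_cov = matrix(0, 2, 2),
                     observed_indices = 1:2)
  expect_equal(nu, c(6.5, 7.2))
  # the 0.1 floor applies componentwise
  nu2 <- state_update(c(5, 8), diag(2), c(-3, 7), matrix(0, 2, 2), 1:2)
  expect_equal(nu2, c(0.1, 7))
})

test_that("an uninformative observation leaves the prediction unchanged", {
  nu <- state_update(pred_mean = c(5, 8), pred_cov = diag(c(2, 3)),
                     obs = c(50, 80), meas_cov = diag(1e12, 2),
                     observed_indices = 1:2)
  expect_equal(nu, c(5, 8), tolerance = 1e-4)
})

test_that("the closed-form update maximizes the literal density product", {
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3)
    pred_cov <- crossprod(A) + diag(0.5, 3)
    pred_mean <- runif(3, 4, 10)
    meas_cov <- diag(runif(2, 0.5, 2))
    obs_idx <- c(1, 3)
    obs <- pred_mean[obs_idx] + rnorm(2)
    target <- function(nu) {
      -(mvn_logdens(nu, pred_mean, pred_cov) +
          mvn_logdens(obs, nu[obs_idx], meas_cov))
    }
    num <- optim(pred_mean, target, method = "BFGS",
                 control = list(reltol = 1e-14))$par
    closed <- state_update(pred_mean, pred_cov, obs, meas_cov, obs_idx)
    expect_equal(closed, num, tolerance = 1e-6)
  }
})

test_that("with zero noise the interval density equals the LNA transition density", {
  pr <- propagate_interval(id_model$network, id_theta, 10, 1)
  o <- 11.3
  res <- interval_logdensity(id_model$network, id_theta, 10, o, 1,
                             meas_cov = matrix(0, 1, 1), observed_indices = 1)
  expect_equal(res$logdens, dnorm(o, pr$mean, sqrt(pr$cov[1, 1]), log = TRUE),
               tolerance = 1e-8)
  # observing exactly the predicted mean gives zero residuals
  res0 <- interval_logdensity(id_model$network, id_theta, 10, pr$mean, 1,
                              matrix(0, 1, 1), 1)
  expect_equal(res0$residuals, 0, tolerance = 1e-10)
})

test_that("the closed-form convolution matches numerical quadrature", {
  # 1-D: integral over nu of f(O | nu, s_meas) f(nu | x, s_lna)
  pr <- propagate_interval(id_model$network, id_theta, 10, 1)
  s_meas <- 0.7
  o <- 8.9
  res <- interval_logdensity(id_model$network, id_theta, 10, o, 1,
                             meas_cov = matrix(s_meas, 1, 1), observed_indices = 1)
  quad <- integrate(function(nu) {
    dnorm(o, nu, sqrt(s_meas)) * dnorm(nu, pr$mean, sqrt(pr$cov[1, 1]))
  }, -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(res$logdens, log(quad), tolerance = 1e-8)
})

test_that("interval densities integrate to one over the observation", {
  pr <- propagate_interval(id_model$network, id_theta, 10, 1)
  total <- integrate(function(o) {
    vapply(o, function(oo) {
      exp(interval_logdensity(id_model$network, id_theta, 10, oo, 1,
                              matrix(0.5, 1, 1), 1)$logdens)
    }, numeric(1))
  }, pr$mean - 12, pr$mean + 12, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("single-interval data reproduces the interval log-density", {
  d <- equidistant_design(1, 1)
  ts <- timeseries(matrix(10.8), d)
  res <- mss_loglik(id_model$network, ts, id_model$param)
  ref <- interval_logdensity(id_model$network, id_theta, 10, 10.8, 1,
                             matrix(0, 1, 1), 1)
  expect_equal(res$value, ref$logdens, tolerance = 1e-8)
})

test_that("a planted extreme outlier masks its interval and only that interval", {
  d <- equidistant_design(5, 1)
  pd <- lna_pseudo_data(id_model$network, id_model$param, d, M = 1, seed = 6)
  vals <- pd[[1]]$values
  clean <- mss_loglik(id_model$network, timeseries(vals, d), id_model$param)
  expect_length(clean$track$masked, 0)
  vals2 <- vals
  vals2[5, 1] <- vals2[5, 1] + 30  # ~ 22 sigma against Sigma(1) = 1.81
  tainted <- mss_loglik(id_model$network, timeseries(vals2, d), id_model$param)
  expect_equal(tainted$track$masked, 5)
  expect_equal(tainted$track$contributions[5], 0)
  expect_equal(tainted$track$contributions[1:4], clean$track$contributions[1:4],
               tolerance = 1e-8)
  # state updating keeps running through the masked interval
  expect_equal(tainted$track$estimates[6, 1], vals2[5, 1])
})

test_that("the MSS objective prefers the generating parameters on average", {
  d <- equidistant_design(10, 1)
  n_data <- 50
  p_true <- id_model$param
  p_wrong <- parameter_point(c(2, 0.1), 10)
  delta <- vapply(seq_len(n_data), function(k) {
    ts <- gillespie_simulate(id_model$network, id_theta, 10, d, seed = 100 + k)
    obs <- timeseries(ts$values, d)
    mss_loglik(id_model$network, obs, p_true)$value -
      mss_loglik(id_model$network, obs, p_wrong)$value
  }, numeric(1))
  expect_gt(mean(delta), 0)
})

test_that("the objective is invariant under species relabeling", {
  lv_swapped <- reaction_network(
    species = c("Y2", "Y1"),
    reactions = list(
      list(educts = c(Y1 = 1), products = c(Y1 = 2), rate = "theta1 * Y1"),
      list(educts = c(Y1 = 1, Y2 = 1), products = c(Y1 = 0, Y2 = 2),
           rate = "theta2 * Y1 * Y2"),
      list(educts = c(Y2 = 1), products = c(), rate = "theta3 * Y2")
    ),
    params = c("theta1", "theta2", "theta3"))
  d <- equidistant_design(8, 1)
  ts <- gillespie_simulate(lv_model$network, lv_theta, c(71, 79), d, seed = 12)
  p1 <- lv_model$param
  v1 <- mss_loglik(lv_model$network, timeseries(ts$values, d), p1)$value
  p2 <- parameter_point(lv_theta, c(79, 71))
  v2 <- mss_loglik(lv_swapped, timeseries(ts$values[, c(2, 1)], d), p2)$value
  expect_equal(v1, v2, tolerance = 1e-8)
})
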