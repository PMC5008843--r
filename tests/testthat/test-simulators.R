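test_that("the SSA is reproducible and freezes at absorbing states", {
  d <- equidistant_design(20, 1)
  a <- gillespie_simulate(lv_model$network, lv_theta, c(71, 79), d, seed = 4)
  b <- gillespie_simulate(lv_model$network, lv_theta, c(71, 79), d, seed = 4)
  expect_identical(a$values, b$values)
  c_ <- gillespie_simulate(lv_model$network, lv_theta, c(71, 79), d, seed = 5)
  expect_false(identical(a$values, c_$values))

  # all propensities vanish at (0, 0): the trajectory is constant
  z <- gillespie_simulate(lv_model$network, lv_theta, c(0, 0), d, seed = 1)
  expect_true(all(z$values == 0))
})

test_that("long-horizon ID simulation matches the Poisson stationary law", {
  # stationary distribution of the immigration-death CME is Poisson(theta1/theta2)
  d <- equidistant_design(2000, 1)
  ts <- gillespie_simulate(id_model$network, id_theta, 10, d, seed = 42)
  x <- ts$values[-(1:100), 1]  # discard burn-in
  n_eff <- length(x) / 10      # conservative for autocorrelation (~ e^-0.1 lag 1)
  se_mean <- sqrt(10 / n_eff)
  expect_lt(abs(mean(x) - 10), 3 * se_mean)
  se_var <- 10 * sqrt(2 / n_eff)  # approx SE of a Poisson(10) variance estimate
  expect_lt(abs(var(x) - 10), 3 * se_var)
})

test_that("pseudo data honours the measurement-noise and rounding contracts", {
  d <- equidistant_design(10, 1)
  pd <- lna_pseudo_data(lv_model$network, lv_model$param, d, M = 3, seed = 9)
  for (ts in pd) {
    expect_identical(ts$values, attr(ts, "latent"))  # Sigma_meas = 0
  }
  pd_r <- lna_pseudo_data(lv_model$network, lv_model$param, d, M = 3, seed = 9,
                          rounding = TRUE)
  for (ts in pd_r) {
    expect_true(all(attr(ts, "latent") == round(attr(ts, "latent"))))
    expect_true(all(attr(ts, "latent") >= 0))
  }
})

test_that("one-step ID pseudo data matches the propagated moments", {
  d <- equidistant_design(1, 1)
  pd <- lna_pseudo_data(id_model$network, id_model$param, d, M = 20000, seed = 2)
  nu1 <- vapply(pd, function(ts) ts$values[1, 1], numeric(1))
  pr <- propagate_interval(id_model$network, id_theta, 10, 1)
  se_m <- sqrt(pr$cov[1, 1] / 20000)
  expect_lt(abs(mean(nu1) - pr$mean), 3 * se_m)
  se_v <- pr$cov[1, 1] * sqrt(2 / 20000)
  expect_lt(abs(var(nu1) - pr$cov[1, 1]), 3 * se_v)
})

test_that("growing M extends the ensemble without reshuffling earlier draws", {
  d <- equidistant_design(5, 1)
  small <- lna_pseudo_data(id_model$network, id_model$param, d, M = 3, seed = 7)
  big <- lna_pseudo_data(id_model$network, id_model$param, d, M = 6, seed = 7)
  # the normal draws are identical; the shared adaptive integrator couples
  # ensemble members only at the solver-tolerance level
  for (k in 1:3) expect_equal(small[[k]]$values, big[[k]]$values, tolerance = 1e-7)
  # same seed and same M is bitwise reproducible
  again <- lna_pseudo_data(id_model$network, id_model$param, d, M = 3, seed = 7)
  for (k in 1:3) expect_identical(small[[k]]$values, again[[k]]$values)
})

test_that("with frozen draws the pseudo states depend smoothly on theta", {
  d <- equidistant_design(5, 1)
  gen <- function(th) {
    p <- parameter_point(th, 10)
    vapply(lna_pseudo_data(id_model$network, p, d, M = 2, seed = 3),
           function(ts) ts$values[, 1], numeric(5))
  }
  fd <- function(h) (gen(id_theta + c(h, 0)) - gen(id_theta - c(h, 0))) / (2 * h)
  d1 <- fd(1e-3)
  d2 <- fd(1e-4)
  d3 <- fd(1e-5)
  # successive halvings of the step converge (differentiable path)
  expect_lt(max(abs(d3 - d2)), max(abs(d2 - d1)) + 1e-6)
  expect_lt(max(abs(d3 - d2)) / max(abs(d3)), 1e-3)
})

test_that("SSA and pseudo-data moments agree for the ID model", {
  d <- equidistant_design(5, 2)
  M <- 4000
  pd <- lna_pseudo_data(id_model$network, id_model$param, d, M = M, seed = 21)
  last_pd <- vapply(pd, function(ts) ts$values[5, 1], numeric(1))
  last_ssa <- vapply(seq_len(M), function(k) {
    gillespie_simulate(id_model$network, id_theta, 10, d, seed = 5000 + k)$values[5, 1]
  }, numeric(1))
  se <- sqrt(var(last_ssa) / M + var(last_pd) / M)
  expect_lt(abs(mean(last_ssa) - mean(last_pd)), 4 * se)
  se_v <- sqrt(2 / M) * (var(last_ssa) + var(last_pd)) / 2
  expect_lt(abs(var(last_ssa) - var(last_pd)), 4 * se_v)
})
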