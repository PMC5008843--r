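test_that("local LNA terms match closed forms for the Immigration-Death model", {
  lt <- local_lna_terms(id_model$network, 10, id_theta)
  expect_equal(lt$J, matrix(-0.1, 1, 1))
  expect_equal(lt$Dmat, matrix(2, 1, 1))  # 1*1*theta1 + (-1)(-1) theta2 x
})

test_that("diffusion vanishes where all propensities vanish", {
  lt <- local_lna_terms(lv_model$network, c(0, 0), lv_theta)
  expect_equal(lt$Dmat, matrix(0, 2, 2))
})

test_that("LV drift Jacobian equals the analytic Jacobian of the rate equations", {
  set.seed(3)
  for (i in 1:20) {
    y <- runif(2, 1, 300)
    J_manual <- matrix(c(lv_theta[1] - lv_theta[2] * y[2], lv_theta[2] * y[2],
                         -lv_theta[2] * y[1], lv_theta[2] * y[1] - lv_theta[3]),
                       2, 2)
    expect_equal(local_lna_terms(lv_model$network, y, lv_theta)$J, J_manual,
                 tolerance = 1e-10)
  }
})

test_that("interval propagation reproduces the analytic ID mean and variance", {
  for (dt in c(0.3, 1, 5, 60)) {
    pr <- propagate_interval(id_model$network, id_theta, 10, dt)
    expect_equal(pr$mean, 10, tolerance = 1e-8)
    expect_equal(pr$cov[1, 1], 10 * (1 - exp(-0.2 * dt)), tolerance = 1e-7)
  }
  # dt -> infinity approaches the Poisson stationary variance theta1/theta2
  pr <- propagate_interval(id_model$network, id_theta, 10, 200)
  expect_equal(pr$cov[1, 1], 10, tolerance = 1e-6)
})

test_that("zero-length intervals return the start state with zero covariance", {
  pr <- propagate_interval(lv_model$network, lv_theta, c(71, 79), 0)
  expect_equal(pr$mean, c(71, 79))
  expect_equal(pr$cov, matrix(0, 2, 2))
  expect_error(propagate_interval(id_model$network, id_theta, 10, -1), "nonnegative")
})

test_that("mean propagation is consistent across interval splits", {
  a <- propagate_interval(lv_model$network, lv_theta, c(71, 79), 1.7)
  b <- propagate_interval(lv_model$network, lv_theta, a$mean, 0.9)
  whole <- propagate_interval(lv_model$network, lv_theta, c(71, 79), 2.6)
  expect_equal(b$mean, whole$mean, tolerance = 1e-7)
})

test_that("full-horizon moments carry the analytic ID inter-temporal covariance", {
  d <- ed_design(c(0.7, 1.9))
  fh <- full_horizon_moments(id_model$network, id_theta, 10, d)
  s1 <- 10 * (1 - exp(-0.2 * 0.7))
  expect_equal(fh$sigma_b[1, 1], s1, tolerance = 1e-7)
  expect_equal(fh$sigma_b[2, 2], 10 * (1 - exp(-0.2 * 1.9)), tolerance = 1e-7)
  expect_equal(fh$sigma_b[1, 2], s1 * exp(-0.1 * 1.2), tolerance = 1e-7)
})

test_that("a single-time horizon reduces to one interval propagation", {
  d <- ed_design(2.5)
  fh <- full_horizon_moments(lv_model$network, lv_theta, c(71, 79), d)
  pr <- propagate_interval(lv_model$network, lv_theta, c(71, 79), 2.5)
  expect_equal(fh$mean[1, ], pr$mean, tolerance = 1e-7)
  expect_equal(fh$sigma_b, pr$cov, tolerance = 1e-6)
})

test_that("restricting the stacked covariance to a sub-design gives a principal submatrix", {
  d_full <- ed_design(c(1, 2, 3, 4))
  d_sub <- ed_design(c(2, 4))
  fh_full <- full_horizon_moments(id_model$network, id_theta, 10, d_full)
  fh_sub <- full_horizon_moments(id_model$network, id_theta, 10, d_sub)
  expect_equal(fh_sub$sigma_b, fh_full$sigma_b[c(2, 4), c(2, 4)], tolerance = 1e-7)
})

test_that("the LV horizon-40 stacked covariance is symmetric and factorizable", {
  d <- equidistant_design(40, 1)
  fh <- full_horizon_moments(lv_model$network, lv_theta, c(71, 79), d)
  expect_equal(fh$sigma_b, t(fh$sigma_b))
  repaired <- fh$sigma_b + diag(1e-10 * max(diag(fh$sigma_b)), 80)
  expect_silent(chol(repaired))
})
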