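# CME generator of the Immigration-Death process on states 0..nmax,
# used as an independent oracle for the closed-form transition law.
id_cme_generator <- function(theta, nmax) {
  Q <- matrix(0, nmax + 1, nmax + 1)
  for (m in 0:nmax) {
    if (m < nmax) Q[m + 2, m + 1] <- theta[1]          # birth m -> m+1
    if (m > 0) Q[m, m + 1] <- theta[2] * m             # death m -> m-1
    Q[m + 1, m + 1] <- -(theta[1] * (m < nmax) + theta[2] * m)
  }
  Q
}

test_that("the closed-form ID transition law matches the CME generator exponential", {
  nmax <- 60
  Q <- id_cme_generator(id_theta, nmax)
  for (dt in c(0.1, 1, 5)) {
    P <- as.matrix(Matrix::expm(Q * dt))
    for (nu0 in c(0, 10, 25)) {
      exact <- exact_transition_id(0:nmax, dt, nu0, id_theta)
      expect_lt(max(abs(exact - P[, nu0 + 1])), 1e-10)
    }
  }
})

test_that("the ID transition law is a normalized probability distribution", {
  for (dt in c(0.1, 1, 15)) {
    for (nu0 in c(0, 10)) {
      total <- sum(exact_transition_id(0:(nu0 + 60), dt, nu0, id_theta))
      expect_equal(total, 1, tolerance = 1e-9)
    }
  }
})

test_that("starting empty, the transition law is Poisson", {
  dt <- 2
  lam <- 10 * (1 - exp(-0.1 * dt))
  expect_equal(exact_transition_id(0:40, dt, 0, id_theta), dpois(0:40, lam),
               tolerance = 1e-12)
})

test_that("the exact Fisher matrix is symmetric and truncation-stable", {
  d <- equidistant_design(50, 1)
  f30 <- fi_exact_id(id_theta, d, truncation = 30, nu0 = 10)
  f60 <- fi_exact_id(id_theta, d, truncation = 60, nu0 = 10)
  expect_equal(f30$matrix, t(f30$matrix))
  expect_lt(max(abs(f30$matrix - f60$matrix) / abs(f60$matrix)), 1e-4)
  expect_error(fi_exact_id(id_theta, d, truncation = 5, nu0 = 10), "truncation")
})

test_that("removing time points never increases the exact D-criterion", {
  d_full <- equidistant_design(40, 1)
  d_sub <- equidistant_design(25, 1)
  D_full <- summarize_fi(fi_exact_id(id_theta, d_full, nu0 = 10))$D
  D_sub <- summarize_fi(fi_exact_id(id_theta, d_sub, nu0 = 10))$D
  expect_gt(D_full, D_sub)
})

test_that("the Monte-Carlo Fisher matrix is symmetric PSD with sane metadata", {
  fi <- fi_mss(id_model$network, id_model$param, equidistant_design(15, 1),
               M = 60, seed = 5)
  expect_equal(fi$matrix, t(fi$matrix))
  ev <- eigen(fi$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * sum(diag(fi$matrix))))
  expect_equal(fi$meta$M_used, 60)
  expect_equal(dim(fi$meta$grads), c(60, 2))
  expect_true(all(fi$meta$entry_se >= 0))
})

test_that("the same seed reproduces the Monte-Carlo Fisher matrix", {
  d <- equidistant_design(10, 1)
  a <- fi_mss(id_model$network, id_model$param, d, M = 40, seed = 11)
  b <- fi_mss(id_model$network, id_model$param, d, M = 40, seed = 11)
  expect_identical(a$matrix, b$matrix)
})

test_that("a parameter no propensity uses gives a zero benchmark row", {
  net <- reaction_network(
    species = "X",
    reactions = list(
      list(educts = c(), products = c(X = 1), rate = "theta1"),
      list(educts = c(X = 1), products = c(), rate = "theta2 * X")
    ),
    params = c("theta1", "theta2", "theta3"))
  fb <- fi_benchmark(net, c(1, 0.1, 5), 10, equidistant_design(10, 1))
  expect_equal(unname(fb$matrix[3, ]), c(0, 0, 0))
  expect_equal(unname(fb$matrix[, 3]), c(0, 0, 0))
})

test_that("Fisher summaries compute criteria, correlation and predicted ARSE", {
  s <- summarize_fi(fisher_matrix(diag(2), c("a", "b"), "exact"),
                    theta_true = c(2, 4))
  expect_equal(s$D, 1)
  expect_equal(s$E, 1)
  expect_equal(s$correlation[1, 2], 0)
  expect_equal(unname(s$predicted_arse), c(50, 25))  # 100/theta_i

  s2 <- summarize_fi(fisher_matrix(diag(c(4, 1)), c("a", "b"), "exact"))
  expect_equal(s2$D, 4)
  expect_equal(s2$E, 1)

  sing <- summarize_fi(fisher_matrix(matrix(c(1, 1, 1, 1), 2), c("a", "b"), "exact"))
  expect_true(sing$singular)
  expect_null(sing$correlation)
})

test_that("benchmark and exact correlations agree at moderate spacing", {
  d <- equidistant_design(60, 2)
  cb <- summarize_fi(fi_benchmark(id_model$network, id_theta, 10, d))$correlation[1, 2]
  ce <- summarize_fi(fi_exact_id(id_theta, d, nu0 = 10))$correlation[1, 2]
  expect_lt(abs(cb - ce), 0.1)
})
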