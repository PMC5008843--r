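# Data generation: exact stochastic simulation (Gillespie's direct method)
# and the interval-wise LNA pseudo-data scheme used by the Monte-Carlo
# Fisher matrix.

# L'Ecuyer-CMRG substreams: trajectory k always sees the same stream for a
# given master seed, so growing M extends rather than reshuffles the
# ensemble. Returns a list of .Random.seed values.
#' @keywords internal
#' @noRd
rng_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  out <- vector("list", n)
  for (k in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    out[[k]] <- s
  }
  out
}

# Evaluate expr with .Random.seed set to a given stream state.
#' @keywords internal
#' @noRd
with_stream <- function(stream, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream, globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  expr
}

#' Exact stochastic simulation (Gillespie)
#'
#' Simulates one exact trajectory of the Markov jump process by the direct
#' method and samples it at the design's measurement times. When all
#' propensities vanish the state is frozen for the rest of the horizon.
#'
#' @inheritParams local_lna_terms
#' @param nu0 Nonnegative integer initial state at `design$t0`.
#' @param design An [ed_design()].
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#' @return A latent [timeseries()] (integer states, all species).
#' @examples
#' m <- builtin_model("immigration_death")
#' ts <- gillespie_simulate(m$network, c(1, 0.1), 10, equidistant_design(20, 1), seed = 1)
#' @export
gillespie_simulate <- function(network, theta, nu0, design, seed) {
  nu0 <- as.numeric(nu0)
  if (any(nu0 < 0) || any(nu0 != round(nu0))) stop("nu0 must be nonnegative integers")
  stream <- rng_streams(seed, 1)[[1]]
  vals <- with_stream(stream, gillespie_core(network, theta, nu0, design$t0, design$times))
  timeseries(vals, design, latent = TRUE, seed = seed)
}

#' @keywords internal
#' @noRd
gillespie_core <- function(network, theta, nu0, t0, times) {
  D <- length(nu0)
  n <- length(times)
  out <- matrix(NA_real_, n, D)
  colnames(out) <- network$species
  state <- nu0
  t <- t0
  next_i <- 1
  S <- network$S
  repeat {
    v <- propensity_eval(network, state, theta)
    a0 <- sum(v)
    if (!is.finite(a0)) stop("propensity overflow during simulation")
    t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    while (next_i <= n && times[next_i] < t_next) {
      out[next_i, ] <- state
      next_i <- next_i + 1
    }
    if (next_i > n) break
    j <- sample.int(length(v), 1, prob = v)
    state <- state + S[, j]
    t <- t_next
  }
  out
}

#' LNA pseudo-data generation
#'
#' Generates `M` pseudo datasets by iteratively sampling the interval-wise
#' LNA transition Gaussians: `nu_i = [Round](x(Delta_i) + u_i A_i)` with
#' `A_i' A_i = Sigma(Delta_i; theta, nu_{i-1})`, then
#' `O_i = nu_i^obs + u~_i B_i` with `B_i' B_i = Sigma_meas`. This is the
#' same approximation the MSS objective uses, so Fisher-information
#' evaluation is internally consistent, and (with rounding off) the states
#' depend smoothly on the parameters.
#'
#' Rounding is off by default (the configuration used for Fisher
#' information); enable it to emulate integer count data, in which case
#' negative rounded states are clamped at 0. Unrounded states are not
#' clamped: the Gaussian support is the whole real line.
#'
#' @inheritParams gillespie_simulate
#' @param param A [parameter_point()] (kinetic parameters, initial state,
#'   measurement covariance).
#' @param M Number of pseudo datasets.
#' @param rounding Round latent states to integers (default `FALSE`).
#' @param rtol,atol LNA integrator tolerances.
#' @return List of `M` observed [timeseries()] objects; each carries its
#'   latent trajectory in attribute `"latent"`.
#' @export
lna_pseudo_data <- function(network, param, design, M, seed, rounding = FALSE,
                            rtol = 1e-8, atol = 1e-10) {
  if (M < 1) stop("M must be >= 1")
  b <- lna_pseudo_data_batch(network, param, design, M, seed, rounding,
                             rtol = rtol, atol = atol)
  lapply(seq_len(M), function(k) {
    ts <- timeseries(b$obs[k, , , drop = TRUE], design, latent = FALSE, seed = seed)
    if (dim(b$obs)[3] == 1) ts$values <- matrix(b$obs[k, , 1], ncol = 1)
    if (dim(b$obs)[2] == 1) ts$values <- matrix(b$obs[k, 1, ], nrow = 1)
    colnames(ts$values) <- network$species[b$observed]
    attr(ts, "latent") <- matrix(b$latent[k, , ], dim(b$latent)[2], dim(b$latent)[3],
                                 dimnames = list(NULL, network$species))
    ts
  })
}

# Batched generator. Normal draws for trajectory k come from substream k of
# the master seed and depend only on (seed, n, D, obs), so the same seed
# yields the same draws at any parameter value (frozen-noise property).
# Returns obs: M x n x obs, latent: M x n x D, masks of nothing yet.
#' @keywords internal
#' @noRd
lna_pseudo_data_batch <- function(network, param, design, M, seed,
                                  rounding = FALSE, rtol = 1e-8, atol = 1e-10) {
  D <- length(network$species)
  obs_idx <- design_observed(design, network)
  n_obs <- length(obs_idx)
  n <- length(design$times)
  theta <- param$theta
  meas_cov <- resolve_meas_cov(param, n_obs)
  streams <- rng_streams(seed, M)
  u <- array(0, c(M, n, D))
  ut <- array(0, c(M, n, n_obs))
  for (k in seq_len(M)) {
    draws <- with_stream(streams[[k]], stats::rnorm(n * (D + n_obs)))
    u[k, , ] <- matrix(draws[seq_len(n * D)], n, D)
    ut[k, , ] <- matrix(draws[n * D + seq_len(n * n_obs)], n, n_obs)
  }
  B <- if (all(meas_cov == 0)) NULL else chol_factor(meas_cov)
  latent <- array(0, c(M, n, D))
  obs <- array(0, c(M, n, n_obs))
  # The drawn states are kept raw (the Gaussian support is the whole real
  # line), but the anchor from which the next interval is propagated is
  # floored at 0.1 -- the same numerical lower bound the MSS state
  # estimates use -- so that propensities stay nonnegative and the LNA
  # diffusion stays PSD when a trajectory grazes the state-space boundary.
  states <- pmax(matrix(rep(param$initial_state, each = M), M, D), STATE_FLOOR)
  tprev <- design$t0
  for (i in seq_len(n)) {
    dt <- design$times[i] - tprev
    pr <- propagate_interval_batch(network, theta, states, dt, rtol = rtol, atol = atol)
    if (D == 1) {
      nu <- pr$mean[, 1] + u[, i, 1] * sqrt(pmax(pr$cov[1, 1, ], 0))
      if (rounding) nu <- pmax(round(nu), 0)
      latent[, i, 1] <- nu
      o <- nu
      if (!is.null(B)) o <- o + ut[, i, 1] * B[1, 1]
      obs[, i, 1] <- o
    } else {
      for (k in seq_len(M)) {
        A <- chol_factor(pr$cov[, , k])
        nu <- pr$mean[k, ] + drop(u[k, i, ] %*% A)
        if (rounding) nu <- pmax(round(nu), 0)
        latent[k, i, ] <- nu
        o <- nu[obs_idx]
        if (!is.null(B)) o <- o + drop(ut[k, i, ] %*% B)
        obs[k, i, ] <- o
      }
    }
    states <- pmax(matrix(latent[, i, ], M, D), STATE_FLOOR)
    tprev <- design$times[i]
  }
  list(obs = obs, latent = latent, observed = obs_idx)
}
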