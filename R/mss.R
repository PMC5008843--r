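# The interval-wise MSS (multiple shooting for stochastic systems)
# log-likelihood approximation with state estimation.
#
# Each inter-measurement interval gets its own LNA started at the current
# state estimate with Sigma(0) = 0. The interval contribution is the
# closed-form Gaussian convolution of the LNA transition density with the
# Gaussian measurement density; after each interval the state estimate is
# updated to the joint mode of (prediction x measurement). Intervals whose
# standardized residuals are beyond the 1e-15 standard-normal quantile on
# any observed component are masked: their log-density contribution is
# dropped (the paper's outlier guard for occasional poor state estimates),
# but state updating still runs so later intervals stay anchored.

# q15: the 1e-15 quantile of a standard normal, approx -7.94.
MASK_QUANTILE <- stats::qnorm(1e-15)

# Lower bound on state-estimate components, for numerical reasons.
STATE_FLOOR <- 0.1

#' MSS state update
#'
#' Closed-form maximizer of the product of the Gaussian LNA prediction
#' density and the Gaussian measurement density: the precision-weighted
#' combination of prediction and observation on the observed components;
#' unobserved components take the conditional mode given the updated
#' observed components. Every component is then bounded below at 0.1.
#'
#' With `meas_cov = 0` the observed components are taken from the data
#' exactly; with very large measurement noise the update approaches the
#' prediction.
#'
#' @param pred_mean Predicted mean (length D).
#' @param pred_cov Predicted covariance (D x D, PSD after repair).
#' @param obs Observation vector (length = number of observed components).
#' @param meas_cov Measurement covariance (obs x obs; 0 allowed).
#' @param observed_indices Indices of the observed components.
#' @return Updated state estimate (length D).
#' @export
state_update <- function(pred_mean, pred_cov, obs, meas_cov, observed_indices) {
  D <- length(pred_mean)
  oi <- observed_indices
  ui <- setdiff(seq_len(D), oi)
  pred_cov <- as.matrix(pred_cov)
  meas_cov <- as.matrix(meas_cov)
  nu <- numeric(D)
  if (all(meas_cov == 0)) {
    # point-mass measurement: observed components pinned to the data
    nu[oi] <- obs
    if (length(ui)) {
      Soo <- pred_cov[oi, oi, drop = FALSE]
      if (rcond_safe(Soo) < 1e-14) {
        stop("singular prediction covariance on the observed block with zero measurement noise")
      }
      nu[ui] <- pred_mean[ui] +
        pred_cov[ui, oi, drop = FALSE] %*% solve(Soo, obs - pred_mean[oi])
    }
  } else {
    P <- diag(D)[oi, , drop = FALSE]
    prec_pred <- solve(psd_repair(pred_cov) + diag(1e-12, D))
    prec_meas <- solve(meas_cov)
    A <- prec_pred + t(P) %*% prec_meas %*% P
    b <- prec_pred %*% pred_mean + t(P) %*% prec_meas %*% obs
    nu <- drop(solve(A, b))
  }
  pmax(nu, STATE_FLOOR)
}

#' @keywords internal
#' @noRd
rcond_safe <- function(m) {
  if (length(m) == 1) return(abs(m[1]))
  tryCatch(rcond(m), error = function(e) 0)
}

#' Interval log-density and standardized residuals
#'
#' Closed form of the interval integral of the MSS objective: the
#' convolution of the Gaussian LNA transition density (projected to the
#' observed components) with the Gaussian measurement density, i.e. the
#' log-density of the observation under
#' `Normal(P x(dt), P Sigma(dt) P' + Sigma_meas)`, plus per-component
#' standardized (whitened) residuals.
#'
#' @inheritParams local_lna_terms
#' @param prev_state_estimate State estimate at the interval start.
#' @param obs_i Observation at the interval end.
#' @param dt Interval length (> 0).
#' @param meas_cov Measurement covariance (obs x obs).
#' @param observed_indices Indices of the observed components.
#' @param rtol,atol LNA integrator tolerances.
#' @return List with `logdens`, `residuals` (whitened, standard normal
#'   under the model), `pred_mean`, `pred_cov`.
#' @export
interval_logdensity <- function(network, theta, prev_state_estimate, obs_i, dt,
                                meas_cov, observed_indices,
                                rtol = 1e-8, atol = 1e-10) {
  if (dt <= 0) stop("dt must be positive")
  pr <- propagate_interval(network, theta, prev_state_estimate, dt,
                           rtol = rtol, atol = atol)
  oi <- observed_indices
  m <- pr$mean[oi]
  C <- pr$cov[oi, oi, drop = FALSE] + as.matrix(meas_cov)
  R <- chol_factor(C)
  z <- backsolve(R, obs_i - m, transpose = TRUE)
  ld <- -0.5 * length(oi) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
  list(logdens = ld, residuals = drop(z), pred_mean = pr$mean, pred_cov = pr$cov)
}

#' MSS log-likelihood
#'
#' Evaluates the MSS objective for one dataset: alternates interval
#' log-densities and state updates across the measurement intervals. The
#' value is the sum of the unmasked interval log-densities; an interval is
#' masked when any observed component's standardized residual exceeds the
#' 1e-15 standard-normal quantile in magnitude.
#'
#' @inheritParams local_lna_terms
#' @param data An observed [timeseries()].
#' @param param A [parameter_point()]; its `initial_state` provides the
#'   state estimate at `t0`.
#' @param rtol,atol LNA integrator tolerances.
#' @return List with `value` (the MSS objective), and `track`: a list with
#'   `estimates` ((n+1) x D state estimates including the initial one),
#'   `masked` (indices of masked intervals), `contributions` (per-interval
#'   log-densities, 0 where masked).
#' @examples
#' m <- builtin_model("immigration_death")
#' d <- equidistant_design(10, 1)
#' pd <- lna_pseudo_data(m$network, m$param, d, M = 1, seed = 1)
#' mss_loglik(m$network, pd[[1]], m$param)$value
#' @export
mss_loglik <- function(network, data, param, rtol = 1e-8, atol = 1e-10) {
  design <- data$design
  obs_idx <- design_observed(design, network)
  if (ncol(data$values) != length(obs_idx)) {
    stop("data columns do not match the design's observed components")
  }
  n <- length(design$times)
  obs_arr <- array(data$values, c(1, n, length(obs_idx)))
  out <- mss_batch_eval(network, design, obs_arr, theta = param$theta,
                        nu0 = param$initial_state,
                        meas_cov = resolve_meas_cov(param, length(obs_idx)),
                        obs_idx = obs_idx, rtol = rtol, atol = atol,
                        keep_track = TRUE)
  list(value = out$value[1],
       track = list(estimates = matrix(out$estimates[1, , ],
                                       ncol = length(network$species),
                                       dimnames = list(NULL, network$species)),
                    masked = which(out$masked[1, ]),
                    contributions = out$contributions[1, ]))
}

# Batched MSS evaluation across M datasets sharing one design and one
# parameter value. obs_arr: M x n x obs. nu0: length-D vector (shared) or
# M x D matrix. fixed_mask: optional M x n logical matrix of intervals to
# drop (used by the Fisher-matrix finite differences, where the mask is
# decided once at the evaluation point); when NULL the mask is computed
# from the residuals.
#' @keywords internal
#' @noRd
mss_batch_eval <- function(network, design, obs_arr, theta, nu0, meas_cov,
                           obs_idx, fixed_mask = NULL, rtol = 1e-8,
                           atol = 1e-10, keep_track = FALSE) {
  M <- dim(obs_arr)[1]
  n <- dim(obs_arr)[2]
  D <- length(network$species)
  n_o <- length(obs_idx)
  zero_meas <- all(meas_cov == 0)
  if (is.null(dim(nu0))) nu0 <- matrix(rep(as.numeric(nu0), each = M), M, D)
  states <- pmax(nu0, STATE_FLOOR)
  value <- numeric(M)
  masked <- matrix(FALSE, M, n)
  contributions <- if (keep_track) matrix(0, M, n) else NULL
  estimates <- if (keep_track) array(0, c(M, n + 1, D)) else NULL
  if (keep_track) estimates[, 1, ] <- states
  tprev <- design$t0
  ui <- setdiff(seq_len(D), obs_idx)
  for (i in seq_len(n)) {
    dt <- design$times[i] - tprev
    pr <- propagate_interval_batch(network, theta, states, dt, rtol = rtol, atol = atol)
    O <- matrix(obs_arr[, i, ], M, n_o)
    if (n_o == 1) {
      m_o <- pr$mean[, obs_idx]
      c_o <- pmax(pr$cov[obs_idx, obs_idx, ], 0) + meas_cov[1, 1]
      z <- (O[, 1] - m_o) / sqrt(c_o)
      ld <- -0.5 * log(2 * pi) - 0.5 * log(c_o) - 0.5 * z^2
      bad <- abs(z) > abs(MASK_QUANTILE)
    } else {
      ld <- numeric(M)
      bad <- logical(M)
      for (k in seq_len(M)) {
        C <- pr$cov[obs_idx, obs_idx, k] + meas_cov
        R <- chol_factor(C)
        zk <- backsolve(R, O[k, ] - pr$mean[k, obs_idx], transpose = TRUE)
        ld[k] <- -0.5 * n_o * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(zk^2)
        bad[k] <- any(abs(zk) > abs(MASK_QUANTILE))
      }
    }
    drop_i <- if (is.null(fixed_mask)) bad else fixed_mask[, i]
    masked[, i] <- if (is.null(fixed_mask)) bad else fixed_mask[, i]
    value <- value + ifelse(drop_i, 0, ld)
    if (keep_track) contributions[, i] <- ifelse(drop_i, 0, ld)
    # state update (runs for masked intervals too, to keep the filtration)
    if (zero_meas) {
      upd <- pr$mean
      upd[, obs_idx] <- O
      if (length(ui)) {
        if (n_o == 1 && length(ui) == 1) {
          s_oo <- pr$cov[obs_idx, obs_idx, ]
          s_uo <- pr$cov[ui, obs_idx, ]
          gain <- ifelse(s_oo > 0, s_uo / s_oo, 0)
          upd[, ui] <- pr$mean[, ui] + gain * (O[, 1] - pr$mean[, obs_idx])
        } else {
          for (k in seq_len(M)) {
            Soo <- pr$cov[obs_idx, obs_idx, k]
            upd[k, ui] <- pr$mean[k, ui] +
              pr$cov[ui, obs_idx, k, drop = FALSE] %*%
                solve(Soo + diag(1e-12, n_o), O[k, ] - pr$mean[k, obs_idx])
          }
        }
      }
      states <- pmax(upd, STATE_FLOOR)
    } else {
      upd <- matrix(0, M, D)
      for (k in seq_len(M)) {
        upd[k, ] <- state_update(pr$mean[k, ], pr$cov[, , k], O[k, ],
                                 meas_cov, obs_idx)
      }
      states <- upd
    }
    if (keep_track) estimates[, i + 1, ] <- states
    tprev <- design$times[i]
  }
  list(value = value, masked = masked, contributions = contributions,
       estimates = estimates)
}
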