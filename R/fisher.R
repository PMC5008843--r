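# Fisher information matrices: the Monte-Carlo FI over the MSS objective,
# the full-horizon-LNA benchmark, and the exact CME solution for the
# Immigration-Death process.

#' Fisher matrix container
#'
#' @param matrix Symmetric p x p matrix.
#' @param labels Names of the p free parameters.
#' @param method One of `"mss"`, `"benchmark"`, `"exact"`, `"empirical"`.
#' @param meta List of metadata (M, seed, fd_step, truncation, mask
#'   statistics, ...).
#' @return A `fisher_matrix` object.
#' @export
fisher_matrix <- function(matrix, labels, method, meta = list()) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("Fisher matrix must be square")
  if (nrow(matrix) != length(labels)) stop("labels length must match dimension")
  rel_asym <- max(abs(matrix - t(matrix))) / max(abs(matrix), 1e-300)
  if (rel_asym > 1e-8) stop("Fisher matrix is not symmetric")
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = symmetrize(matrix), labels = labels,
                 method = method, meta = meta),
            class = "fisher_matrix")
}

#' @export
print.fisher_matrix <- function(x, ...) {
  cat(sprintf("<fisher_matrix (%s), %d parameters>\n", x$method, length(x$labels)))
  print(signif(x$matrix, 4))
  invisible(x)
}

#' Monte-Carlo MSS Fisher information
#'
#' Approximates the Fisher information as the Monte-Carlo mean, over `M`
#' pseudo datasets drawn from the interval-wise LNA scheme, of outer
#' products of the gradient of the MSS objective:
#' `FI = (1/M) sum_k g_k g_k'` with
#' `g_k = d F_MSS(O^(k), vartheta) / d vartheta`.
#'
#' The free-parameter vector `vartheta` contains the free kinetic
#' parameters, the free (by default unobserved) initial-state components
#' and any free measurement-noise entries, as declared in the
#' [parameter_point()]. Gradients are computed by central finite
#' differences; the pseudo data and the interval mask are held fixed at the
#' evaluation point while `vartheta` is perturbed.
#'
#' @inheritParams lna_pseudo_data
#' @param fd_step Relative finite-difference step (absolute floor 1e-6).
#' @return A [fisher_matrix()] with `method = "mss"`. Metadata includes
#'   `M`, `seed`, `fd_step`, the per-entry standard error of the
#'   Monte-Carlo mean (`entry_se`), running means over k (`running`,
#'   p(p+1)/2 columns) and mask statistics.
#' @examples
#' \donttest{
#' m <- builtin_model("immigration_death")
#' fi <- fi_mss(m$network, m$param, equidistant_design(20, 1), M = 50, seed = 1)
#' summarize_fi(fi, theta_true = m$param$theta)$correlation
#' }
#' @export
fi_mss <- function(network, param, design, M, seed, fd_step = 1e-4,
                   rtol = 1e-8, atol = 1e-10) {
  if (M < 2) stop("M must be >= 2")
  design <- resolve_design(design, network)
  layout <- free_layout(param, design, network)
  p <- length(layout$value)
  if (p < 1) stop("the free-parameter vector is empty")
  pd <- lna_pseudo_data_batch(network, param, design, M, seed, rounding = FALSE,
                              rtol = rtol, atol = atol)
  obs_idx <- pd$observed
  meas_cov <- resolve_meas_cov(param, length(obs_idx))
  # mask decided once, at the evaluation point
  base <- mss_batch_eval(network, design, pd$obs, param$theta,
                         param$initial_state, meas_cov, obs_idx,
                         rtol = rtol, atol = atol)
  mask <- base$masked
  all_masked <- rowSums(!mask) == 0
  keep <- which(!all_masked)
  if (length(keep) < M) {
    warning(sprintf("%d pseudo dataset(s) had all intervals masked and were dropped",
                    M - length(keep)))
  }
  if (length(keep) < 2) stop("fewer than 2 usable pseudo datasets")
  G <- matrix(0, length(keep), p)
  h <- fd_steps(layout$value, rel = fd_step, floor_ = 1e-6)
  for (j in seq_len(p)) {
    up <- layout$value; up[j] <- up[j] + h[j]
    dn <- layout$value; dn[j] <- dn[j] - h[j]
    fp <- eval_vartheta(network, design, pd$obs, keep, mask, layout, up,
                        obs_idx, rtol, atol)
    fm <- eval_vartheta(network, design, pd$obs, keep, mask, layout, dn,
                        obs_idx, rtol, atol)
    G[, j] <- (fp - fm) / (2 * h[j])
  }
  Mk <- length(keep)
  FI <- crossprod(G) / Mk
  # per-entry Monte-Carlo convergence: running mean of the outer-product
  # terms and the standard error of the final mean
  terms_ij <- function(i, j) G[, i] * G[, j]
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  running <- matrix(0, Mk, nrow(pairs))
  entry_se <- matrix(0, p, p)
  for (q in seq_len(nrow(pairs))) {
    tt <- terms_ij(pairs[q, 1], pairs[q, 2])
    running[, q] <- cumsum(tt) / seq_len(Mk)
    se <- stats::sd(tt) / sqrt(Mk)
    entry_se[pairs[q, 1], pairs[q, 2]] <- se
    entry_se[pairs[q, 2], pairs[q, 1]] <- se
  }
  colnames(running) <- paste0(layout$labels[pairs[, 1]], ":", layout$labels[pairs[, 2]])
  fisher_matrix(FI, layout$labels, "mss",
                meta = list(M = M, M_used = Mk, seed = seed, fd_step = fd_step,
                            grads = G, entry_se = entry_se, running = running,
                            masked_total = sum(mask[keep, , drop = FALSE]),
                            masked_per_dataset = rowSums(mask[keep, , drop = FALSE])))
}

#' @keywords internal
#' @noRd
eval_vartheta <- function(network, design, obs_arr, keep, mask, layout,
                          vartheta, obs_idx, rtol, atol) {
  pp <- layout$set(vartheta)
  mss_batch_eval(network, design,
                 obs_arr[keep, , , drop = FALSE], pp$theta, pp$initial_state,
                 pp$meas_cov, obs_idx,
                 fixed_mask = mask[keep, , drop = FALSE],
                 rtol = rtol, atol = atol)$value
}

#' Benchmark full-horizon Fisher information
#'
#' The Fisher matrix of the multivariate normal model over the whole
#' stacked trajectory: mean equal to the rate-equation solution and
#' covariance `Sigma_B` from a single full-horizon LNA with inter-temporal
#' covariances. Entry (j, k) is
#' `dmu'/dtheta_j Sigma_B^-1 dmu/dtheta_k +
#'  1/2 trace(Sigma_B^-1 dSigma_B/dtheta_j Sigma_B^-1 dSigma_B/dtheta_k)`,
#' with derivatives by central finite differences. Deterministic (no Monte
#' Carlo); kinetic parameters only.
#'
#' @inheritParams full_horizon_moments
#' @param fd_step Relative finite-difference step.
#' @return A [fisher_matrix()] with `method = "benchmark"`.
#' @export
fi_benchmark <- function(network, theta, nu0, design, fd_step = 1e-4,
                         rtol = 1e-8, atol = 1e-10) {
  p <- length(theta)
  base <- full_horizon_moments(network, theta, nu0, design, rtol = rtol, atol = atol)
  SB <- psd_repair(base$sigma_b)
  R <- tryCatch(chol(SB), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(SB + diag(1e-10 * max(diag(SB)), nrow(SB))),
                  error = function(e) NULL)
    if (is.null(R)) {
      stop(sprintf("Sigma_B is numerically singular (rcond = %.2e)", rcond_safe(SB)))
    }
  }
  SBinv <- chol2inv(R)
  h <- fd_steps(theta, rel = fd_step, floor_ = 1e-6)
  dmu <- vector("list", p)
  dSB <- vector("list", p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    mp <- full_horizon_moments(network, tp, nu0, design, rtol = rtol, atol = atol)
    mm <- full_horizon_moments(network, tm, nu0, design, rtol = rtol, atol = atol)
    dmu[[j]] <- (mp$mu - mm$mu) / (2 * h[j])
    dSB[[j]] <- (mp$sigma_b - mm$sigma_b) / (2 * h[j])
  }
  FI <- matrix(0, p, p)
  W <- lapply(dSB, function(dS) SBinv %*% dS)
  for (j in seq_len(p)) {
    for (k in j:p) {
      val <- drop(t(dmu[[j]]) %*% SBinv %*% dmu[[k]]) +
        0.5 * sum(W[[j]] * t(W[[k]]))
      FI[j, k] <- FI[k, j] <- val
    }
  }
  fisher_matrix(FI, paste0("theta", seq_len(p)), "benchmark",
                meta = list(fd_step = fd_step, rcond = rcond_safe(SB)))
}

#' Exact Immigration-Death transition probability
#'
#' The exact CME transition probability of the Immigration-Death process
#' (immigration rate `theta1`, per-capita death rate `theta2`): the state
#' after `dt` is the sum of Binomial(`nu0`, `exp(-theta2 dt)`) survivors
#' and Poisson(`theta1/theta2 (1 - exp(-theta2 dt))`) immigrants.
#'
#' @param k Target state(s), nonnegative integers (vectorized).
#' @param dt Time increment.
#' @param nu0 Start state, a nonnegative integer.
#' @param theta Parameters `(theta1, theta2)`.
#' @return Probabilities `P(k, dt | nu0, theta)`.
#' @examples
#' # Poisson tail mass above 30 from an empty start after a long horizon
#' 1 - sum(exact_transition_id(0:30, 1500, 0, c(1, 0.1)))
#' @export
exact_transition_id <- function(k, dt, nu0, theta) {
  if (any(k < 0) || any(k != round(k))) stop("k must be nonnegative integers")
  if (nu0 < 0 || nu0 != round(nu0)) stop("nu0 must be a nonnegative integer")
  p_surv <- exp(-theta[2] * dt)
  lambda <- theta[1] / theta[2] * (1 - p_surv)
  vapply(k, function(kk) {
    j <- 0:min(kk, nu0)
    sum(stats::dbinom(j, nu0, p_surv) * stats::dpois(kk - j, lambda))
  }, numeric(1))
}

# Transition matrix over states 0..trunc: entry [k+1, m+1] = P(k | m, dt).
# Vectorized as (Poisson-immigration Toeplitz) %*% (binomial-survival):
# P(k | m) = sum_j dpois(k - j, lambda) dbinom(j, m, p).
#' @keywords internal
#' @noRd
id_transition_matrix <- function(dt, theta, trunc) {
  p_surv <- exp(-theta[2] * dt)
  lambda <- theta[1] / theta[2] * (1 - p_surv)
  states <- 0:trunc
  B <- outer(states, states, function(j, m) stats::dbinom(j, m, p_surv))
  Tp <- outer(states, states, function(k, j) {
    ifelse(k >= j, stats::dpois(pmax(k - j, 0), lambda), 0)
  })
  Tp %*% B
}

#' Exact Immigration-Death Fisher information
#'
#' Deterministic Fisher matrix from the exact CME transition law on a
#' truncated state space: a double sum over successive states of
#' log-derivative outer products weighted by the transition probability and
#' the marginal state distribution at the interval start, accumulated over
#' all measurement intervals. Log-derivatives by central finite differences
#' in `theta`.
#'
#' @param theta Parameters `(theta1, theta2)`.
#' @param design An [ed_design()].
#' @param truncation Largest state kept (default 30).
#' @param nu0 Initial state at `design$t0`.
#' @param fd_step Relative finite-difference step.
#' @return A [fisher_matrix()] with `method = "exact"`.
#' @export
fi_exact_id <- function(theta, design, truncation = 30, nu0 = 10,
                        fd_step = 1e-4) {
  if (nu0 > truncation) stop("truncation must be at least nu0")
  n <- length(design$times)
  dts <- diff(c(design$t0, design$times))
  h <- fd_steps(theta, rel = fd_step, floor_ = 1e-6)
  uniq <- unique(dts)
  mats <- lapply(uniq, function(dt) {
    T0 <- id_transition_matrix(dt, theta, trunc = truncation)
    dlog <- lapply(seq_along(theta), function(j) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      (log(id_transition_matrix(dt, tp, truncation)) -
       log(id_transition_matrix(dt, tm, truncation))) / (2 * h[j])
    })
    # w[[j]][[k]] over start states: sum over target states of the weighted
    # log-derivative products
    w <- lapply(seq_along(theta), function(j) {
      lapply(seq_along(theta), function(k) {
        colSums(dlog[[j]] * dlog[[k]] * T0)
      })
    })
    list(T = T0, w = w)
  })
  names(mats) <- as.character(uniq)
  p <- length(theta)
  FI <- matrix(0, p, p)
  marg <- numeric(truncation + 1)
  marg[nu0 + 1] <- 1
  deficit <- 0
  for (i in seq_len(n)) {
    mi <- mats[[as.character(dts[i])]]
    for (j in seq_len(p)) for (k in j:p) {
      val <- sum(mi$w[[j]][[k]] * marg)
      FI[j, k] <- FI[j, k] + val
      if (k > j) FI[k, j] <- FI[j, k]
    }
    # probability mass leaking above the truncation in this interval,
    # weighted by how much of the marginal sits at each start state
    deficit <- max(deficit, sum((1 - colSums(mi$T)) * marg))
    marg <- drop(mi$T %*% marg)
  }
  if (deficit > 1e-6) {
    stop(sprintf("truncated probability mass deficit %.2e > 1e-6; increase truncation",
                 deficit))
  }
  fisher_matrix(FI, paste0("theta", seq_len(p)), "exact",
                meta = list(truncation = truncation, nu0 = nu0, fd_step = fd_step))
}

#' Summarize a Fisher matrix
#'
#' Optimality criteria and estimator-precision summaries: the D-criterion
#' (determinant, confidence-ellipsoid volume), the E-criterion (minimum
#' eigenvalue, largest ellipsoid axis), the estimator correlation matrix
#' from the inverse, and the predicted relative error per parameter
#' `100 sqrt((FI^-1)_ii) / theta_i` when true values are supplied.
#'
#' @param fi A [fisher_matrix()].
#' @param theta_true Optional true parameter values aligned with the
#'   Fisher labels (used for the predicted ARSE).
#' @return List with `D`, `E`, `correlation`, `covariance`,
#'   `predicted_arse` (or `NULL`), and `singular` (`TRUE` when the matrix
#'   is not invertible, flagging structural non-identifiability; only the
#'   criteria are then returned).
#' @export
summarize_fi <- function(fi, theta_true = NULL) {
  m <- fi$matrix
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  out <- list(D = det(m), E = min(ev), singular = FALSE,
              correlation = NULL, covariance = NULL, predicted_arse = NULL)
  cov <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(cov) || rcond_safe(m) < 1e-14) {
    out$singular <- TRUE
    return(out)
  }
  sdv <- sqrt(diag(cov))
  corr <- cov / outer(sdv, sdv)
  dimnames(corr) <- dimnames(cov) <- list(fi$labels, fi$labels)
  out$covariance <- cov
  out$correlation <- corr
  if (!is.null(theta_true)) {
    if (length(theta_true) != length(fi$labels)) {
      stop("theta_true length must match the Fisher labels")
    }
    out$predicted_arse <- 100 * sdv / theta_true
    names(out$predicted_arse) <- fi$labels
  }
  out
}
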