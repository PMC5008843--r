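# Linear noise approximation: interval-wise moment propagation and
# full-horizon moments with inter-temporal covariances.
#
# The mean follows the rate equations dx/dt = S v(x, theta); the covariance
# follows dSigma/dt = J Sigma + Sigma J' + Omega^-1 D with Sigma(0) = 0,
# J = S dv/dx and D_ik = sum_j S_ij S_kj v_j. Only the upper triangle of
# Sigma is integrated; the result is symmetrized and slightly negative
# eigenvalues from floating-point drift are clamped ("PSD repair").
#
# All propagation is performed by a batched integrator that advances an
# ensemble of M independent (mean, covariance) systems in one solver call;
# the Monte-Carlo Fisher matrix leans on this to evaluate hundreds of
# pseudo datasets jointly.

# vech index pairs for the upper triangle of a D x D matrix.
#' @keywords internal
#' @noRd
vech_pairs <- function(D) {
  idx <- which(upper.tri(diag(D), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' Local LNA terms
#'
#' Evaluates the drift Jacobian `J = S dv/dx` and the diffusion matrix
#' `D_ik = sum_j S_ij S_kj v_j` of the linear noise approximation at a
#' state.
#'
#' @inheritParams propensity_eval
#' @param x Nonnegative state vector.
#' @return List with matrices `J` (D x D) and `Dmat` (D x D, symmetric PSD
#'   when all propensities are nonnegative).
#' @export
local_lna_terms <- function(network, x, theta) {
  D <- length(network$species)
  states <- matrix(as.numeric(x), 1, D)
  v <- propensity_eval_batch(network, states, theta)[1, ]
  if (any(!is.finite(v))) stop("non-finite propensity at the given state")
  jac <- propensity_jac_batch(network, states, theta)
  if (any(!vapply(jac, function(m) all(is.finite(m)), logical(1)))) {
    stop("non-finite propensity derivative at the given state")
  }
  S <- network$S
  dvdx <- do.call(rbind, lapply(jac, function(m) m[1, ]))  # r x D
  J <- S %*% dvdx
  Dmat <- S %*% (v * t(S))
  list(J = unname(J), Dmat = unname(symmetrize(Dmat)))
}

# Batched joint mean/covariance ODE over one interval.
# start_states: M x D. Returns list(mean = M x D, cov = array D x D x M).
#' @keywords internal
#' @noRd
propagate_interval_batch <- function(network, theta, start_states, dt,
                                     rtol = 1e-8, atol = 1e-10) {
  M <- nrow(start_states)
  D <- ncol(start_states)
  if (dt < 0) stop("dt must be nonnegative")
  if (dt == 0) {
    return(list(mean = start_states, cov = array(0, c(D, D, M))))
  }
  # lsoda reserves an O(n^2) workspace; cap the joint system size and
  # stitch larger ensembles from chunks
  states_per <- D + D * (D + 1) / 2
  max_chunk <- max(1L, floor(2000 / states_per))
  if (M > max_chunk) {
    idx <- split(seq_len(M), ceiling(seq_len(M) / max_chunk))
    mean <- matrix(0, M, D)
    cov <- array(0, c(D, D, M))
    for (ii in idx) {
      part <- propagate_interval_batch(network, theta,
                                       start_states[ii, , drop = FALSE], dt,
                                       rtol = rtol, atol = atol)
      mean[ii, ] <- part$mean
      cov[, , ii] <- part$cov
    }
    return(list(mean = mean, cov = cov))
  }
  S <- network$S
  r <- ncol(S)
  vp <- vech_pairs(D)
  nv <- nrow(vp)
  np <- D + nv  # states per trajectory
  omega_inv <- 1 / network$volume
  # map (i,k) -> vech slot
  slot <- matrix(0L, D, D)
  for (k in seq_len(nv)) {
    slot[vp[k, 1], vp[k, 2]] <- k
    slot[vp[k, 2], vp[k, 1]] <- k
  }
  # Trajectory-major packing: y = (x_1..x_D, vech Sigma) per trajectory,
  # concatenated. The joint system is block diagonal across trajectories,
  # so the solver can be told the Jacobian is banded with width np - 1 —
  # otherwise the stiff (BDF) phase would difference and factorize a dense
  # (M*np)^2 Jacobian, which dominates the cost for stiff models.
  rhs <- function(t, y, p) {
    Y <- matrix(y, np, M)
    states <- t(Y[seq_len(D), , drop = FALSE])
    v <- propensity_eval_batch(network, states, theta)
    jac <- propensity_jac_batch(network, states, theta)
    # J[i,k] per dataset: sum_j S[i,j] * dv_j/dx_k
    Jm <- vector("list", D * D)
    for (i in seq_len(D)) for (k in seq_len(D)) {
      acc <- 0
      for (j in seq_len(r)) if (S[i, j] != 0) acc <- acc + S[i, j] * jac[[j]][, k]
      Jm[[(i - 1) * D + k]] <- acc
    }
    Jget <- function(i, k) Jm[[(i - 1) * D + k]]
    sget <- function(i, k) Y[D + slot[i, k], ]
    dY <- matrix(0, np, M)
    for (i in seq_len(D)) {
      acc <- 0
      for (j in seq_len(r)) if (S[i, j] != 0) acc <- acc + S[i, j] * v[, j]
      dY[i, ] <- acc
    }
    for (kk in seq_len(nv)) {
      i <- vp[kk, 1]; k <- vp[kk, 2]
      acc <- 0
      for (l in seq_len(D)) {
        acc <- acc + Jget(i, l) * sget(l, k) + sget(i, l) * Jget(k, l)
      }
      dmat <- 0
      for (j in seq_len(r)) {
        if (S[i, j] != 0 && S[k, j] != 0) dmat <- dmat + S[i, j] * S[k, j] * v[, j]
      }
      dY[D + kk, ] <- acc + omega_inv * dmat
    }
    list(as.numeric(dY))
  }
  y0 <- as.numeric(rbind(t(start_states), matrix(0, nv, M)))
  sol <- deSolve::ode(y = y0, times = c(0, dt), func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      jactype = "bandint", bandup = np - 1, banddown = np - 1)
  if (nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), -1]))) {
    stop(sprintf("LNA integrator failed over dt = %g (rtol %g, atol %g, reached t = %g)",
                 dt, rtol, atol, sol[nrow(sol), 1]))
  }
  YT <- matrix(sol[nrow(sol), -1], np, M)
  mean <- t(YT[seq_len(D), , drop = FALSE])
  cov <- array(0, c(D, D, M))
  for (kk in seq_len(nv)) {
    i <- vp[kk, 1]; k <- vp[kk, 2]
    cov[i, k, ] <- YT[D + kk, ]
    cov[k, i, ] <- YT[D + kk, ]
  }
  list(mean = mean, cov = cov)
}

#' Propagate interval moments
#'
#' Jointly integrates the mean ODE and the LNA covariance ODE from a start
#' state over an interval of length `dt`, with `Sigma(0) = 0`.
#'
#' @inheritParams local_lna_terms
#' @param start_state Start state (length D).
#' @param dt Interval length, `>= 0`.
#' @param rtol,atol Integrator tolerances (stiff-capable `lsoda`).
#' @return List with `dt`, `mean` (length D) and `cov` (D x D, symmetric,
#'   PSD-repaired).
#' @examples
#' m <- builtin_model("immigration_death")
#' propagate_interval(m$network, c(1, 0.1), 10, 1)  # var = 10 (1 - e^-0.2)
#' @export
propagate_interval <- function(network, theta, start_state, dt,
                               rtol = 1e-8, atol = 1e-10) {
  D <- length(network$species)
  out <- propagate_interval_batch(network, theta,
                                  matrix(as.numeric(start_state), 1, D), dt,
                                  rtol = rtol, atol = atol)
  cov <- symmetrize(out$cov[, , 1, drop = TRUE])
  if (D == 1) cov <- matrix(out$cov[1, 1, 1], 1, 1)
  list(dt = dt, mean = drop(out$mean[1, ]), cov = psd_repair(cov))
}

#' Full-horizon LNA moments
#'
#' Computes the stacked mean vector and the full inter-temporal covariance
#' matrix of the benchmark approach: one mean ODE run over the whole
#' horizon, the covariance `Sigma(t)` integrated from `Sigma(t0) = 0`, and
#' the fundamental matrix `Phi(t0, t)` from `dPhi/dt = J(x(t)) Phi`. The
#' covariance between times `s <= t` is `Sigma(s) Phi(s, t)'` with
#' `Phi(s, t) = Phi(t0, t) Phi(t0, s)^-1`; blocks for `s > t` follow by
#' symmetry.
#'
#' @inheritParams local_lna_terms
#' @param nu0 Initial state at `design$t0`.
#' @param design An [ed_design()]; the stacked moments cover its
#'   measurement times (the initial time has zero variance and is excluded).
#' @param rtol,atol Integrator tolerances.
#' @return List with `mu` (length n*D stacked means), `sigma_b`
#'   (n*D x n*D symmetric block matrix), `mean` (n x D), `cov` (list of
#'   D x D per time), `phi_step` (list of per-interval fundamental
#'   matrices `Phi(t_{i-1}, t_i)`), `times`.
#' @export
full_horizon_moments <- function(network, theta, nu0, design,
                                 rtol = 1e-8, atol = 1e-10) {
  D <- length(network$species)
  times <- design$times
  n <- length(times)
  S <- network$S
  r <- ncol(S)
  vp <- vech_pairs(D)
  nv <- nrow(vp)
  omega_inv <- 1 / network$volume
  slot <- matrix(0L, D, D)
  for (k in seq_len(nv)) {
    slot[vp[k, 1], vp[k, 2]] <- k
    slot[vp[k, 2], vp[k, 1]] <- k
  }
  rhs <- function(t, y, p) {
    x <- y[seq_len(D)]
    states <- matrix(x, 1, D)
    v <- propensity_eval_batch(network, states, theta)[1, ]
    jac <- propensity_jac_batch(network, states, theta)
    dvdx <- do.call(rbind, lapply(jac, function(m) m[1, ]))
    J <- S %*% dvdx
    Sig <- matrix(0, D, D)
    for (kk in seq_len(nv)) {
      Sig[vp[kk, 1], vp[kk, 2]] <- Sig[vp[kk, 2], vp[kk, 1]] <- y[D + kk]
    }
    dSig <- J %*% Sig + Sig %*% t(J) + omega_inv * S %*% (v * t(S))
    Phi <- matrix(y[D + nv + seq_len(D * D)], D, D)
    dPhi <- J %*% Phi
    list(c(drop(S %*% v), dSig[upper.tri(dSig, diag = TRUE)][order_vech(D)],
           as.numeric(dPhi)))
  }
  # One pass over the horizon, restarting the fundamental matrix at the
  # identity at each measurement time: per-interval factors
  # Phi_i = Phi(t_{i-1}, t_i) stay well scaled even when Phi(t0, t) decays
  # below double precision over long horizons.
  mean_m <- matrix(0, n, D)
  cov_l <- vector("list", n)
  phi_step <- vector("list", n)
  x <- as.numeric(nu0)
  sig_vech <- rep(0, nv)
  tprev <- design$t0
  for (i in seq_len(n)) {
    y0 <- c(x, sig_vech, as.numeric(diag(D)))
    sol <- deSolve::ode(y = y0, times = c(tprev, times[i]), func = rhs,
                        parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
    if (nrow(sol) < 2 || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf("LNA integrator failed over the full horizon near t = %g", tprev))
    }
    yT <- sol[nrow(sol), -1]
    x <- yT[seq_len(D)]
    sig_vech <- yT[D + seq_len(nv)]
    mean_m[i, ] <- x
    Sig <- matrix(0, D, D)
    for (kk in seq_len(nv)) {
      Sig[vp[kk, 1], vp[kk, 2]] <- Sig[vp[kk, 2], vp[kk, 1]] <- sig_vech[kk]
    }
    cov_l[[i]] <- symmetrize(Sig)
    phi_step[[i]] <- matrix(yT[D + nv + seq_len(D * D)], D, D)
    tprev <- times[i]
  }
  sigma_b <- matrix(0, n * D, n * D)
  for (i in seq_len(n)) {
    bi <- (i - 1) * D + seq_len(D)
    sigma_b[bi, bi] <- cov_l[[i]]
    if (i < n) {
      blk <- cov_l[[i]]                    # becomes cov(nu(t_i), nu(t_j))
      for (j in (i + 1):n) {
        bj <- (j - 1) * D + seq_len(D)
        blk <- blk %*% t(phi_step[[j]])    # right-multiply by Phi(t_{j-1}, t_j)'
        sigma_b[bi, bj] <- blk
        sigma_b[bj, bi] <- t(blk)
      }
    }
  }
  list(mu = as.numeric(t(mean_m)), sigma_b = symmetrize(sigma_b),
       mean = mean_m, cov = cov_l, phi_step = phi_step, times = times)
}

# upper.tri(diag=TRUE) enumerates column-major already; keep an explicit
# permutation so the vech layout matches vech_pairs.
#' @keywords internal
#' @noRd
order_vech <- function(D) seq_len(D * (D + 1) / 2)
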