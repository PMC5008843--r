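# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
symmetrize <- function(m) (m + t(m)) / 2

# Clamp slightly negative eigenvalues introduced by floating-point drift in
# the covariance ODE. Eigenvalues below -tol_rel * max(|lambda|, 1) are left
# alone (that indicates a genuinely indefinite matrix and is reported by the
# caller); those in [-tol, 0) are set to 0.
#' @keywords internal
#' @noRd
psd_repair <- function(m, tol_rel = 1e-10) {
  m <- symmetrize(m)
  e <- eigen(m, symmetric = TRUE)
  lam <- e$values
  floor_ <- -tol_rel * max(abs(lam[1]), 1)
  lam[lam < 0 & lam >= floor_] <- 0
  e$vectors %*% (lam * t(e$vectors))
}

# Upper-triangular factor A with t(A) %*% A == m, after PSD repair.
#' @keywords internal
#' @noRd
chol_factor <- function(m, tol_rel = 1e-10) {
  r <- tryCatch(chol(symmetrize(m)), error = function(e) NULL)
  if (is.null(r)) {
    r <- tryCatch(chol(psd_repair(m, tol_rel) + diag(1e-12 * max(diag(m), 1), nrow(m))),
                  error = function(e) NULL)
  }
  if (is.null(r)) stop("covariance factorization failed after PSD repair")
  r
}

# Log-density of a multivariate normal, via Cholesky. x may be a matrix with
# one row per evaluation point.
#' @keywords internal
#' @noRd
dmvnorm_log <- function(x, mean, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- ncol(x)
  R <- chol_factor(sigma)
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

# Relative central-difference step sizes with an absolute floor.
#' @keywords internal
#' @noRd
fd_steps <- function(x, rel = 1e-4, floor_ = 1e-6) {
  pmax(abs(x) * rel, floor_)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
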