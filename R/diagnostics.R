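# LNA-validity diagnostics.
#
# Two complementary checks: (1) whitened-residual Kolmogorov-Smirnov tests
# of the Gaussian assumption, either over the whole stacked trajectory
# (the benchmark's assumption) or interval-wise (the MSS assumption); and
# (2) the half-step Fisher consistency check, which inserts midpoints into
# the design and compares the diagonals of the two Fisher matrices —
# ratios far from 1 flag a breakdown of the interval-wise LNA.

#' Whitened-residual Kolmogorov-Smirnov test
#'
#' Tests whether a latent trajectory is compatible with the Gaussian model
#' at the true parameters. In `"benchmark"` mode the stacked trajectory is
#' whitened with the full-horizon moments (`z = A (nu - mu)` with
#' `(A' A)^-1 = Sigma_B`); in `"interval"` mode each interval residual
#' `nu_i - x(Delta_i; theta, nu_{i-1})` is whitened with its interval LNA
#' covariance and the pieces are concatenated. A two-sided KS test
#' compares the whitened sample with the standard normal.
#'
#' @inheritParams local_lna_terms
#' @param data A latent [timeseries()] with all species observed.
#' @param nu0 Initial state at `design$t0` (the known starting point of
#'   the trajectory).
#' @param mode `"benchmark"` or `"interval"`.
#' @param rtol,atol LNA integrator tolerances.
#' @return List with `whitened` (the whitened vector), `p_value`, and
#'   `statistic`.
#' @export
whitened_residual_ks <- function(data, network, theta, nu0,
                                 mode = c("benchmark", "interval"),
                                 rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  if (!data$latent || ncol(data$values) != length(network$species)) {
    stop("the whitening test needs a fully observed latent trajectory")
  }
  design <- data$design
  if (mode == "benchmark") {
    fh <- full_horizon_moments(network, theta, nu0, design,
                               rtol = rtol, atol = atol)
    resid <- as.numeric(t(data$values)) - fh$mu
    A <- chol_factor(solve(psd_repair(fh$sigma_b) +
                             diag(1e-10 * max(diag(fh$sigma_b)), length(resid))))
    z <- drop(A %*% resid)
  } else {
    n <- length(design$times)
    D <- length(network$species)
    z <- numeric(0)
    prev <- as.numeric(nu0)
    tprev <- design$t0
    for (i in seq_len(n)) {
      pr <- propagate_interval(network, theta, pmax(prev, STATE_FLOOR),
                               design$times[i] - tprev, rtol = rtol, atol = atol)
      A <- chol_factor(solve(psd_repair(pr$cov) + diag(1e-10 * max(diag(pr$cov), 1), D)))
      z <- c(z, drop(A %*% (data$values[i, ] - pr$mean)))
      prev <- data$values[i, ]
      tprev <- design$times[i]
    }
  }
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(whitened = z, p_value = ks$p.value, statistic = unname(ks$statistic))
}

#' Half-step Fisher consistency check
#'
#' Computes the MSS Fisher matrix on the design `T` and on the refined
#' design `T'` that inserts a midpoint into every interval, using the same
#' master seed, and returns the elementwise ratios of the two diagonals.
#' If the interval-wise LNA holds, halving the step must not change the
#' information content, so ratios should be near 1; ratios orders of
#' magnitude away flag an LNA breakdown for that inter-sample distance.
#'
#' @inheritParams fi_mss
#' @param refine If `FALSE` the second design is `T` itself (degenerate
#'   control: all ratios exactly 1).
#' @return List with `ratios` (per free parameter), `mean`, `sd`, and the
#'   two Fisher matrices.
#' @export
halfstep_fi_check <- function(network, param, design, M, seed,
                              refine = TRUE, ...) {
  if (length(design$times) < 2 && refine) stop("design needs at least 2 times")
  m1 <- fi_mss(network, param, design, M = M, seed = seed, ...)
  design2 <- if (refine) {
    tt <- c(design$t0, design$times)
    mids <- (tt[-1] + tt[-length(tt)]) / 2
    ed_design(sort(c(design$times, mids)), observed = design$observed,
              t0 = design$t0)
  } else design
  m2 <- fi_mss(network, param, design2, M = M, seed = seed, ...)
  ratios <- diag(m1$matrix) / diag(m2$matrix)
  list(ratios = stats::setNames(ratios, m1$labels),
       mean = mean(ratios), sd = stats::sd(ratios),
       fi_T = m1, fi_Tprime = m2)
}
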