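# Maximum-likelihood estimation under the three objectives and the
# empirical Fisher matrix assembled from repeated estimates.

#' Estimate parameters by maximum likelihood
#'
#' Maximizes one of the three objectives over the free parameters:
#' the MSS objective (interval-wise LNA with state estimation), the
#' full-horizon benchmark (multivariate-normal log-density of the stacked
#' trajectory), or the exact Immigration-Death transition likelihood.
#' Optimization is a bounded derivative-free local search (Nelder-Mead on
#' log-parameters with a soft box penalty) from multiple starts; the best
#' converged start is returned.
#'
#' @inheritParams mss_loglik
#' @param param_init A [parameter_point()] giving the starting values and
#'   the free-parameter declaration.
#' @param method One of `"mss"`, `"benchmark"`, `"exact_id"`.
#' @param lower,upper Bounds on the free parameters (recycled; defaults
#'   `init/100` and `init*100`).
#' @param n_starts Number of multi-starts (first start at `param_init`,
#'   the rest log-uniform between the bounds).
#' @param seed Seed for the multi-start draws.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return List with `theta_hat` (named free-parameter estimate),
#'   `objective_value`, `converged`, `n_evaluations`, `method`, and
#'   `param_hat` (a [parameter_point()] at the optimum).
#' @export
estimate_parameters <- function(network, data, param_init,
                                method = c("mss", "benchmark", "exact_id"),
                                lower = NULL, upper = NULL, n_starts = 5,
                                seed = 1, control = list()) {
  method <- match.arg(method)
  design <- resolve_design(data$design, network)
  layout <- free_layout(param_init, design, network)
  v0 <- layout$value
  p <- length(v0)
  lower <- rep_len(lower %||% (v0 / 100), p)
  upper <- rep_len(upper %||% (v0 * 100), p)
  if (any(lower <= 0)) stop("bounds must be positive")
  obs_idx <- design$observed

  objective <- switch(method,
    mss = function(vt) {
      pp <- layout$set(vt)
      mss_batch_eval(network, design,
                     array(data$values, c(1, nrow(data$values), ncol(data$values))),
                     pp$theta, pp$initial_state, pp$meas_cov, obs_idx)$value[1]
    },
    benchmark = {
      if (!setequal(obs_idx, seq_along(network$species))) {
        stop("the benchmark objective requires full observation")
      }
      function(vt) {
        pp <- layout$set(vt)
        fh <- full_horizon_moments(network, pp$theta, pp$initial_state, design)
        SB <- fh$sigma_b + diag(1e-10, length(fh$mu))
        as.numeric(dmvnorm_log(as.numeric(t(data$values)), fh$mu, SB))
      }
    },
    exact_id = {
      if (length(network$species) != 1) {
        stop("the exact objective applies to the Immigration-Death model only")
      }
      vals <- round(data$values[, 1])
      trunc_ <- max(30, max(vals) + 10, max(param_init$initial_state) + 10)
      dts <- diff(c(design$t0, design$times))
      prev <- c(param_init$initial_state[1], vals[-length(vals)])
      function(vt) {
        pp <- layout$set(vt)
        ll <- 0
        for (u in unique(dts)) {
          sel <- which(dts == u)
          Tm <- id_transition_matrix(u, pp$theta, trunc_)
          ll <- ll + sum(log(pmax(Tm[cbind(vals[sel] + 1, prev[sel] + 1)], 1e-300)))
        }
        ll
      }
    })

  # log-scale objective with a soft box penalty
  neg_obj <- function(lv) {
    vt <- exp(lv)
    pen <- sum(pmax(vt / upper - 1, 0)^2 + pmax(lower / vt - 1, 0)^2)
    val <- tryCatch(objective(pmin(pmax(vt, lower), upper)),
                    error = function(e) -Inf)
    if (!is.finite(val)) return(1e10)
    -val + 1e6 * pen
  }
  starts <- matrix(log(v0), 1, p)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    extra <- matrix(stats::runif((n_starts - 1) * p, log(lower), log(upper)),
                    n_starts - 1, p, byrow = (p == 1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    starts <- rbind(starts, extra)
  }
  best <- NULL
  n_eval <- 0
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], neg_obj, method = "Nelder-Mead",
                   control = utils::modifyList(list(maxit = 2000, reltol = 1e-10), control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_eval <- n_eval + fit$counts[1]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e9) {
    return(list(theta_hat = stats::setNames(rep(NA_real_, p), layout$labels),
                objective_value = NA_real_, converged = FALSE,
                n_evaluations = n_eval, method = method, param_hat = NULL))
  }
  vt <- pmin(pmax(exp(best$par), lower), upper)
  pp <- layout$set(vt)
  list(theta_hat = stats::setNames(vt, layout$labels),
       objective_value = -best$value, converged = TRUE,
       n_evaluations = n_eval, method = method,
       param_hat = parameter_point(pp$theta, pp$initial_state,
                                   meas_cov = param_init$meas_cov,
                                   free_theta = param_init$free_theta,
                                   free_nu0 = param_init$free_nu0,
                                   free_meas = param_init$free_meas))
}

#' Empirical Fisher matrix from repeated estimates
#'
#' Inverts the sample covariance of estimates obtained from independently
#' simulated datasets, after removing non-converged replicates, and
#' reports the empirical average relative squared error
#' `ARSE_i = 100 sqrt(mean((theta_hat_i - theta_i)^2 / theta_i^2))`.
#'
#' @param estimates Matrix of estimates, one row per replicate.
#' @param theta_true True parameter values (length = columns).
#' @param convergence_rule Predicate on one estimate row returning `TRUE`
#'   when the replicate converged. The default replicates the
#'   Immigration-Death filter: the first component must not exceed 3.
#' @return List with `fi` (a [fisher_matrix()], `method = "empirical"`),
#'   `arse` (per parameter, percent), `n_excluded`, `n_used`.
#' @export
empirical_fi_from_estimates <- function(estimates, theta_true,
                                        convergence_rule = function(est) est[1] <= 3) {
  estimates <- as.matrix(estimates)
  p <- ncol(estimates)
  keep <- apply(estimates, 1, function(r) all(is.finite(r)) && isTRUE(convergence_rule(r)))
  est <- estimates[keep, , drop = FALSE]
  if (nrow(est) < p + 1) stop("need at least p + 1 converged estimates")
  Cov <- stats::cov(est)
  FIe <- tryCatch(solve(Cov), error = function(e) {
    stop("sample covariance of the estimates is singular")
  })
  arse <- 100 * sqrt(colMeans((sweep(est, 2, theta_true) / rep(theta_true, each = nrow(est)))^2))
  labels <- colnames(estimates) %||% paste0("theta", seq_len(p))
  list(fi = fisher_matrix(symmetrize(FIe), labels, "empirical",
                          meta = list(n_used = nrow(est), n_excluded = sum(!keep))),
       arse = stats::setNames(arse, labels),
       n_excluded = sum(!keep), n_used = nrow(est))
}

#' Simulation-estimation batch driver
#'
#' Simulates `n_sim` datasets with the Gillespie algorithm at the true
#' parameters, estimates the free parameters on each with the chosen
#' objective, and assembles the empirical Fisher matrix and ARSEs.
#'
#' @inheritParams estimate_parameters
#' @param param A [parameter_point()] at the true values.
#' @param design An [ed_design()].
#' @param n_sim Number of simulated datasets.
#' @param seed Master seed; dataset k uses substream k.
#' @param param_init Starting [parameter_point()] for the estimations
#'   (defaults to the truth; pass a perturbed point for a harder study).
#' @param convergence_rule Passed to [empirical_fi_from_estimates()].
#' @param ... Passed to [estimate_parameters()].
#' @return List with `estimates` (n_sim x p), `empirical` (see
#'   [empirical_fi_from_estimates()]), `n_converged`.
#' @export
simulation_study <- function(network, param, design, n_sim, seed,
                             method = "mss", param_init = param,
                             convergence_rule = function(est) est[1] <= 3, ...) {
  design <- resolve_design(design, network)
  layout <- free_layout(param, design, network)
  p <- length(layout$value)
  est <- matrix(NA_real_, n_sim, p, dimnames = list(NULL, layout$labels))
  for (k in seq_len(n_sim)) {
    ts <- gillespie_simulate(network, param$theta, round(param$initial_state),
                             design, seed = seed + k)
    obs <- timeseries(ts$values[, design$observed, drop = FALSE], design,
                      latent = FALSE, seed = seed + k)
    fit <- estimate_parameters(network, obs, param_init, method = method,
                               n_starts = 1, seed = seed + k, ...)
    if (fit$converged) est[k, ] <- fit$theta_hat
  }
  emp <- empirical_fi_from_estimates(est, layout$value, convergence_rule)
  list(estimates = est, empirical = emp,
       n_converged = sum(stats::complete.cases(est)))
}
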