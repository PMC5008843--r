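# Design evaluation and optimal-design search.

#' Scan equidistant designs
#'
#' Evaluates a Fisher matrix and an optimality criterion for a family of
#' equidistant designs with a fixed number of observations and varying
#' inter-sample distance. For the Monte-Carlo MSS Fisher matrix the same
#' master seed is reused across designs so that the comparison is not
#' blurred by simulation noise.
#'
#' @inheritParams fi_mss
#' @param dts Numeric vector of inter-sample distances.
#' @param n_points Number of observations per design.
#' @param criterion `"D"` (determinant), `"E"` (minimum eigenvalue) or
#'   `"ARSE"` (mean predicted relative error, percent).
#' @param fi_method `"mss"`, `"benchmark"` or `"exact_id"`.
#' @param M Pseudo datasets per design (MSS method only).
#' @param ... Passed to the Fisher-matrix constructor.
#' @return A data frame with columns `dt`, `criterion`, `value`.
#' @export
scan_designs <- function(network, param, dts, n_points,
                         criterion = c("D", "E", "ARSE"),
                         fi_method = c("mss", "benchmark", "exact_id"),
                         M = 500, seed = 1, ...) {
  criterion <- match.arg(criterion)
  fi_method <- match.arg(fi_method)
  if (length(dts) < 1) stop("empty design grid")
  vals <- vapply(dts, function(dt) {
    design <- equidistant_design(n_points, dt)
    fi <- design_fi(network, param, design, fi_method, M, seed, ...)
    criterion_value(fi, criterion, param)
  }, numeric(1))
  data.frame(dt = dts, criterion = criterion, value = vals)
}

#' @keywords internal
#' @noRd
design_fi <- function(network, param, design, fi_method, M, seed, ...) {
  switch(fi_method,
    mss = fi_mss(network, param, design, M = M, seed = seed, ...),
    benchmark = fi_benchmark(network, param$theta, param$initial_state, design, ...),
    exact_id = fi_exact_id(param$theta, design, nu0 = param$initial_state[1], ...))
}

#' @keywords internal
#' @noRd
criterion_value <- function(fi, criterion, param) {
  s <- summarize_fi(fi, theta_true = NULL)
  switch(criterion,
    D = s$D,
    E = s$E,
    ARSE = {
      if (s$singular) return(NA_real_)
      p <- min(length(param$theta), length(fi$labels))
      mean(100 * sqrt(diag(s$covariance))[seq_len(p)] / param$theta[seq_len(p)])
    })
}

#' Particle-swarm design optimization
#'
#' Searches for the measurement schedule maximizing an optimality
#' criterion of the Fisher matrix. The search space is the vector of
#' inter-sample distances (so time ordering holds by construction) within
#' `spacing_bounds`; times are accumulated from `t0 = 0`. With
#' `integer_times` the candidate times are rounded to integers (ties
#' toward the smaller time) and duplicate times repaired by unit shifts.
#' The Fisher matrix is evaluated with a fixed seed, making the stochastic
#' MSS objective deterministic so that standard optimizers apply.
#'
#' PSO hyperparameters beyond `iterations`/`particles` are fixed
#' conventional defaults: inertia 0.7, cognitive and social weights 1.5,
#' reflecting bounds.
#'
#' @inheritParams scan_designs
#' @param n_points Number of observations in the design.
#' @param spacing_bounds Length-2 vector `(lo, hi)` of admissible
#'   inter-sample distances (default `c(1, 12)`).
#' @param integer_times Restrict observation times to integers.
#' @param iterations,particles PSO budget (defaults 20 and 25).
#' @param criterion `"D"` or `"E"`.
#' @return List with `design` (the best [ed_design()]), `value` (its
#'   criterion), and `trace` (best value per iteration, nondecreasing).
#' @export
optimize_design_pso <- function(network, param, n_points,
                                spacing_bounds = c(1, 12),
                                integer_times = TRUE,
                                criterion = c("D", "E"),
                                fi_method = c("mss", "benchmark", "exact_id"),
                                M = 500, iterations = 20, particles = 25,
                                seed = 1, observed = NULL, ...) {
  criterion <- match.arg(criterion)
  fi_method <- match.arg(fi_method)
  lo <- spacing_bounds[1]; hi <- spacing_bounds[2]
  if (!(0 < lo && lo <= hi)) stop("need 0 < lo <= hi spacing bounds")
  if (n_points < 2) stop("n_points must be >= 2")

  times_of <- function(spacings) {
    tms <- cumsum(spacings)
    if (integer_times) {
      # round half toward the smaller time, then repair duplicates upward
      tms <- ceiling(tms - 0.5)
      tms[1] <- max(tms[1], 1)
      for (i in seq_along(tms)[-1]) {
        if (tms[i] <= tms[i - 1]) tms[i] <- tms[i - 1] + 1
      }
    }
    tms
  }
  evaluate <- function(spacings) {
    design <- ed_design(times_of(spacings), observed = observed)
    fi <- design_fi(network, param, design, fi_method, M, seed, ...)
    v <- criterion_value(fi, criterion, param)
    if (!is.finite(v)) -Inf else v
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 1L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  pos <- matrix(stats::runif(particles * n_points, lo, hi), particles, n_points)
  vel <- matrix(stats::runif(particles * n_points, -(hi - lo), hi - lo) / 4,
                particles, n_points)
  pbest <- pos
  pbest_val <- apply(pos, 1, evaluate)
  gi <- which.max(pbest_val)
  gbest <- pbest[gi, ]
  gbest_val <- pbest_val[gi]
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(particles * n_points), particles, n_points)
    r2 <- matrix(stats::runif(particles * n_points), particles, n_points)
    gmat <- matrix(gbest, particles, n_points, byrow = TRUE)
    vel <- w * vel + c1 * r1 * (pbest - pos) + c2 * r2 * (gmat - pos)
    pos <- pos + vel
    # reflecting bounds
    over <- pos > hi; pos[over] <- 2 * hi - pos[over]; vel[over] <- -vel[over]
    under <- pos < lo; pos[under] <- 2 * lo - pos[under]; vel[under] <- -vel[under]
    pos <- pmin(pmax(pos, lo), hi)
    vals <- apply(pos, 1, evaluate)
    imp <- vals > pbest_val
    pbest[imp, ] <- pos[imp, , drop = FALSE]
    pbest_val[imp] <- vals[imp]
    gi <- which.max(pbest_val)
    if (pbest_val[gi] > gbest_val) {
      gbest_val <- pbest_val[gi]
      gbest <- pbest[gi, ]
    }
    trace[it] <- gbest_val
  }
  list(design = ed_design(times_of(gbest), observed = observed),
       value = gbest_val, trace = trace)
}
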