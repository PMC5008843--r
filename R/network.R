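# Reaction-network representation.
#
# A network is a D x r stoichiometric matrix together with r propensity
# expressions in particle-number units. Propensities are stored as R
# expression trees (not opaque closures) so that the species Jacobian
# needed by the LNA can be formed symbolically via stats::D, with a
# finite-difference fallback for expressions D() cannot differentiate.

#' Build a reaction network
#'
#' Constructs a validated reaction network from per-reaction educt/product
#' counts and propensity expressions. Propensities are given in
#' particle-number units; the reaction volume `volume` enters the LNA
#' diffusion term as `volume^-1 * D`.
#'
#' @param species Character vector of species names (columns of the state).
#' @param reactions A list; each element is a list with fields
#'   `educts`, `products` (named integer vectors over species; omitted
#'   species count 0) and `rate`, a one-sided formula or string giving the
#'   propensity as an expression in the species and parameter names.
#' @param params Character vector of kinetic-parameter names.
#' @param volume Positive reaction volume Omega (default 1; the built-in
#'   models are formulated directly in molecule counts).
#' @param name Optional model name.
#' @return An object of class `reaction_network` with fields `species`,
#'   `S` (D x r net stoichiometry), `propensities` (list of expressions),
#'   `params`, `volume`.
#' @examples
#' net <- reaction_network(
#'   species = "X",
#'   reactions = list(
#'     list(educts = c(), products = c(X = 1), rate = "theta1"),
#'     list(educts = c(X = 1), products = c(), rate = "theta2 * X")
#'   ),
#'   params = c("theta1", "theta2")
#' )
#' propensity_eval(net, state = 10, theta = c(1, 0.1))
#' @export
reaction_network <- function(species, reactions, params, volume = 1, name = NULL) {
  species <- as.character(species)
  params <- as.character(params)
  if (anyDuplicated(species)) stop("duplicate species names")
  if (anyDuplicated(params)) stop("duplicate parameter names")
  if (length(intersect(species, params))) stop("a name cannot be both species and parameter")
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0) {
    stop("volume must be a positive scalar")
  }
  D <- length(species)
  r <- length(reactions)
  if (r < 1) stop("at least one reaction is required")

  S <- matrix(0L, D, r, dimnames = list(species, NULL))
  prop <- vector("list", r)
  for (j in seq_len(r)) {
    rx <- reactions[[j]]
    ed <- rx$educts %||% integer()
    pr <- rx$products %||% integer()
    for (side in list(ed, pr)) {
      if (length(side)) {
        bad <- setdiff(names(side), species)
        if (length(bad)) stop(sprintf("reaction %d: unknown species '%s'", j, bad[1]))
        if (any(side != round(side)) || any(side < 0)) {
          stop(sprintf("reaction %d: stoichiometry must be nonnegative integers", j))
        }
      }
    }
    net <- stats::setNames(rep(0L, D), species)
    if (length(pr)) net[names(pr)] <- net[names(pr)] + as.integer(pr)
    if (length(ed)) net[names(ed)] <- net[names(ed)] - as.integer(ed)
    S[, j] <- net
    ex <- rx$rate
    if (inherits(ex, "formula")) ex <- ex[[2]]
    if (is.character(ex)) ex <- str2lang(ex)
    if (!is.language(ex) && !is.numeric(ex)) {
      stop(sprintf("reaction %d: rate must be an expression or string", j))
    }
    syms <- all.vars(ex)
    bad <- setdiff(syms, c(species, params))
    if (length(bad)) stop(sprintf("reaction %d: unknown symbol '%s' in rate", j, bad[1]))
    prop[[j]] <- ex
  }

  structure(
    list(species = species, S = S, propensities = prop, params = params,
         volume = volume, name = name,
         .prop_fun = compile_propensities(species, params, prop),
         .jac_fun = compile_propensity_jacobian(species, params, prop)),
    class = "reaction_network"
  )
}

# Compile the propensity expressions into one function (state, theta) -> r
# propensities. Species/parameter names are bound in an evaluation frame;
# the expressions vectorize over batched states (each species a vector).
#' @keywords internal
#' @noRd
compile_propensities <- function(species, params, prop) {
  force(species); force(params); force(prop)
  function(state_list, theta) {
    env <- list2env(state_list, parent = baseenv())
    for (i in seq_along(params)) assign(params[i], theta[[i]], envir = env)
    lapply(prop, eval, envir = env)
  }
}

# Symbolic d v_j / d x_i where stats::D succeeds, otherwise NULL entries
# trigger a finite-difference fallback at evaluation time.
#' @keywords internal
#' @noRd
compile_propensity_jacobian <- function(species, params, prop) {
  r <- length(prop)
  D <- length(species)
  dexpr <- vector("list", r)
  for (j in seq_len(r)) {
    dexpr[[j]] <- lapply(species, function(s) {
      tryCatch(stats::D(prop[[j]], s), error = function(e) NULL)
    })
  }
  force(params)
  function(state_list, theta) {
    env <- list2env(state_list, parent = baseenv())
    for (i in seq_along(params)) assign(params[i], theta[[i]], envir = env)
    # returns list over reactions of list over species of derivative values
    lapply(seq_len(r), function(j) {
      lapply(seq_len(D), function(i) {
        de <- dexpr[[j]][[i]]
        if (is.null(de)) NA_real_ else eval(de, envir = env)
      })
    })
  }
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network%s: %d species, %d reactions, %d parameters, volume %g>\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$species), ncol(x$S), length(x$params), x$volume))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (j in seq_len(ncol(x$S))) {
    cat(sprintf("  R%d: %s  [S: %s]\n", j, deparse1(x$propensities[[j]]),
                paste(x$S[, j], collapse = ",")))
  }
  invisible(x)
}

#' Evaluate reaction propensities
#'
#' Evaluates the propensity (particle-number rate) of every reaction at a
#' state and parameter vector.
#'
#' @param network A [reaction_network()].
#' @param state Nonnegative numeric state vector (length D).
#' @param theta Positive numeric kinetic-parameter vector.
#' @param check If `TRUE` (default), error on negative or non-finite
#'   propensities, naming the offending reaction.
#' @return Numeric vector of length r.
#' @export
propensity_eval <- function(network, state, theta, check = TRUE) {
  stopifnot(inherits(network, "reaction_network"))
  D <- length(network$species)
  if (length(state) != D) stop("state length does not match species count")
  if (length(theta) != length(network$params)) stop("theta length does not match parameter count")
  sl <- stats::setNames(as.list(as.numeric(state)), network$species)
  v <- vapply(network$.prop_fun(sl, as.numeric(theta)), as.numeric, numeric(1))
  if (check) {
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("propensity of reaction %d is %s at the given state",
                   bad[1], format(v[bad[1]])))
    }
  }
  v
}

# Batched propensity evaluation: states is an M x D matrix; returns M x r.
#' @keywords internal
#' @noRd
propensity_eval_batch <- function(network, states, theta) {
  M <- nrow(states)
  sl <- stats::setNames(lapply(seq_along(network$species), function(i) states[, i]),
                        network$species)
  vl <- network$.prop_fun(sl, as.numeric(theta))
  out <- matrix(0, M, length(vl))
  for (j in seq_along(vl)) out[, j] <- vl[[j]]  # scalars recycle
  out
}

# Batched propensity Jacobian: returns list over reactions of M x D matrices.
# NA entries (symbolic differentiation unavailable) are filled by central
# finite differences on the state.
#' @keywords internal
#' @noRd
propensity_jac_batch <- function(network, states, theta) {
  M <- nrow(states)
  D <- ncol(states)
  sl <- stats::setNames(lapply(seq_len(D), function(i) states[, i]), network$species)
  jl <- network$.jac_fun(sl, as.numeric(theta))
  r <- length(jl)
  out <- vector("list", r)
  for (j in seq_len(r)) {
    m <- matrix(0, M, D)
    for (i in seq_len(D)) {
      val <- jl[[j]][[i]]
      if (length(val) == 1 && is.na(val)) {
        h <- pmax(abs(states[, i]) * 1e-6, 1e-8)
        up <- states; up[, i] <- up[, i] + h
        dn <- states; dn[, i] <- dn[, i] - h
        m[, i] <- (propensity_eval_batch(network, up, theta)[, j] -
                   propensity_eval_batch(network, dn, theta)[, j]) / (2 * h)
      } else {
        m[, i] <- val
      }
    }
    out[[j]] <- m
  }
  out
}

#' Parameter point
#'
#' Bundles the kinetic parameters, initial state and measurement-noise
#' covariance at which Fisher matrices and likelihoods are evaluated, plus
#' a specification of which entries form the free-parameter vector.
#'
#' The free-parameter vector consists of the free kinetic parameters, the
#' free initial-state components (by default the components a design leaves
#' unobserved) and any free measurement-noise entries; its layout defines
#' all Fisher-matrix dimensions.
#'
#' @param theta Positive kinetic-parameter vector (named or in network order).
#' @param initial_state Nonnegative initial state (length D).
#' @param meas_cov Measurement-noise covariance over the observed
#'   components, a symmetric PSD matrix, a scalar (isotropic), or `NULL`
#'   for noise-free observation (the default used in the Immigration-Death
#'   and Lotka-Volterra studies).
#' @param free_theta Logical vector: which kinetic parameters are free
#'   (default all).
#' @param free_nu0 Which initial-state components are free: `"unobserved"`
#'   (default; resolved against the design at use time), a logical vector,
#'   or `FALSE` for none.
#' @param free_meas Logical: treat the diagonal of `meas_cov` as free
#'   (default `FALSE`).
#' @return A `parameter_point` object.
#' @export
parameter_point <- function(theta, initial_state, meas_cov = NULL,
                            free_theta = TRUE, free_nu0 = "unobserved",
                            free_meas = FALSE) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("theta must be positive and finite")
  initial_state <- as.numeric(initial_state)
  if (any(initial_state < 0)) stop("initial_state must be nonnegative")
  if (length(free_theta) == 1) free_theta <- rep(isTRUE(free_theta), length(theta))
  structure(list(theta = theta, initial_state = initial_state,
                 meas_cov = meas_cov, free_theta = free_theta,
                 free_nu0 = free_nu0, free_meas = free_meas),
            class = "parameter_point")
}

#' @export
print.parameter_point <- function(x, ...) {
  cat("<parameter_point>\n  theta:", paste(signif(x$theta, 6), collapse = ", "),
      "\n  initial state:", paste(x$initial_state, collapse = ", "), "\n")
  invisible(x)
}

# Resolve the measurement covariance to a concrete obs x obs matrix.
#' @keywords internal
#' @noRd
resolve_meas_cov <- function(param, n_obs_comp) {
  mc <- param$meas_cov
  if (is.null(mc)) return(matrix(0, n_obs_comp, n_obs_comp))
  if (length(mc) == 1) return(diag(as.numeric(mc), n_obs_comp))
  mc <- as.matrix(mc)
  if (!isTRUE(all.equal(mc, t(mc)))) stop("meas_cov must be symmetric")
  if (nrow(mc) != n_obs_comp) stop("meas_cov dimension does not match observed components")
  mc
}

# The free-parameter vector vartheta = (free theta, free nu0, free meas_cov
# diagonal), with labels, plus a setter reconstructing a parameter_point.
#' @keywords internal
#' @noRd
free_layout <- function(param, design, network) {
  ft <- param$free_theta
  theta_idx <- which(ft)
  nu0_free <- param$free_nu0
  D <- length(param$initial_state)
  if (identical(nu0_free, "unobserved")) {
    nu0_idx <- setdiff(seq_len(D), design$observed)
  } else if (isFALSE(nu0_free) || is.null(nu0_free)) {
    nu0_idx <- integer()
  } else {
    nu0_idx <- which(rep_len(as.logical(nu0_free), D))
  }
  mc <- resolve_meas_cov(param, length(design$observed))
  meas_idx <- if (isTRUE(param$free_meas)) seq_len(nrow(mc)) else integer()
  labels <- c(paste0("theta", theta_idx),
              if (length(nu0_idx)) paste0("nu0_", network$species[nu0_idx]),
              if (length(meas_idx)) paste0("measvar", meas_idx))
  value <- c(param$theta[theta_idx], param$initial_state[nu0_idx], diag(mc)[meas_idx])
  list(
    labels = labels,
    value = value,
    theta_idx = theta_idx, nu0_idx = nu0_idx, meas_idx = meas_idx,
    set = function(vartheta) {
      th <- param$theta
      nu0 <- param$initial_state
      k <- length(theta_idx)
      th[theta_idx] <- vartheta[seq_len(k)]
      if (length(nu0_idx)) nu0[nu0_idx] <- vartheta[k + seq_along(nu0_idx)]
      mc2 <- mc
      if (length(meas_idx)) {
        diag(mc2)[meas_idx] <- vartheta[k + length(nu0_idx) + seq_along(meas_idx)]
      }
      list(theta = th, initial_state = nu0, meas_cov = mc2)
    }
  )
}
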