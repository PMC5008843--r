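# The three built-in study models: Immigration-Death, Lotka-Volterra and a
# bursting Calcium oscillation model (G-protein / PLC / cytosolic Ca).

#' Built-in reaction-network models
#'
#' Returns one of the three study models together with its reference
#' parameters and initial state.
#'
#' \describe{
#'   \item{`immigration_death`}{Constitutive gene expression: immigration at
#'     rate `theta1`, first-order death at `theta2 * X`. Reference
#'     `theta = (1, 0.1)`, `x0 = 10` (the stationary Poisson mean).}
#'   \item{`lotka_volterra`}{Prey reproduction `theta1 * Y1`, predation
#'     `theta2 * Y1 * Y2`, predator death `theta3 * Y2`. Reference
#'     `theta = (0.5, 0.0025, 0.3)`, `nu0 = (71, 79)`.}
#'   \item{`calcium`}{Three-species Calcium oscillation model: active
#'     G-protein subunit `G`, activated phospholipase C `PLC`, and cytosolic
#'     calcium `Ca`, with Michaelis-Menten degradation terms. The rate ODEs
#'     are decomposed into 8 unit-stoichiometry reactions, one per additive
#'     term; this term-wise split is the standard stochastic reading of the
#'     model and is not unique (any split whose net rates reproduce the ODE
#'     right-hand side has the same mean dynamics, but the diffusion term
#'     depends on the decomposition).}
#' }
#'
#' @param name One of `"immigration_death"`, `"lotka_volterra"`,
#'   `"calcium"`.
#' @return A list with elements `network` (a [reaction_network()]) and
#'   `param` (a [parameter_point()] holding the reference parameters).
#' @examples
#' m <- builtin_model("lotka_volterra")
#' m$network$S
#' m$param$theta
#' @export
builtin_model <- function(name = c("immigration_death", "lotka_volterra", "calcium")) {
  name <- match.arg(name)
  switch(name,
    immigration_death = {
      net <- reaction_network(
        species = "X",
        reactions = list(
          list(educts = c(), products = c(X = 1), rate = "theta1"),
          list(educts = c(X = 1), products = c(), rate = "theta2 * X")
        ),
        params = c("theta1", "theta2"),
        name = "immigration_death"
      )
      list(network = net,
           param = parameter_point(theta = c(1, 0.1), initial_state = 10))
    },
    lotka_volterra = {
      net <- reaction_network(
        species = c("Y1", "Y2"),
        reactions = list(
          list(educts = c(Y1 = 1), products = c(Y1 = 2), rate = "theta1 * Y1"),
          list(educts = c(Y1 = 1, Y2 = 1), products = c(Y1 = 0, Y2 = 2),
               rate = "theta2 * Y1 * Y2"),
          list(educts = c(Y2 = 1), products = c(), rate = "theta3 * Y2")
        ),
        params = c("theta1", "theta2", "theta3"),
        name = "lotka_volterra"
      )
      list(network = net,
           param = parameter_point(theta = c(0.5, 0.0025, 0.3),
                                   initial_state = c(71, 79)))
    },
    calcium = {
      # One reaction per additive ODE term, unit stoichiometry.
      net <- reaction_network(
        species = c("Ca", "G", "PLC"),
        reactions = list(
          list(educts = c(), products = c(G = 1), rate = "theta1"),
          list(educts = c(), products = c(G = 1), rate = "theta2 * G"),
          list(educts = c(G = 1), products = c(), rate = "theta3 * G * Ca / (G + theta4)"),
          list(educts = c(G = 1), products = c(), rate = "theta5 * G * PLC / (G + theta6)"),
          list(educts = c(), products = c(PLC = 1), rate = "theta7 * G"),
          list(educts = c(PLC = 1), products = c(), rate = "theta8 * PLC / (PLC + theta9)"),
          list(educts = c(), products = c(Ca = 1), rate = "theta10 * G"),
          list(educts = c(Ca = 1), products = c(), rate = "theta11 * Ca / (Ca + theta12)")
        ),
        params = paste0("theta", 1:12),
        name = "calcium"
      )
      theta <- c(212, 2.95, 1.52, 190, 4.88, 1180, 1.24, 32240, 29090,
                 13.58, 153000, 160)
      list(network = net,
           param = parameter_point(theta = theta, initial_state = c(10, 10, 10)))
    }
  )
}

#' ODE right-hand side of a reaction network
#'
#' Evaluates `S %*% v(x, theta)`, the deterministic rate equations.
#'
#' @inheritParams propensity_eval
#' @return Numeric vector of length D.
#' @export
ode_rhs <- function(network, state, theta) {
  drop(network$S %*% propensity_eval(network, state, theta, check = FALSE))
}
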