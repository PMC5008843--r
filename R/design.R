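# Experimental designs and time-series containers.

#' Experimental design
#'
#' A design is the ordered set of measurement times, the observed species
#' and (through the parameter point) the measurement-noise covariance. The
#' initial time `t0` carries the known initial condition and is not itself
#' a measurement: a design with `n` times has `n` observations and `n`
#' likelihood intervals, matching the convention "100 observations" = 100
#' inter-sample intervals after `t0`.
#'
#' @param times Strictly increasing measurement times, all greater than `t0`.
#' @param observed Integer indices of the observed species (default: all
#'   species, resolved at use time when `NULL`).
#' @param t0 Initial time (default 0).
#' @return An `ed_design` object with fields `times`, `observed`, `t0`.
#' @examples
#' equidistant_design(n = 100, dt = 1)
#' @export
ed_design <- function(times, observed = NULL, t0 = 0) {
  times <- as.numeric(times)
  if (length(times) < 1) stop("at least one measurement time is required")
  if (any(diff(c(t0, times)) <= 0)) stop("times must be strictly increasing and > t0")
  if (!is.null(observed)) {
    observed <- sort(unique(as.integer(observed)))
    if (length(observed) < 1 || any(observed < 1)) stop("observed must be positive indices")
  }
  structure(list(times = times, observed = observed, t0 = t0), class = "ed_design")
}

#' @rdname ed_design
#' @param n Number of observations (intervals).
#' @param dt Inter-sample distance.
#' @export
equidistant_design <- function(n, dt, observed = NULL, t0 = 0) {
  ed_design(t0 + dt * seq_len(n), observed = observed, t0 = t0)
}

#' @export
print.ed_design <- function(x, ...) {
  cat(sprintf("<ed_design: %d observations on (%g, %g], observed = %s>\n",
              length(x$times), x$t0, max(x$times),
              if (is.null(x$observed)) "all" else paste(x$observed, collapse = ",")))
  invisible(x)
}

# Resolve observed indices against a network.
#' @keywords internal
#' @noRd
design_observed <- function(design, network) {
  obs <- design$observed %||% seq_along(network$species)
  if (any(obs > length(network$species))) stop("observed index exceeds species count")
  obs
}

# Internal: a design whose `observed` is resolved (used by free_layout).
#' @keywords internal
#' @noRd
resolve_design <- function(design, network) {
  design$observed <- design_observed(design, network)
  design
}

#' Time series aligned to a design
#'
#' One row per measurement time of the design (the initial state at `t0`
#' belongs to the model, not the data). Latent series carry all D species;
#' observed series carry one column per observed component.
#'
#' @param values Numeric matrix, `length(design$times)` rows.
#' @param design An [ed_design()].
#' @param latent `TRUE` for full latent-state trajectories, `FALSE` for
#'   (possibly noisy, partial) observations.
#' @param seed Optional seed recorded for reproducibility.
#' @return A `timeseries` object.
#' @export
timeseries <- function(values, design, latent = FALSE, seed = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(design$times)) {
    stop("row count must equal the number of design times")
  }
  if (any(!is.finite(values))) stop("time-series values must be finite")
  structure(list(values = values, design = design, latent = latent, seed = seed),
            class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries: %d x %d (%s)%s>\n", nrow(x$values), ncol(x$values),
              if (x$latent) "latent" else "observed",
              if (is.null(x$seed)) "" else sprintf(", seed %s", x$seed)))
  invisible(x)
}
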