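# Plain-text I/O: time series, model configurations, Fisher matrices.

#' Read / write a time series
#'
#' Delimited text with a `time` column and one column per recorded
#' component; one row per measurement time. Values round-trip at full
#' precision. Reading enforces strictly increasing times.
#'
#' @param ts A [timeseries()].
#' @param path File path.
#' @param t0 Initial time used when reconstructing the design on read.
#' @param observed Observed indices for the reconstructed design.
#' @param latent Latent flag for the reconstructed series.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns a [timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(time = ts$design$times, ts$values, check.names = FALSE)
  if (is.null(colnames(ts$values))) {
    colnames(df)[-1] <- paste0("V", seq_len(ncol(ts$values)))
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, t0 = 0, observed = NULL, latent = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column")
  tms <- as.numeric(df$time)
  if (anyNA(tms)) stop("non-numeric entries in the time column")
  if (any(duplicated(tms))) stop("duplicate time rows")
  if (any(diff(tms) <= 0)) stop("times must be strictly increasing")
  vals <- as.matrix(df[setdiff(names(df), "time")])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("ragged or non-numeric rows in the time series")
  timeseries(vals, ed_design(tms, observed = observed, t0 = t0), latent = latent)
}

#' Read / write a model configuration
#'
#' YAML (or JSON) description of a reaction network with parameter values,
#' initial state and volume; the built-in models can be exported to this
#' format and re-imported losslessly.
#'
#' @param model A list with `network` and `param`, as returned by
#'   [builtin_model()].
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a list with `network` and `param`.
#' @export
write_model_config <- function(model, path) {
  net <- model$network
  spec <- list(
    name = net$name,
    species = as.list(net$species),
    parameters = stats::setNames(as.list(model$param$theta), net$params),
    volume = net$volume,
    initial_state = as.list(model$param$initial_state),
    reactions = lapply(seq_len(ncol(net$S)), function(j) {
      ed <- educt_counts(net, j)
      list(educts = as.list(ed$educts), products = as.list(ed$products),
           rate = deparse1(net$propensities[[j]]))
    })
  )
  if (grepl("[.]json$", path)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

# Net stoichiometry is stored; split into educts/products by sign for the
# config (sufficient for zeroth/first-order and the built-in models whose
# propensities are explicit expressions anyway).
#' @keywords internal
#' @noRd
educt_counts <- function(net, j) {
  s <- net$S[, j]
  list(educts = stats::setNames(as.list(pmax(-s, 0)[s < 0]), net$species[s < 0]),
       products = stats::setNames(as.list(pmax(s, 0)[s > 0]), net$species[s > 0]))
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  spec <- if (grepl("[.]json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  species <- unlist(spec$species)
  params <- names(spec$parameters)
  net <- reaction_network(
    species = species,
    reactions = lapply(spec$reactions, function(rx) {
      list(educts = unlist(rx$educts), products = unlist(rx$products),
           rate = rx$rate)
    }),
    params = params,
    volume = spec$volume %||% 1,
    name = spec$name
  )
  list(network = net,
       param = parameter_point(unlist(spec$parameters),
                               unlist(spec$initial_state)))
}

#' Serialize a Fisher matrix to JSON
#'
#' @param fi A [fisher_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fisher_json <- function(fi, path) {
  meta <- fi$meta
  meta$running <- NULL  # bulky trace, not part of the exchange format
  meta$entry_se <- if (!is.null(meta$entry_se)) unname(apply(meta$entry_se, 1, as.list))
  jsonlite::write_json(
    list(labels = fi$labels,
         matrix = unname(apply(fi$matrix, 1, as.list)),
         method = fi$method,
         meta = meta),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
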