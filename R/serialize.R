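# JSON serialization of fitted models (stable key order, lossless round trip).

#' Write a fitted model to JSON
#'
#' Both `maxent_model` and `envelope_model` objects are supported; the
#' document carries a `kind` tag so [read_model()] can dispatch.
#'
#' @param model a `maxent_model` or `envelope_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- if (inherits(model, "maxent_model")) {
    list(kind = "maxent",
         features = model$features, lambda = model$lambda, beta = model$beta,
         beta_multiplier = model$beta_multiplier, logZ = model$logZ,
         entropy = model$entropy, tau = model$tau,
         variables = model$variables, bg_means = as.list(model$bg_means),
         gain_trace = model$gain_trace, objective = model$objective,
         converged = model$converged, meta = model$meta)
  } else if (inherits(model, "envelope_model")) {
    out <- list(kind = "envelope", envelope_kind = model$kind,
                metric = model$metric, stats = model$stats,
                variables = model$variables)
    if (!is.null(model$cov)) out$cov <- as.data.frame(model$cov)
    if (!is.null(model$d_max)) out$d_max <- model$d_max
    out
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path JSON file path.
#' @return the reconstructed model object.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$kind, "maxent")) {
    structure(list(
      features = as.data.frame(doc$features), lambda = as.numeric(doc$lambda),
      beta = as.numeric(doc$beta), beta_multiplier = doc$beta_multiplier,
      logZ = doc$logZ, entropy = doc$entropy, tau = doc$tau,
      variables = doc$variables, bg_means = unlist(doc$bg_means),
      gain_trace = list(feature = as.integer(doc$gain_trace$feature),
                        gain = as.numeric(doc$gain_trace$gain)),
      objective = doc$objective, converged = doc$converged,
      meta = doc$meta), class = "maxent_model")
  } else if (identical(doc$kind, "envelope")) {
    model <- list(kind = doc$envelope_kind, metric = doc$metric,
                  stats = as.data.frame(doc$stats), variables = doc$variables)
    if (!is.null(doc$cov)) {
      model$cov <- as.matrix(doc$cov)
      dimnames(model$cov) <- list(model$variables, model$variables)
    }
    if (!is.null(doc$d_max)) model$d_max <- doc$d_max
    structure(model, class = "envelope_model")
  } else stop("format error: unknown model kind", call. = FALSE)
}
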