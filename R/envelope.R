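# Classic presence-only envelope algorithms used alongside the
# maximum-entropy model to build multi-algorithm consensus maps:
# Bioclim, Envelope Score, and Environmental Distance with four metrics.

#' Fit a presence-only envelope model
#'
#' Computes per-variable min/max, 5th/95th percentiles and mean over the
#' presences. For `env_distance`, also the covariance of the presences
#' (Mahalanobis; ridged with `ridge * I` when singular) and the normalizing
#' distance `d_max`, the maximum distance from the presence mean over the
#' training background rows.
#'
#' @param presence `sample_matrix` of presences (>= 2 rows; for Mahalanobis
#'   at least `p + 1` rows with `p` variables).
#' @param kind `"bioclim"`, `"envelope_score"` or `"env_distance"`.
#' @param metric distance metric for `env_distance`: `"euclidean"`,
#'   `"mahalanobis"`, `"manhattan_gower"` or `"chebyshev"`.
#' @param background training background `sample_matrix` (required for
#'   `env_distance`, to set `d_max`).
#' @param ridge ridge added to a singular presence covariance.
#' @return an object of class `envelope_model`.
#' @export
fit_envelope <- function(presence,
                         kind = c("bioclim", "envelope_score", "env_distance"),
                         metric = c("euclidean", "mahalanobis",
                                    "manhattan_gower", "chebyshev"),
                         background = NULL, ridge = 1e-6) {
  kind <- match.arg(kind); metric <- match.arg(metric)
  x <- presence$x
  if (nrow(x) < 2L) stop("input error: need >= 2 presence rows", call. = FALSE)
  stats_tab <- data.frame(
    variable = colnames(x),
    min = apply(x, 2, min), max = apply(x, 2, max),
    p5 = apply(x, 2, stats::quantile, probs = 0.05, names = FALSE),
    p95 = apply(x, 2, stats::quantile, probs = 0.95, names = FALSE),
    mean = colMeans(x), row.names = NULL
  )
  model <- list(kind = kind, metric = metric, stats = stats_tab,
                variables = colnames(x))
  if (kind == "env_distance") {
    if (is.null(background))
      stop("input error: env_distance needs the training background",
           call. = FALSE)
    if (metric == "mahalanobis") {
      if (nrow(x) < ncol(x) + 1L)
        stop("input error: mahalanobis needs >= p + 1 presences", call. = FALSE)
      S <- stats::cov(x)
      if (rcond(S) < 1e-10) S <- S + diag(ridge, ncol(x))
      model$cov <- S
    }
    d <- .env_dist(model, background$x)
    model$d_max <- max(d)
    if (model$d_max <= 0)
      stop("numeric error: degenerate d_max", call. = FALSE)
  }
  class(model) <- "envelope_model"
  model
}

# distance of rows to the presence mean under the model's metric
.env_dist <- function(model, x) {
  mu <- model$stats$mean
  dev <- sweep(x, 2, mu)
  switch(model$metric,
    euclidean = sqrt(rowSums(dev^2)),
    chebyshev = apply(abs(dev), 1, max),
    manhattan_gower = {
      rg <- pmax(model$stats$max - model$stats$min, 1e-12)
      rowSums(sweep(abs(dev), 2, rg, "/")) / ncol(x)
    },
    mahalanobis = sqrt(stats::mahalanobis(x, mu, model$cov))
  )
}

#' Predict suitability from an envelope model
#'
#' Bioclim scores 1 when every variable is inside the 5-95 percentile
#' envelope, 0.5 when every variable is inside min-max but some falls in the
#' tails, else 0. Envelope Score is the fraction of variables inside
#' min-max. Environmental Distance is `max(0, 1 - d / d_max)` with `d` the
#' chosen metric's distance to the presence mean.
#'
#' @param object an `envelope_model`.
#' @param x covariate matrix (named columns) or a `sample_matrix`.
#' @param ... unused.
#' @return numeric vector in \[0, 1\].
#' @export
predict.envelope_model <- function(object, x, ...) {
  if (inherits(x, "sample_matrix")) x <- x$x
  if (!identical(colnames(x), object$variables))
    stop("input error: variable mismatch", call. = FALSE)
  st <- object$stats
  switch(object$kind,
    bioclim = {
      in_core <- rep(TRUE, nrow(x)); in_full <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x))) {
        in_core <- in_core & x[, j] >= st$p5[j] & x[, j] <= st$p95[j]
        in_full <- in_full & x[, j] >= st$min[j] & x[, j] <= st$max[j]
      }
      ifelse(in_core, 1, ifelse(in_full, 0.5, 0))
    },
    envelope_score = {
      inside <- matrix(FALSE, nrow(x), ncol(x))
      for (j in seq_len(ncol(x)))
        inside[, j] <- x[, j] >= st$min[j] & x[, j] <= st$max[j]
      rowMeans(inside)
    },
    env_distance = pmax(0, 1 - .env_dist(object, x) / object$d_max)
  )
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf("<envelope_model> %s%s on %s\n", x$kind,
              if (x$kind == "env_distance") paste0(" (", x$metric, ")") else "",
              paste(x$variables, collapse = ", ")))
  invisible(x)
}
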