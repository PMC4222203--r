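# Model evaluation: AUC-ROC, cross-validation, jackknife variable
# importance, response curves, and the bundled evaluation report.

#' Rank-based AUC-ROC for presence vs background scores
#'
#' The Mann-Whitney estimator: the probability that a random presence
#' outscores a random background point, with ties counted one half
#' (`U / (n_p * n_b)` computed from midranks).
#'
#' @param presence_scores,background_scores numeric vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1L || nb < 1L) stop("input error: empty score vector", call. = FALSE)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Cross-validated AUC of a maximum-entropy model
#'
#' Presences are split into `k` folds by a seeded permutation; each fold is
#' held out in turn, the model is refitted on the remaining presences
#' against the shared background, and the held-out presences are scored
#' against the background (the background is not split, the convention of
#' the tool this re-implements).
#'
#' @param presence,background `sample_matrix` objects.
#' @param k number of folds (>= 2, <= number of presences).
#' @param seed integer seed for the fold permutation.
#' @param ... passed to [maxent_fit()] (e.g. `beta_multiplier`,
#'   `knots_per_variable`).
#' @return list with `auc` (per fold), `mean`, `sd`, `folds` (assignments).
#' @export
cross_validate <- function(presence, background, k = 5, seed = 1, ...) {
  m <- nrow(presence$x)
  if (k < 2) stop("input error: k must be >= 2", call. = FALSE)
  if (k > m) stop("input error: k exceeds the number of presences", call. = FALSE)
  rng <- .local_rng(seed)
  perm <- rng$sample_int(m, m, replace = FALSE, prob = NULL)
  fold <- integer(m)
  fold[perm] <- rep_len(seq_len(k), m)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    ptrain <- .new_sample_matrix(presence$x[tr, , drop = FALSE], "presence",
                                 presence$cell_ids[tr], presence$months[tr])
    model <- maxent_fit(ptrain, background, ...)
    test_scores <- predict(model, presence$x[!tr, , drop = FALSE])
    bg_scores <- predict(model, background$x)
    aucs[f] <- auc(test_scores, bg_scores)
  }
  list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs), folds = fold)
}

# unpenalized training gain of a fitted model: mean presence log-probability
# improvement over the uniform model, mean(eta) - logZ + log(N)
.maxent_gain <- function(model, presence) {
  eta_p <- .maxent_eta(model, presence$x)
  mean(eta_p) - model$logZ + log(model$meta$n_norm %||% model$meta$n_background)
}

#' Jackknife variable-importance gains
#'
#' Refits the model with each covariate alone and with each omitted and
#' reports the unpenalized training gain of each refit plus the full model
#' (the classic jackknife bar chart's numbers).
#'
#' @param presence,background `sample_matrix` objects (>= 2 variables).
#' @param ... passed to [maxent_fit()].
#' @return data.frame with columns `variable, gain_only, gain_without`, plus
#'   attribute `gain_full`.
#' @export
jackknife_variables <- function(presence, background, ...) {
  vars <- colnames(presence$x)
  if (length(vars) < 2L) stop("input error: need >= 2 variables", call. = FALSE)
  sub <- function(sm, keep) .new_sample_matrix(
    sm$x[, keep, drop = FALSE], sm$role, sm$cell_ids, sm$months)
  full <- maxent_fit(presence, background, ...)
  gain_full <- .maxent_gain(full, presence)
  res <- lapply(vars, function(v) {
    only <- maxent_fit(sub(presence, v), sub(background, v), ...)
    without <- maxent_fit(sub(presence, setdiff(vars, v)),
                          sub(background, setdiff(vars, v)), ...)
    c(gain_only = .maxent_gain(only, sub(presence, v)),
      gain_without = .maxent_gain(without, sub(presence, setdiff(vars, v))))
  })
  out <- data.frame(variable = vars, do.call(rbind, res), row.names = NULL)
  attr(out, "gain_full") <- gain_full
  out
}

#' Marginal response curve of one covariate
#'
#' Varies the covariate over its training range at `n_points` while holding
#' all other covariates at their background means, and returns the logistic
#' outputs.
#'
#' @param model a fitted `maxent_model`.
#' @param variable covariate name.
#' @param n_points number of evaluation points.
#' @param from,to optional sub-range (defaults to the training range).
#' @return data.frame with columns `value`, `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           from = NULL, to = NULL) {
  if (!variable %in% model$variables)
    stop("input error: unknown variable '", variable, "'", call. = FALSE)
  ft <- model$features[model$features$variable == variable, , drop = FALSE]
  lo <- if (nrow(ft)) ft$lo[1] else model$bg_means[variable]
  hi <- if (nrow(ft)) ft$hi[1] else model$bg_means[variable]
  v <- seq(from %||% lo, to %||% hi, length.out = n_points)
  x <- matrix(rep(model$bg_means, each = n_points), n_points,
              length(model$variables),
              dimnames = list(NULL, model$variables))
  x[, variable] <- v
  data.frame(value = v, suitability = predict(model, x, type = "logistic"))
}

#' Full evaluation report for a maximum-entropy model
#'
#' Bundles training AUC, cross-validated AUC, percent contributions,
#' jackknife gains and response curves into one list, convenient for JSON
#' export.
#'
#' @param model fitted `maxent_model`.
#' @param presence,background `sample_matrix` objects used for training.
#' @param k cross-validation folds (0 skips CV).
#' @param seed seed for the CV fold permutation.
#' @param jackknife run the jackknife refits?
#' @param n_points points per response curve.
#' @param ... passed to refits ([maxent_fit()]).
#' @return list of class `evaluation_report`.
#' @export
evaluate_model <- function(model, presence, background, k = 5, seed = 1,
                           jackknife = TRUE, n_points = 50, ...) {
  train_auc <- auc(predict(model, presence$x), predict(model, background$x))
  cv <- if (k >= 2) cross_validate(presence, background, k = k, seed = seed, ...)
        else NULL
  contrib <- variable_contributions(model)
  jk <- if (jackknife && length(model$variables) >= 2L)
    jackknife_variables(presence, background, ...) else NULL
  curves <- lapply(stats::setNames(model$variables, model$variables),
                   function(v) response_curve(model, v, n_points))
  structure(list(
    auc = train_auc,
    cv_auc_mean = if (is.null(cv)) NA_real_ else cv$mean,
    cv_auc_sd = if (is.null(cv)) NA_real_ else cv$sd,
    contributions = contrib,
    jackknife = jk,
    response_curves = curves
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC %.3f (cv %.3f +- %.3f)\n",
              x$auc, x$cv_auc_mean, x$cv_auc_sd))
  cat("contributions (%):\n")
  print(round(x$contributions, 1))
  invisible(x)
}
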