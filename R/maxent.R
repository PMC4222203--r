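# Presence-only maximum-entropy model with hinge features and L1
# (lasso-type) regularization, fitted by cyclic coordinate descent with
# soft-thresholding. The raw model is the Gibbs distribution
# p(x) = exp(eta(x)) / Z with eta = sum_j lambda_j f_j(x), normalized over
# the background rows PLUS the presence rows (the original tool's default
# "add samples to background"; this bounds the objective, which over the
# background alone can be driven to -Inf by hinge combinations that
# strictly separate the presences). Fitting minimizes
#   J(lambda) = -mean_presence eta + log sum_{background+presence} exp(eta)
#               + sum_j beta_j |lambda_j|
# where beta_j = beta_multiplier * 0.5 * sd_presence(f_j) / sqrt(m)
# (the hinge-class default of the tool this re-implements), floored at
# 0.001 * feature range.

#' Build hinge features from training data
#'
#' For every covariate, knots are placed at evenly spaced quantiles of the
#' combined presence + background values and both a forward hinge
#' `max(0, (v - knot) / (hi - knot))` and a reverse hinge
#' `max(0, (knot - v) / (knot - lo))` are emitted per knot (degenerate
#' zero-width hinges are skipped). `lo`/`hi` are the combined training
#' min/max, so every feature lies in \[0, 1\] on the training data.
#' Constant covariates contribute no features (with a warning).
#'
#' @param presence,background `sample_matrix` objects sharing variables.
#' @param knots_per_variable number of knots per covariate (default 30).
#' @return data.frame with columns `variable, knot, direction, lo, hi`.
#' @export
build_features <- function(presence, background, knots_per_variable = 30) {
  stopifnot(knots_per_variable >= 1)
  if (!identical(colnames(presence$x), colnames(background$x)))
    stop("input error: presence and background variables differ", call. = FALSE)
  out <- list()
  for (v in colnames(presence$x)) {
    vals <- c(presence$x[, v], background$x[, v])
    lo <- min(vals); hi <- max(vals)
    if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
      warning("build_features: variable '", v, "' is constant; skipped")
      next
    }
    knots <- unique(stats::quantile(vals, probs = seq(0, 1, length.out = knots_per_variable),
                                    names = FALSE, type = 7))
    for (k in knots) {
      if (hi - k > 1e-12 * (hi - lo))
        out[[length(out) + 1L]] <- data.frame(variable = v, knot = k,
                                              direction = "forward", lo = lo, hi = hi)
      if (k - lo > 1e-12 * (hi - lo))
        out[[length(out) + 1L]] <- data.frame(variable = v, knot = k,
                                              direction = "reverse", lo = lo, hi = hi)
    }
  }
  if (!length(out)) return(data.frame(variable = character(), knot = numeric(),
                                      direction = character(), lo = numeric(),
                                      hi = numeric()))
  do.call(rbind, out)
}

#' Evaluate hinge features on a covariate matrix
#'
#' @param features data.frame from [build_features()].
#' @param x numeric matrix with named columns covering the feature variables.
#' @param clamp clamp covariates to each feature's training `[lo, hi]`
#'   (MaxEnt's default behaviour when projecting beyond the training range).
#' @return matrix, one column per feature, values in \[0, 1\] when clamped.
#' @export
feature_matrix <- function(features, x, clamp = TRUE) {
  n <- nrow(x)
  f <- matrix(0, n, nrow(features))
  for (j in seq_len(nrow(features))) {
    ft <- features[j, ]
    v <- x[, ft$variable]
    if (clamp) v <- pmin(pmax(v, ft$lo), ft$hi)
    f[, j] <- if (ft$direction == "forward")
      pmax(0, (v - ft$knot) / (ft$hi - ft$knot))
    else
      pmax(0, (ft$knot - v) / (ft$knot - ft$lo))
  }
  f
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy presence-only model
#'
#' Deterministic cyclic coordinate descent on the L1-penalized negative
#' log-likelihood (see the header of this file), with an exact per-coordinate
#' soft-threshold Newton step safeguarded by step halving so the regularized
#' gain never decreases. Iteration stops when the per-sweep gain change
#' falls below `tol` and every feature satisfies the KKT box condition
#' `|mean_presence f_j - E_p f_j| <= beta_j + kkt_tol`, or at `max_iter`
#' sweeps (then the model carries `converged = FALSE` and a warning is
#' raised).
#'
#' @param presence,background `sample_matrix` objects sharing variables.
#' @param beta_multiplier global scaling of the per-feature L1 penalties
#'   (default 1).
#' @param knots_per_variable hinge knots per covariate (default 30).
#' @param tol stopping tolerance on the per-sweep regularized gain change.
#' @param max_iter maximum number of coordinate-descent sweeps.
#' @param features optional prebuilt feature table (overrides
#'   [build_features()]); used mainly for controlled experiments.
#' @param kkt_tol stopping tolerance on the KKT box violation.
#' @return an object of class `maxent_model` with elements `features`,
#'   `lambda`, `beta`, `logZ` (over the training normalization set:
#'   background plus presences), `entropy`
#'   (nats), `tau` (logistic-link prevalence, 0.5), `gain_trace`
#'   (per-update feature index and regularized-gain increment),
#'   `objective`, `converged`, and training metadata.
#' @export
maxent_fit <- function(presence, background, beta_multiplier = 1,
                       knots_per_variable = 30, tol = 1e-5, max_iter = 500,
                       features = NULL, kkt_tol = 1e-4) {
  if (nrow(presence$x) < 1L) stop("input error: need >= 1 presence row", call. = FALSE)
  if (nrow(background$x) < 2L) stop("input error: need >= 2 background rows", call. = FALSE)
  if (!all(is.finite(presence$x)) || !all(is.finite(background$x)))
    stop("input error: non-finite covariates", call. = FALSE)
  if (is.null(features))
    features <- build_features(presence, background, knots_per_variable)
  m <- nrow(presence$x); N <- nrow(background$x)
  Fp <- feature_matrix(features, presence$x, clamp = FALSE)
  Fb <- feature_matrix(features, background$x, clamp = FALSE)
  # normalization set: background plus presence rows
  Fz <- rbind(Fb, Fp)
  # a feature constant over the normalization set cannot shape the model
  # distribution (its eta shift is absorbed by Z); drop it
  informative <- apply(Fz, 2, function(z) diff(range(z)) > 0)
  n_dropped <- sum(!informative)
  features <- features[informative, , drop = FALSE]
  rownames(features) <- NULL
  Fp <- Fp[, informative, drop = FALSE]
  Fz <- Fz[, informative, drop = FALSE]
  k <- nrow(features)
  Nz <- nrow(Fz)
  mean_p <- if (k) colMeans(Fp) else numeric(0)

  # per-feature penalties: hinge default 0.5 * sd/sqrt(m), floored
  sd_p <- if (m > 1L) apply(Fp, 2, stats::sd) else rep(0, k)
  rng_f <- apply(Fz, 2, function(z) diff(range(z)))
  beta <- beta_multiplier * 0.5 * pmax(sd_p, 0.001 * pmax(rng_f, 1e-6)) / sqrt(m)

  # Cycle order: features sorted once by their gain potential at lambda = 0
  # (|gradient| net of penalty, descending; ties by feature index). Under
  # collinear covariates this assigns shared gain to the genuinely stronger
  # feature first, as the greedy selection of the original tool does, while
  # keeping the sweeps deterministic.
  if (k > 0L) {
    g0 <- abs(colMeans(Fz) - mean_p) - beta
    ord <- order(-g0)
    features <- features[ord, , drop = FALSE]
    rownames(features) <- NULL
    Fp <- Fp[, ord, drop = FALSE]; Fz <- Fz[, ord, drop = FALSE]
    mean_p <- mean_p[ord]; beta <- beta[ord]
    sd_p <- sd_p[ord]; rng_f <- rng_f[ord]
  }

  lambda <- rep(0, k)
  eta_b <- rep(0, Nz)
  mean_eta_p <- 0
  logZ <- log(Nz)
  trace_feat <- integer(0); trace_gain <- numeric(0)
  converged <- (k == 0L)
  iter <- 0L

  objective <- function() -mean_eta_p + logZ + sum(beta * abs(lambda))

  if (k > 0L) for (iter in seq_len(max_iter)) {
    sweep_gain <- 0
    logZ <- .logsumexp(eta_b)           # refresh against drift
    w <- exp(eta_b - logZ)
    for (j in seq_len(k)) {
      fb <- Fz[, j]
      Ef <- sum(w * fb)
      g <- Ef - mean_p[j]
      h <- max(sum(w * fb * fb) - Ef * Ef, 1e-12)
      lam_new <- .soft(h * lambda[j] - g, beta[j]) / h
      d <- lam_new - lambda[j]
      if (!is.finite(d) || abs(d) < 1e-14) next
      # exact objective change for step d, halved until it actually
      # decreases the objective (handles overshooting Newton steps from
      # near-degenerate curvature, including non-finite trial objectives)
      best <- NULL
      cand_d <- d
      for (try in 1:60) {
        lam_c <- lambda[j] + cand_d
        dlogZ <- log(sum(w * exp(cand_d * fb)))
        dJ <- -mean_p[j] * cand_d + dlogZ +
          beta[j] * (abs(lam_c) - abs(lambda[j]))
        if (is.finite(dJ) && dJ < 0) { best <- list(d = cand_d, dlogZ = dlogZ, dJ = dJ); break }
        cand_d <- cand_d / 2
        if (abs(cand_d) < 1e-14) break
      }
      if (is.null(best)) next
      lambda[j] <- lambda[j] + best$d
      mean_eta_p <- mean_eta_p + best$d * mean_p[j]
      eta_b <- eta_b + best$d * fb
      logZ <- logZ + best$dlogZ
      w <- exp(eta_b - logZ)
      gain <- -best$dJ
      sweep_gain <- sweep_gain + gain
      trace_feat <- c(trace_feat, j); trace_gain <- c(trace_gain, gain)
    }
    logZ <- .logsumexp(eta_b)
    w <- exp(eta_b - logZ)
    kkt <- abs(mean_p - as.numeric(crossprod(Fz, w)))
    if (sweep_gain < tol && max(kkt - beta) <= kkt_tol) { converged <- TRUE; break }
  }
  if (!converged) warning("maxent_fit: not converged after ", max_iter, " sweeps")

  logZ <- .logsumexp(eta_b)
  w <- exp(eta_b - logZ)
  H <- -sum(w[w > 0] * log(w[w > 0]))
  structure(list(
    features = features, lambda = lambda, beta = beta,
    beta_multiplier = beta_multiplier, logZ = logZ, entropy = H, tau = 0.5,
    variables = colnames(presence$x),
    bg_means = colMeans(background$x),
    gain_trace = list(feature = trace_feat, gain = trace_gain),
    objective = objective(), converged = converged,
    meta = list(n_presence = m, n_background = N, n_norm = Nz,
                iterations = iter, n_features_dropped = n_dropped)
  ), class = "maxent_model")
}

.soft <- function(z, b) sign(z) * pmax(abs(z) - b, 0)

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> %d features (%d active), %d presences vs ",
                     "%d background, logZ=%.4f, H=%.4f%s\n"),
              length(x$lambda), sum(x$lambda != 0), x$meta$n_presence,
              x$meta$n_background, x$logZ, x$entropy,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# linear predictor eta(x) for a covariate matrix (clamped to training range)
.maxent_eta <- function(model, x) {
  if (!nrow(model$features)) return(rep(0, nrow(x)))
  f <- feature_matrix(model$features, x, clamp = TRUE)
  as.numeric(f %*% model$lambda)
}

#' Predict from a fitted maximum-entropy model
#'
#' `type = "raw"` returns the Gibbs probabilities over the supplied rows
#' (normalized to sum to 1 over those rows). `type = "logistic"` returns the
#' standard logistic output `c*q / (1 + c*q)` with `q = exp(eta - logZ)`
#' (logZ from the training background) and `c = exp(H)`, the tau = 0.5
#' convention: a cell of typical training suitability scores 0.5.
#' Covariates are clamped to each feature's training range.
#'
#' @param object a `maxent_model`.
#' @param x covariate matrix (named columns) or a `sample_matrix`.
#' @param type `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, x, type = c("logistic", "raw"), ...) {
  type <- match.arg(type)
  if (inherits(x, "sample_matrix")) x <- x$x
  eta <- .maxent_eta(object, x)
  if (type == "raw") {
    e <- exp(eta - max(eta))
    e / sum(e)
  } else {
    q <- exp(eta - object$logZ)
    cq <- exp(object$entropy) * q
    cq / (1 + cq)
  }
}

#' Percent contribution of each covariate
#'
#' The positive regularized-gain increments collected during fitting are
#' summed per covariate and normalized to 100. Covariates whose features
#' were never usefully updated get 0.
#'
#' @param model a fitted `maxent_model`.
#' @return named numeric vector of percentages summing to 100 (all zero,
#'   with a warning, when no gain was recorded).
#' @export
variable_contributions <- function(model) {
  vars <- model$variables
  out <- stats::setNames(rep(0, length(vars)), vars)
  tr <- model$gain_trace
  if (!length(tr$feature)) {
    warning("variable_contributions: empty gain trace")
    return(out)
  }
  fv <- model$features$variable[tr$feature]
  pos <- tr$gain > 0
  agg <- tapply(tr$gain[pos], fv[pos], sum)
  out[names(agg)] <- agg
  if (sum(out) > 0) out <- 100 * out / sum(out)
  out
}
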