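# Projection of fitted models onto environmental stacks, thresholded /
# consensus / ensemble maps, and range-boundary profiles.

#' Project a fitted model onto an environmental stack
#'
#' Evaluates the model's suitability (MaxEnt logistic output or envelope
#' score) on every ocean cell; land stays masked.
#'
#' @param model a `maxent_model` or `envelope_model`.
#' @param stack an `env_stack` carrying all model variables.
#' @return a `suitability_map`: list with `grid` (an [env_grid()] of
#'   suitability), `model_id`, `time_tag`, `scenario_tag`, `gcm_tag`.
#' @export
project <- function(model, stack) {
  sm <- stack_matrix(stack, model$variables)
  score <- predict(model, sm$x)
  ref <- stack$grids[[1]]
  v <- matrix(NA_real_, length(ref$lat), length(ref$lon))
  v[sm$idx] <- score
  structure(list(
    grid = env_grid("suitability", "dimensionless", ref$lat, ref$lon, v, ref$mask),
    model_id = class(model)[1], time_tag = stack$time_tag,
    scenario_tag = stack$scenario_tag, gcm_tag = stack$gcm_tag
  ), class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s [%s | %s%s]\n", x$model_id,
              as.character(x$time_tag), x$scenario_tag,
              if (is.null(x$gcm_tag)) "" else paste0(" | ", x$gcm_tag)))
  invisible(x)
}

.map_grid <- function(x) {
  if (inherits(x, "suitability_map")) x$grid else x
}

#' Threshold a suitability map into a binary range map
#'
#' A cell is presence iff suitability `>= t` (cells exactly at the cutoff
#' count as presence); masked cells stay masked.
#'
#' @param map a `suitability_map` or suitability [env_grid()].
#' @param t threshold in (0, 1).
#' @return an [env_grid()] with variable `"count"` holding 0/1.
#' @export
threshold_map <- function(map, t) {
  stopifnot(t > 0, t < 1)
  g <- .map_grid(map)
  v <- ifelse(g$mask, as.numeric(g$values >= t), NA_real_)
  env_grid("count", "dimensionless", g$lat, g$lon, v, g$mask)
}

#' Multi-algorithm consensus map
#'
#' Per cell, the number of models whose suitability reaches the common
#' threshold (default 0.2, the value used for the 16-model comparison this
#' package mirrors).
#'
#' @param maps list of `suitability_map`s or suitability grids on one
#'   geometry.
#' @param t threshold.
#' @return list of class `consensus_map`: `grid` (integer counts),
#'   `threshold`, `n_models`.
#' @export
consensus <- function(maps, t = 0.2) {
  stopifnot(length(maps) >= 1L)
  grids <- lapply(maps, .map_grid)
  ref <- grids[[1]]
  for (g in grids) if (!same_geometry(ref, g))
    stop("alignment error: consensus maps on different geometries", call. = FALSE)
  counts <- matrix(0, length(ref$lat), length(ref$lon))
  mask <- Reduce(`&`, lapply(grids, function(g) g$mask))
  for (g in grids) counts <- counts + (!is.na(g$values) & g$values >= t)
  counts[!mask] <- NA_real_
  structure(list(
    grid = env_grid("count", "dimensionless", ref$lat, ref$lon, counts, mask),
    threshold = t, n_models = length(maps)
  ), class = "consensus_map")
}

#' Ensemble projection across climate-model members
#'
#' Projects one fitted model on each member stack (same month and scenario,
#' different GCMs) and returns the per-cell mean and population standard
#' deviation of the member suitabilities.
#'
#' @param model fitted model.
#' @param stacks list of `env_stack`s sharing geometry, month and scenario.
#' @return list of class `ensemble_map`: `mean` and `sd` ([env_grid()]s),
#'   `members` (GCM tags), `scenario`, `month`.
#' @export
ensemble <- function(model, stacks) {
  stopifnot(length(stacks) >= 1L)
  tt <- unique(vapply(stacks, function(s) as.character(s$time_tag), character(1)))
  sc <- unique(vapply(stacks, function(s) s$scenario_tag, character(1)))
  if (length(tt) != 1L || length(sc) != 1L)
    stop("input error: ensemble members must share month and scenario",
         call. = FALSE)
  maps <- lapply(stacks, function(s) project(model, s)$grid)
  ref <- maps[[1]]
  n <- length(maps)
  vals <- lapply(maps, function(g) g$values)
  # mean and population SD computed on deviations from the first member, so
  # identical members give sd exactly 0 (and good accuracy generally)
  devs <- lapply(vals, function(v) v - vals[[1]])
  mdev <- Reduce(`+`, devs) / n
  mu <- vals[[1]] + mdev
  sdv <- sqrt(Reduce(`+`, lapply(devs, function(d) (d - mdev)^2)) / n)
  structure(list(
    mean = env_grid("suitability", "dimensionless", ref$lat, ref$lon, mu, ref$mask),
    sd = env_grid("suitability", "dimensionless", ref$lat, ref$lon, sdv, ref$mask),
    members = vapply(stacks, function(s) s$gcm_tag %||% "unknown", character(1)),
    scenario = sc, month = tt
  ), class = "ensemble_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Range-boundary latitude profile
#'
#' For each longitude column, returns the most equatorward latitude of the
#' contiguous above-threshold run that touches the polar side of the column
#' (masked cells inside the run are skipped, so coastlines do not split a
#' range; a detached equatorward patch is not counted as "the" boundary).
#' `NA` where a column has no above-threshold cell.
#'
#' @param map a `suitability_map`, suitability grid, or 0/1 grid from
#'   [threshold_map()].
#' @param t threshold (ignored if the input is already binary 0/1).
#' @param pole `"south"` (default) or `"north"`: the side the range touches.
#' @param contiguous if `FALSE`, simply return the most equatorward
#'   above-threshold cell per column.
#' @return data.frame with columns `lon`, `lat`.
#' @export
boundary_latitude <- function(map, t = 0.2, pole = c("south", "north"),
                              contiguous = TRUE) {
  pole <- match.arg(pole)
  g <- .map_grid(map)
  above <- !is.na(g$values) & g$values >= t
  nlat <- length(g$lat)
  lat_out <- rep(NA_real_, length(g$lon))
  for (j in seq_along(g$lon)) {
    col_above <- above[, j]
    col_ocean <- g$mask[, j]
    ord <- if (pole == "south") seq_len(nlat) else rev(seq_len(nlat))
    hits <- which(col_above[ord])
    if (!length(hits)) next
    if (!contiguous) {
      lat_out[j] <- g$lat[ord[hits[length(hits)]]]
      next
    }
    # walk equatorward from the polar-most hit; land does not break the run
    pos <- hits[1]
    while (pos < nlat) {
      nxt <- pos + 1L
      if (!col_ocean[ord[nxt]] || col_above[ord[nxt]]) pos <- nxt else break
    }
    # report the last ABOVE cell of the run (trailing land is not range)
    run <- ord[hits[1]:pos]
    run <- run[col_above[run]]
    lat_out[j] <- g$lat[run[length(run)]]
  }
  data.frame(lon = g$lon, lat = lat_out)
}
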