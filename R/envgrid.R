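# Raster data model: regular lat/lon grids of surface-ocean variables.
# Conventions: coordinates are cell centers; latitudes ascending; longitudes
# ascending in [-180, 180); values are NA exactly where the mask says land.

.CANON_UNITS <- c(
  sst = "degC", salinity = "PSU", nitrate = "umol_per_L",
  silicate = "umol_per_L", bias = "dimensionless",
  suitability = "dimensionless", count = "dimensionless"
)
.KNOWN_VARS <- names(.CANON_UNITS)

#' Construct an environmental grid
#'
#' An `env_grid` is the package's raster primitive: one variable on a regular
#' latitude/longitude grid of cell centers, with an ocean/land mask. Values
#' are stored as an `nlat x nlon` matrix (rows = ascending latitude) and are
#' `NA` exactly on masked (land) cells.
#'
#' @param variable one of `"sst"`, `"salinity"`, `"nitrate"`, `"silicate"`,
#'   `"bias"`, `"suitability"`, `"count"`.
#' @param units unit string; canonical units are `degC`, `PSU`, `umol_per_L`
#'   and `dimensionless` (see [harmonize_units()] for conversions).
#' @param lat,lon numeric vectors of cell-center coordinates, ascending and
#'   uniformly spaced; `lon` in `[-180, 180)`.
#' @param values numeric matrix `length(lat) x length(lon)`.
#' @param mask logical matrix, `TRUE` for ocean. Defaults to `!is.na(values)`.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(variable, units, lat, lon, values, mask = NULL) {
  if (!variable %in% .KNOWN_VARS)
    stop("unknown variable '", variable, "'", call. = FALSE)
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  .check_axis(lat, "lat")
  .check_axis(lon, "lon")
  if (any(lon < -180 | lon >= 180))
    stop("lon centers must lie in [-180, 180)", call. = FALSE)
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(lat), length(lon))))
    stop("values must be a length(lat) x length(lon) matrix", call. = FALSE)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  values[!mask] <- NA_real_
  if (anyNA(values[mask]))
    stop("values must be present on every ocean (unmasked) cell", call. = FALSE)
  structure(
    list(variable = variable, units = units, lat = lat, lon = lon,
         values = values, mask = mask),
    class = "env_grid"
  )
}

.check_axis <- function(x, name) {
  if (length(x) < 1L) stop(name, " axis is empty", call. = FALSE)
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0)) stop(name, " centers must be ascending", call. = FALSE)
    if (max(abs(d - d[1])) > 1e-8 * max(abs(d[1]), 1))
      stop(name, " spacing is not uniform", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %s [%s]  %d x %d cells, step %.4g deg, %d ocean\n",
              x$variable, x$units, length(x$lat), length(x$lon),
              grid_step(x), sum(x$mask)))
  invisible(x)
}

#' Grid spacing in degrees
#' @param grid an `env_grid`.
#' @return scalar cell size (the grids used here are square-celled).
#' @export
grid_step <- function(grid) {
  if (length(grid$lat) > 1L) diff(grid$lat[1:2]) else diff(grid$lon[1:2])
}

#' Test whether two grids share geometry (axes and step, not mask)
#' @param a,b `env_grid` objects.
#' @export
same_geometry <- function(a, b) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) < 1e-8 && max(abs(a$lon - b$lon)) < 1e-8
}

#' Locate the grid cell containing a point
#'
#' A point belongs to the cell whose center is nearest, with the half-open
#' tie-break toward +lon/+lat (a point exactly on a cell edge belongs to the
#' cell on the increasing side).
#'
#' @param grid an `env_grid` (only its geometry is used).
#' @param lon,lat point coordinates (vectors of equal length).
#' @return integer matrix with columns `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
cell_of <- function(grid, lon, lat) {
  step <- grid_step(grid)
  row <- floor((lat - grid$lat[1]) / step + 0.5) + 1L
  col <- floor((lon - grid$lon[1]) / step + 0.5) + 1L
  row[row < 1L | row > length(grid$lat)] <- NA_integer_
  col[col < 1L | col > length(grid$lon)] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Bundle aligned grids into an environmental stack
#'
#' @param grids list of `env_grid` objects (one per variable).
#' @param time_tag `"annual"` or an integer month 1..12.
#' @param scenario_tag `"present"` or a scenario name (e.g. `"rcp85"`).
#' @param gcm_tag climate-model tag or `NULL`.
#' @return an `env_stack`: named list of grids plus tags.
#' @seealso [align_stack()] which verifies geometry and intersects masks.
#' @export
env_stack <- function(grids, time_tag = "annual", scenario_tag = "present",
                      gcm_tag = NULL) {
  vars <- vapply(grids, function(g) g$variable, character(1))
  if (anyDuplicated(vars)) stop("duplicate variables in stack", call. = FALSE)
  names(grids) <- vars
  structure(
    list(grids = grids, time_tag = time_tag, scenario_tag = scenario_tag,
         gcm_tag = gcm_tag),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> [%s | %s%s] vars: %s\n",
              as.character(x$time_tag), x$scenario_tag,
              if (is.null(x$gcm_tag)) "" else paste0(" | ", x$gcm_tag),
              paste(names(x$grids), collapse = ", ")))
  invisible(x)
}

#' Align grids into a stack, verifying geometry and intersecting masks
#'
#' A cell is ocean in the stack only if it is ocean in every member grid;
#' values on newly masked cells become `NA` in all members.
#'
#' @inheritParams env_stack
#' @return an `env_stack`.
#' @export
align_stack <- function(grids, time_tag = "annual", scenario_tag = "present",
                        gcm_tag = NULL) {
  if (length(grids) < 1L) stop("need at least one grid", call. = FALSE)
  ref <- grids[[1]]
  for (g in grids) {
    if (!same_geometry(ref, g))
      stop("alignment error: grid geometry mismatch for variable '",
           g$variable, "'", call. = FALSE)
  }
  mask <- Reduce(`&`, lapply(grids, function(g) g$mask))
  grids <- lapply(grids, function(g) {
    g$mask <- mask
    g$values[!mask] <- NA_real_
    g
  })
  env_stack(grids, time_tag, scenario_tag, gcm_tag)
}

# Covariate matrix over all ocean cells of a stack, one row per ocean cell.
# Returns list(x = matrix, idx = linear cell indices into values matrices).
stack_matrix <- function(stack, variables = names(stack$grids)) {
  miss <- setdiff(variables, names(stack$grids))
  if (length(miss))
    stop("input error: stack is missing variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  mask <- stack$grids[[1]]$mask
  idx <- which(mask)
  x <- vapply(variables, function(v) stack$grids[[v]]$values[idx],
              numeric(length(idx)))
  if (length(idx) == 1L) x <- matrix(x, nrow = 1L, dimnames = list(NULL, variables))
  list(x = x, idx = idx, mask = mask)
}
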