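# ESRI ASCII grid I/O, unit harmonization and regridding.

.ASCII_NODATA <- -9999

#' Write a grid to disk
#'
#' Writes the ESRI ASCII grid format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header, rows north to south). Values are written
#' with 9 significant digits so a read/write round trip is lossless well
#' below 1e-6.
#'
#' @param grid an [env_grid()].
#' @param path output file path.
#' @param format `"ascii"`. `"netcdf"` is recognized but unsupported in this
#'   build (no NetCDF library available) and raises a format error.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("ascii", "netcdf")) {
  format <- match.arg(format)
  if (format == "netcdf")
    stop("format error: NetCDF output requires a NetCDF library ",
         "(not available in this build); use format = 'ascii'", call. = FALSE)
  step <- grid_step(grid)
  v <- grid$values
  v[!grid$mask] <- .ASCII_NODATA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", length(grid$lon)),
    paste("nrows", length(grid$lat)),
    paste("xllcorner", formatC(grid$lon[1] - step / 2, format = "g", digits = 12)),
    paste("yllcorner", formatC(grid$lat[1] - step / 2, format = "g", digits = 12)),
    paste("cellsize", formatC(step, format = "g", digits = 12)),
    paste("NODATA_value", .ASCII_NODATA)
  ), con)
  # rows north -> south
  for (i in rev(seq_along(grid$lat)))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 9), collapse = " "), con)
  invisible(path)
}

#' Read a grid from disk
#'
#' Cells equal to the file's `NODATA_value` become masked. Longitude centers
#' are normalized to `[-180, 180)` (columns are reordered when the file uses
#' a `[0, 360)` domain).
#'
#' @param path input file.
#' @param variable,units metadata to attach (the ASCII format stores neither).
#' @param format `"ascii"` (see [write_grid()] about `"netcdf"`).
#' @return an [env_grid()].
#' @export
read_grid <- function(path, variable, units, format = c("ascii", "netcdf")) {
  format <- match.arg(format)
  if (format == "netcdf")
    stop("format error: NetCDF input requires a NetCDF library ",
         "(not available in this build); use format = 'ascii'", call. = FALSE)
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("format error: incomplete ASCII grid header", call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else .ASCII_NODATA
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows); step <- hdr$cellsize
  dat <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
              quiet = TRUE)
  if (length(dat) != nr * nc)
    stop("format error: expected ", nr * nc, " values, got ", length(dat),
         call. = FALSE)
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]          # to ascending latitude
  mask <- m != nodata
  m[!mask] <- NA_real_
  lat <- hdr$yllcorner + step / 2 + step * (seq_len(nr) - 1L)
  lon <- hdr$xllcorner + step / 2 + step * (seq_len(nc) - 1L)
  # normalize longitudes to [-180, 180), reordering columns
  lon2 <- ((lon + 180) %% 360) - 180
  ord <- order(lon2)
  env_grid(variable, units, lat, lon2[ord], m[, ord, drop = FALSE],
           mask[, ord, drop = FALSE])
}

#' Convert a grid to canonical measurement units
#'
#' Supported conversions: Kelvin to Celsius (`K` -> `degC`) and
#' mol m^-3 to umol L^-1 (`mol_per_m3` -> `umol_per_L`, factor 1000).
#' Grids already in canonical units pass through unchanged (idempotent).
#'
#' @param grid an [env_grid()].
#' @param declared_units override for `grid$units` (optional).
#' @return the converted grid.
#' @export
harmonize_units <- function(grid, declared_units = grid$units) {
  u <- declared_units
  canonical <- unname(.CANON_UNITS[grid$variable])
  if (identical(u, canonical)) { grid$units <- u; return(grid) }
  if (u == "K" && canonical == "degC") {
    grid$values <- grid$values - 273.15
  } else if (u == "mol_per_m3" && canonical == "umol_per_L") {
    grid$values <- grid$values * 1000
  } else {
    stop("unit error: no conversion from '", u, "' to '", canonical,
         "' for variable '", grid$variable, "'", call. = FALSE)
  }
  grid$units <- canonical
  grid
}

#' Regrid a field onto another grid's geometry
#'
#' Bilinear interpolation (default, for smooth fields) or nearest-neighbour
#' (for masks and bias grids). Masked source cells get zero interpolation
#' weight; a target cell whose whole stencil is masked, or which falls
#' outside the source extent, becomes masked. Bilinear reproduces any field
#' affine in (lat, lon) exactly away from mask edges.
#'
#' @param grid source [env_grid()].
#' @param target an `env_grid` supplying the output geometry.
#' @param method `"bilinear"` or `"nearest"`.
#' @return an `env_grid` on the target geometry.
#' @export
regrid <- function(grid, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  step <- grid_step(grid)
  if (max(target$lat) < min(grid$lat) - step || min(target$lat) > max(grid$lat) + step ||
      max(target$lon) < min(grid$lon) - step || min(target$lon) > max(grid$lon) + step)
    stop("input error: source and target domains do not overlap", call. = FALSE)
  nlat <- length(target$lat); nlon <- length(target$lon)
  out <- matrix(NA_real_, nlat, nlon)
  if (method == "nearest") {
    ri <- .nearest_index(target$lat, grid$lat)
    ci <- .nearest_index(target$lon, grid$lon)
    ok <- !is.na(ri); okc <- !is.na(ci)
    for (i in which(ok)) for (j in which(okc)) {
      if (grid$mask[ri[i], ci[j]]) out[i, j] <- grid$values[ri[i], ci[j]]
    }
  } else {
    v <- grid$values; v[!grid$mask] <- 0
    w <- grid$mask * 1
    for (i in seq_len(nlat)) {
      fy <- .lin_weights(target$lat[i], grid$lat)
      if (is.null(fy)) next
      for (j in seq_len(nlon)) {
        fx <- .lin_weights(target$lon[j], grid$lon)
        if (is.null(fx)) next
        ww <- outer(fy$w, fx$w)
        mm <- w[fy$i, fx$i, drop = FALSE]
        tot <- sum(ww * mm)
        if (tot > 1e-12)
          out[i, j] <- sum(ww * mm * grid$values[fy$i, fx$i, drop = FALSE],
                           na.rm = TRUE) / tot
      }
    }
  }
  env_grid(grid$variable, grid$units, target$lat, target$lon, out,
           !is.na(out))
}

.nearest_index <- function(x, centers) {
  step <- if (length(centers) > 1L) diff(centers[1:2]) else 1
  i <- floor((x - centers[1]) / step + 0.5) + 1L
  i[i < 1L | i > length(centers)] <- NA_integer_
  as.integer(i)
}

# indices and weights of the two bracketing centers; NULL if outside hull
.lin_weights <- function(x, centers) {
  n <- length(centers)
  if (x < centers[1] || x > centers[n]) return(NULL)
  if (n == 1L) return(list(i = 1L, w = 1))
  j <- findInterval(x, centers, rightmost.closed = TRUE)
  j <- min(max(j, 1L), n - 1L)
  t <- (x - centers[j]) / (centers[j + 1] - centers[j])
  list(i = c(j, j + 1L), w = c(1 - t, t))
}
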