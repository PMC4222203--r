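# Synthetic ocean: WOA-like environmental layers, a known true suitability
# surface, biased presence sampling, and perturbed future-scenario layers.
# The generator emulates the STRUCTURE of the real inputs (1-degree-class
# masked grid, meridional SST/nutrient gradients, monthly seasonality,
# nitrate-silicate coupling with a decoupling band at the northern range
# edge, austral-summer sampling bias), not their values.

.SST_FREEZE <- -1.9   # degC, seawater freezing point; monthly SST is floored here

#' Parameters of the synthetic ocean
#'
#' Defaults describe a 2-degree Southern-Ocean-centric world: SST rises from
#' `sst_pole` to `sst_equator` through a mid-latitude transition, nitrate is
#' high south of a meandering front near 45S and collapses northward over
#' `nutrient_decay_lat` degrees, silicate tracks nitrate (ratio ~2) except in
#' `si_decouple_band` where it is depleted while nitrate stays high, and
#' monthly SST seasonality has amplitude `seasonal_amp` peaking in February
#' in the southern hemisphere.
#'
#' @param grid_step cell size in degrees (2 for tests; 1 supported). Must
#'   divide both spans evenly.
#' @param lat_range,lon_range domain edges in degrees.
#' @param sst_pole,sst_equator polar and equatorial annual SST, degC.
#' @param seasonal_amp amplitude of the monthly SST cycle, degC (>= 0).
#' @param nitrate_max polar nitrate concentration, umol/L.
#' @param nutrient_decay_lat width (degrees) of the nitrate front.
#' @param si_decouple_band `c(lat_lo, lat_hi)` of the silicate-depleted band.
#' @param land_fraction proportion of cells masked as land, in \[0, 0.3\].
#' @param seed integer seed driving the land mask and noise fields.
#' @return a validated list of class `ocean_params`.
#' @export
ocean_params <- function(grid_step = 2, lat_range = c(-78, 80),
                         lon_range = c(-180, 180), sst_pole = -1.8,
                         sst_equator = 28, seasonal_amp = 3,
                         nitrate_max = 30, nutrient_decay_lat = 4,
                         si_decouple_band = c(-50, -40),
                         land_fraction = 0.2, seed = 1) {
  p <- list(grid_step = grid_step, lat_range = lat_range,
            lon_range = lon_range, sst_pole = sst_pole,
            sst_equator = sst_equator, seasonal_amp = seasonal_amp,
            nitrate_max = nitrate_max,
            nutrient_decay_lat = nutrient_decay_lat,
            si_decouple_band = si_decouple_band,
            land_fraction = land_fraction, seed = as.integer(seed))
  spans <- c(diff(lat_range), diff(lon_range))
  if (any(abs(spans / grid_step - round(spans / grid_step)) > 1e-9))
    stop("configuration error: grid_step must divide the lat and lon spans",
         call. = FALSE)
  if (sst_pole >= sst_equator)
    stop("configuration error: sst_pole must be < sst_equator", call. = FALSE)
  if (seasonal_amp < 0)
    stop("configuration error: seasonal_amp must be >= 0", call. = FALSE)
  if (si_decouple_band[1] >= si_decouple_band[2] ||
      si_decouple_band[1] < lat_range[1] || si_decouple_band[2] > lat_range[2])
    stop("configuration error: si_decouple_band must lie inside lat_range",
         call. = FALSE)
  if (land_fraction < 0 || land_fraction > 0.3)
    stop("configuration error: land_fraction must be in [0, 0.3]", call. = FALSE)
  class(p) <- "ocean_params"
  p
}

#' Parameters of the true suitability surface
#'
#' The "true" habitat suitability is a smooth product of two logistic
#' factors: one rising with nitrate around `nitrate_mid` (15 umol/L, the
#' species' observed nitrate envelope edge) and one falling with SST above
#' `sst_max` (7.5 degC). Smooth logistics rather than hard thresholds keep
#' parameter recovery well-posed.
#'
#' @param nitrate_mid nitrate midpoint, umol/L.
#' @param nitrate_slope logistic slope in L/umol (> 0).
#' @param sst_max SST midpoint, degC.
#' @param sst_slope logistic slope in 1/degC (> 0).
#' @return a list of class `truth_params`.
#' @export
truth_params <- function(nitrate_mid = 15, nitrate_slope = 1,
                         sst_max = 7.5, sst_slope = 1) {
  if (nitrate_slope <= 0 || sst_slope <= 0)
    stop("configuration error: slopes must be > 0", call. = FALSE)
  structure(list(nitrate_mid = nitrate_mid, nitrate_slope = nitrate_slope,
                 sst_max = sst_max, sst_slope = sst_slope),
            class = "truth_params")
}

# smooth random land blobs; exactly land_fraction of cells become land
.make_mask <- function(lat, lon, land_fraction, seed) {
  nlat <- length(lat); nlon <- length(lon)
  if (land_fraction <= 0) return(matrix(TRUE, nlat, nlon))
  rng <- .local_rng(seed)
  k <- 25L
  clat <- rng$runif(k, min(lat), max(lat))
  clon <- rng$runif(k, -180, 180)
  rad <- rng$runif(k, 5, 15)
  field <- matrix(0, nlat, nlon)
  for (b in seq_len(k)) {
    dlon <- abs(outer(rep(1, nlat), lon) - clon[b])
    dlon <- pmin(dlon, 360 - dlon)                 # wrap across the dateline
    dlat <- outer(lat, rep(1, nlon)) - clat[b]
    field <- field + exp(-(dlon^2 + dlat^2) / (2 * rad[b]^2))
  }
  field < stats::quantile(field, 1 - land_fraction, type = 7)
}

# seeded RNG sandbox: draws do not disturb the global .Random.seed
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       sample_int = draw(function(n, size, replace, prob)
         sample.int(n, size, replace = replace, prob = prob)))
}

# smooth pseudo-random 2-D field, zero mean, unit-ish scale
.smooth_noise <- function(lat, lon, rng, n_modes = 12L) {
  nlat <- length(lat); nlon <- length(lon)
  a <- rng$rnorm(n_modes, 0, 1)
  kx <- rng$sample_int(4L, n_modes, replace = TRUE, prob = NULL)
  ky <- rng$sample_int(4L, n_modes, replace = TRUE, prob = NULL)
  ph1 <- rng$runif(n_modes, 0, 2 * pi); ph2 <- rng$runif(n_modes, 0, 2 * pi)
  f <- matrix(0, nlat, nlon)
  latn <- (lat - min(lat)) / diff(range(lat))
  for (m in seq_len(n_modes))
    f <- f + a[m] * outer(sin(2 * pi * ky[m] * latn + ph2[m]),
                          sin(pi * kx[m] * lon / 180 + ph1[m]))
  f / max(1e-9, stats::sd(as.vector(f)))
}

#' Generate the synthetic environmental layers
#'
#' Builds 12 monthly stacks of sst, salinity, nitrate and silicate on one
#' masked grid, plus an annual stack equal (exactly) to the per-cell mean of
#' the monthly stacks. Monthly SST is the annual profile plus a seasonal
#' anomaly `-seasonal_amp * sign(lat) * cos(2*pi*(m-2)/12)` (Southern-
#' Hemisphere February warmest, August coldest), floored at -1.9 degC.
#' Nitrate is monotone decreasing from the southern pole toward the equator
#' along every longitude, with a sinusoidally meandering front; silicate is
#' approximately `2 * nitrate` plus smooth noise except inside the
#' decoupling band where it is depleted and decorrelated from nitrate.
#'
#' @param params an [ocean_params()] object.
#' @return list with elements `annual` (an `env_stack`) and `monthly`
#'   (list of 12 `env_stack`s). Deterministic for a fixed seed.
#' @export
make_environment <- function(params) {
  stopifnot(inherits(params, "ocean_params"))
  step <- params$grid_step
  lat <- seq(params$lat_range[1] + step / 2, params$lat_range[2] - step / 2, by = step)
  lon <- seq(params$lon_range[1] + step / 2, params$lon_range[2] - step / 2, by = step)
  nlat <- length(lat); nlon <- length(lon)
  mask <- .make_mask(lat, lon, params$land_fraction, params$seed)
  rng <- .local_rng(params$seed + 1L)

  latm <- outer(lat, rep(1, nlon))
  lonm <- outer(rep(1, nlat), lon)

  # annual SST profile: equatorial warm pool to polar water through a
  # mid-latitude transition centered at 35 degrees
  sst_base <- params$sst_equator +
    (params$sst_pole - params$sst_equator) * stats::plogis((abs(latm) - 35) / 10)

  # nitrate: high south of a meandering front near 45S; monotone in latitude
  front <- -45 + 3 * sin(2 * pi * lonm / 360)
  nitrate <- params$nitrate_max *
    stats::plogis(-(latm - front) / params$nutrient_decay_lat)

  # silicate tracks nitrate except inside the decoupling band
  si_noise <- .smooth_noise(lat, lon, rng)
  silicate <- 2 * nitrate + 1.0 * si_noise
  band <- latm >= params$si_decouple_band[1] & latm <= params$si_decouple_band[2]
  silicate[band] <- 5 + 1.0 * si_noise[band]
  silicate <- pmax(silicate, 0.1)

  salinity <- 34.2 - 0.8 * stats::plogis((abs(latm) - 45) / 8) +
    0.15 * .smooth_noise(lat, lon, rng)

  month_grids <- vector("list", 12L)
  sst_sum <- matrix(0, nlat, nlon)
  for (m in 1:12) {
    anom <- -params$seasonal_amp * sign(latm) * cos(2 * pi * (m - 2) / 12)
    sst_m <- pmax(sst_base + anom, .SST_FREEZE)
    sst_sum <- sst_sum + sst_m
    month_grids[[m]] <- sst_m
  }
  sst_annual <- sst_sum / 12

  mk <- function(var, vals) {
    vals[!mask] <- NA_real_
    env_grid(var, unname(.CANON_UNITS[var]), lat, lon, vals, mask)
  }
  monthly <- lapply(1:12, function(m) {
    env_stack(list(mk("sst", month_grids[[m]]), mk("salinity", salinity),
                   mk("nitrate", nitrate), mk("silicate", silicate)),
              time_tag = m)
  })
  annual <- env_stack(list(mk("sst", sst_annual), mk("salinity", salinity),
                           mk("nitrate", nitrate), mk("silicate", silicate)),
                      time_tag = "annual")
  list(annual = annual, monthly = monthly)
}

#' Evaluate the true suitability surface on a stack
#'
#' Per ocean cell, `s = plogis(nitrate_slope * (nitrate - nitrate_mid)) *
#' plogis(sst_slope * (sst_max - sst))`, which lies in \[0, 1\].
#'
#' @param stack an `env_stack` containing `nitrate` and `sst`.
#' @param truth a [truth_params()] object.
#' @return an [env_grid()] with variable `"suitability"`.
#' @export
true_suitability <- function(stack, truth = truth_params()) {
  miss <- setdiff(c("nitrate", "sst"), names(stack$grids))
  if (length(miss))
    stop("input error: stack is missing variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- stack$grids$nitrate; s <- stack$grids$sst
  v <- stats::plogis(truth$nitrate_slope * (n$values - truth$nitrate_mid)) *
    stats::plogis(truth$sst_slope * (truth$sst_max - s$values))
  env_grid("suitability", "dimensionless", n$lat, n$lon, v, n$mask)
}

#' Default seasonal sampling weights (austral-summer bias)
#'
#' Monthly sampling effort proportional to `1 + cos(2*pi*(m-1)/12)`,
#' normalized: maximal in January, near zero in July, mimicking the strong
#' austral-summer bias of high-latitude sampling campaigns.
#' @return numeric vector of 12 proportions summing to 1.
#' @export
default_month_weights <- function() {
  w <- 1 + cos(2 * pi * (0:11) / 12)
  w / sum(w)
}

#' Sample biased presence records from the true suitability
#'
#' Draws `n` records over (ocean cell, month) with probability proportional
#' to `suitability(month) * bias(cell) * month_weights[month]`. Records carry
#' the lon/lat of the cell center, the month, and a source tag.
#'
#' @param truth_maps list of 12 suitability [env_grid()]s (one per month).
#' @param n number of records (with replacement; repeat visits to a cell in
#'   different months are the point of the downstream dedupe bookkeeping).
#' @param bias optional effort [env_grid()] on the same geometry.
#' @param month_weights 12 non-negative proportions summing to 1.
#' @param seed integer seed.
#' @return data.frame of class `occurrence_set` with columns
#'   `lon, lat, month, source`.
#' @export
sample_presences <- function(truth_maps, n, bias = NULL,
                             month_weights = default_month_weights(),
                             seed = 1) {
  stopifnot(length(truth_maps) == 12L, n >= 1)
  if (abs(sum(month_weights) - 1) > 1e-8)
    stop("input error: month_weights must sum to 1", call. = FALSE)
  g1 <- truth_maps[[1]]
  if (!is.null(bias) && !same_geometry(g1, bias))
    stop("alignment error: bias grid geometry mismatch", call. = FALSE)
  idx <- which(g1$mask)
  b <- if (is.null(bias)) rep(1, length(idx)) else bias$values[idx]
  w <- unlist(lapply(1:12, function(m)
    truth_maps[[m]]$values[idx] * b * month_weights[m]))
  w[is.na(w)] <- 0
  if (sum(w) <= 0)
    stop("input error: all sampling weights are zero", call. = FALSE)
  rng <- .local_rng(seed)
  draw <- rng$sample_int(length(w), n, replace = TRUE, prob = w)
  month <- (draw - 1L) %/% length(idx) + 1L
  cell <- idx[(draw - 1L) %% length(idx) + 1L]
  rc <- arrayInd(cell, dim(g1$values))
  out <- data.frame(lon = g1$lon[rc[, 2]], lat = g1$lat[rc[, 1]],
                    month = month, source = "synthetic")
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Perturbed future-scenario layers for pseudo-GCMs
#'
#' Each pseudo-GCM `g` warms SST by `delta_sst * (1 + eps_g)` and scales
#' nitrate (and silicate, consistently) by `nitrate_scale * (1 + eps'_g)`,
#' with per-GCM perturbations drawn once from `seed`
#' (`eps ~ Normal(0, perturb_sd)`). Salinity is unchanged.
#'
#' @param monthly list of 12 present-day `env_stack`s.
#' @param delta_sst mean warming, degC.
#' @param nitrate_scale multiplicative nutrient change in (0, 1].
#' @param n_gcms number of pseudo-GCMs (>= 1).
#' @param seed integer seed.
#' @param scenario scenario tag for the outputs (e.g. `"rcp85"`).
#' @param perturb_sd standard deviation of the per-GCM perturbations
#'   (0 gives identical members up to the mean scenario shift).
#' @return list of length `n_gcms`; each element a list of 12 `env_stack`s
#'   tagged with the scenario and a GCM id.
#' @export
make_future <- function(monthly, delta_sst = 2, nitrate_scale = 0.8,
                        n_gcms = 2, seed = 1, scenario = "rcp85",
                        perturb_sd = 0.1) {
  if (n_gcms < 1) stop("configuration error: n_gcms must be >= 1", call. = FALSE)
  if (nitrate_scale <= 0 || nitrate_scale > 1)
    stop("configuration error: nitrate_scale must be in (0, 1]", call. = FALSE)
  rng <- .local_rng(seed)
  eps_sst <- rng$rnorm(n_gcms, 0, perturb_sd)
  eps_nit <- rng$rnorm(n_gcms, 0, perturb_sd)
  lapply(seq_len(n_gcms), function(g) {
    lapply(monthly, function(st) {
      gr <- st$grids
      gr$sst$values <- gr$sst$values + delta_sst * (1 + eps_sst[g])
      sc <- nitrate_scale * (1 + eps_nit[g])
      gr$nitrate$values <- gr$nitrate$values * sc
      gr$silicate$values <- gr$silicate$values * sc
      env_stack(gr, time_tag = st$time_tag, scenario_tag = scenario,
                gcm_tag = sprintf("gcm%02d", g))
    })
  })
}
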