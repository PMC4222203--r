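# Presence-only occurrence handling: CSV parsing, grid-cell deduplication in
# yearly or monthly mode, covariate extraction, background sampling and bias
# grids.

#' Read presence-only occurrence records from CSV
#'
#' Expects a header containing `lon` and `lat`; optional `month` (integer
#' 1..12 or an ISO date whose month is taken) and `source`. Rows with
#' unparseable or out-of-range coordinates are rejected and counted.
#'
#' @param path CSV file path.
#' @return data.frame of class `occurrence_set` with columns
#'   `lon, lat, month, source` (`month` is `NA` when unknown) and attribute
#'   `n_rejected`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("lon", "lat") %in% names(df)))
    stop("format error: CSV must have lon and lat columns", call. = FALSE)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  month <- rep(NA_integer_, nrow(df))
  mcol <- if ("month" %in% names(df)) df$month else if ("date" %in% names(df)) df$date else NULL
  if (!is.null(mcol)) {
    mc <- as.character(mcol)
    asint <- suppressWarnings(as.integer(mc))
    isdate <- is.na(asint) & grepl("^\\d{4}-\\d{2}", mc)
    month[!is.na(asint)] <- asint[!is.na(asint)]
    month[isdate] <- as.integer(substr(mc[isdate], 6, 7))
    month[!is.na(month) & (month < 1 | month > 12)] <- NA_integer_
  }
  src <- if ("source" %in% names(df)) as.character(df$source) else rep("unknown", nrow(df))
  # normalize longitudes given as [0, 360)
  lon <- ifelse(!is.na(lon) & lon >= 180 & lon < 360, lon - 360, lon)
  ok <- !is.na(lon) & !is.na(lat) & lon >= -180 & lon < 180 & lat >= -90 & lat <= 90
  n_rejected <- sum(!ok)
  if (n_rejected > 0)
    message("read_occurrences: rejected ", n_rejected,
            " row(s) with invalid coordinates")
  out <- data.frame(lon = lon[ok], lat = lat[ok], month = month[ok],
                    source = src[ok])
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Deduplicate occurrences at grid resolution
#'
#' Yearly mode keeps one record per occupied grid cell (repeat visits to the
#' same location in different months collapse, the mechanism by which 210
#' monthly records can become 157 yearly ones). Monthly mode keeps one per
#' (cell, month) pair; records with unknown month are kept in yearly mode
#' and dropped (with a reported count) in monthly mode.
#'
#' @param records an `occurrence_set` (or data.frame with lon/lat/month).
#' @param grid an [env_grid()] supplying the geometry.
#' @param mode `"yearly"` or `"monthly"`.
#' @return deduplicated `occurrence_set` (first record of each group, in
#'   input order) with attributes `mode`, `n_dropped_unknown_month` and
#'   `cell` (matrix of row/col indices).
#' @export
dedupe <- function(records, grid, mode = c("yearly", "monthly")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("input error: no records", call. = FALSE)
  rc <- cell_of(grid, records$lon, records$lat)
  inside <- !is.na(rc[, 1]) & !is.na(rc[, 2])
  records <- records[inside, , drop = FALSE]
  rc <- rc[inside, , drop = FALSE]
  n_unknown <- 0L
  if (mode == "monthly") {
    known <- !is.na(records$month)
    n_unknown <- sum(!known)
    if (n_unknown > 0)
      message("dedupe: dropped ", n_unknown, " record(s) without month in monthly mode")
    records <- records[known, , drop = FALSE]
    rc <- rc[known, , drop = FALSE]
    key <- paste(rc[, 1], rc[, 2], records$month)
  } else {
    key <- paste(rc[, 1], rc[, 2])
  }
  keep <- !duplicated(key)
  if (!any(keep)) warning("dedupe: empty result")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "n_dropped_unknown_month") <- n_unknown
  attr(out, "cell") <- rc[keep, , drop = FALSE]
  class(out) <- c("occurrence_set", "data.frame")
  out
}

.new_sample_matrix <- function(x, role, cell_ids, months, n_dropped = 0L) {
  structure(list(x = x, role = role, cell_ids = cell_ids, months = months,
                 n_dropped_masked = n_dropped),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<sample_matrix> %s: %d rows x %d variables (%s)\n",
              x$role, nrow(x$x), ncol(x$x),
              paste(colnames(x$x), collapse = ", ")))
  invisible(x)
}

#' Extract per-record environmental covariates
#'
#' Yearly mode reads every record's covariates from the annual stack;
#' monthly mode reads each record's covariates from the stack of its
#' sampling month. Records falling on masked (land) cells are dropped with
#' a reported count.
#'
#' @param occset deduplicated `occurrence_set` (see [dedupe()]).
#' @param annual annual `env_stack`.
#' @param monthly list of 12 monthly `env_stack`s (monthly mode).
#' @param mode `"yearly"` or `"monthly"`.
#' @param variables covariate order; defaults to the annual stack's variables.
#' @return a `sample_matrix` with role `"presence"`.
#' @export
extract_covariates <- function(occset, annual, monthly = NULL,
                               mode = c("yearly", "monthly"),
                               variables = names(annual$grids)) {
  mode <- match.arg(mode)
  ref <- annual$grids[[1]]
  rc <- cell_of(ref, occset$lon, occset$lat)
  n <- nrow(occset)
  x <- matrix(NA_real_, n, length(variables), dimnames = list(NULL, variables))
  for (i in seq_len(n)) {
    st <- if (mode == "yearly") annual else {
      m <- occset$month[i]
      if (is.na(m) || is.null(monthly) || length(monthly) < m)
        stop("input error: missing monthly stack for record month ", m,
             call. = FALSE)
      monthly[[m]]
    }
    for (v in variables) {
      g <- st$grids[[v]]
      if (is.null(g)) stop("input error: stack missing variable ", v, call. = FALSE)
      x[i, v] <- g$values[rc[i, 1], rc[i, 2]]
    }
  }
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("extract_covariates: dropped ", n_dropped, " record(s) on masked cells")
  lin <- (rc[keep, 2] - 1L) * length(ref$lat) + rc[keep, 1]
  .new_sample_matrix(x[keep, , drop = FALSE], "presence", lin,
                     if (mode == "monthly") occset$month[keep] else rep(NA_integer_, sum(keep)),
                     n_dropped)
}

#' Sample background points over the ocean
#'
#' Without a bias grid, ocean cells are drawn uniformly; with one, with
#' probability proportional to the bias value (zero-bias cells are never
#' drawn). In monthly mode each draw is assigned a month uniformly at random
#' and its covariates come from that month's stack, so the background
#' represents the full seasonal cycle of available environments.
#'
#' @param stack annual `env_stack` (supplies geometry, mask and yearly
#'   covariates).
#' @param n number of points (default 10000, the MaxEnt convention).
#' @param bias optional effort [env_grid()] on the same geometry.
#' @param seed integer seed.
#' @param replace sample with replacement? Default `FALSE` (requires
#'   `n <=` number of admissible ocean cells).
#' @param monthly optional list of 12 monthly `env_stack`s; when given,
#'   covariates are month-resolved as described above.
#' @param variables covariate order.
#' @return a `sample_matrix` with role `"background"`.
#' @export
sample_background <- function(stack, n = 10000, bias = NULL, seed = 1,
                              replace = FALSE, monthly = NULL,
                              variables = names(stack$grids)) {
  ref <- stack$grids[[1]]
  idx <- which(ref$mask)
  w <- rep(1, length(idx))
  if (!is.null(bias)) {
    if (!same_geometry(ref, bias))
      stop("alignment error: bias grid geometry mismatch", call. = FALSE)
    w <- bias$values[idx]
    w[is.na(w)] <- 0
    if (all(w <= 0)) stop("input error: all-zero bias grid", call. = FALSE)
    pos <- w > 0
    idx <- idx[pos]; w <- w[pos]
  }
  if (!replace && n > length(idx))
    stop("input error: n exceeds the number of admissible ocean cells",
         call. = FALSE)
  rng <- .local_rng(seed)
  pick <- if (is.null(bias) && !replace && n == length(idx)) seq_along(idx)
          else rng$sample_int(length(idx), n, replace = replace,
                              prob = if (is.null(bias)) NULL else w)
  cells <- idx[pick]
  months <- rep(NA_integer_, n)
  if (!is.null(monthly))
    months <- pmin(pmax(as.integer(ceiling(rng$runif(n, 0, 12))), 1L), 12L)
  x <- matrix(NA_real_, n, length(variables), dimnames = list(NULL, variables))
  if (is.null(monthly)) {
    for (v in variables) x[, v] <- stack$grids[[v]]$values[cells]
  } else {
    for (m in 1:12) {
      rows <- which(months == m)
      if (!length(rows)) next
      for (v in variables) x[rows, v] <- monthly[[m]]$grids[[v]]$values[cells[rows]]
    }
  }
  .new_sample_matrix(x, "background", cells, months)
}

#' Build a sampling-effort bias grid from all-taxa records
#'
#' Per-cell record counts, optionally smoothed with a square moving-window
#' mean of the given radius (in cells), then floored over ocean cells at
#' `floor_frac * max` so that every ocean cell keeps a small positive
#' sampling probability (the background stays global).
#'
#' @param records data.frame with `lon`, `lat`.
#' @param grid an [env_grid()] supplying geometry and mask.
#' @param smooth_radius window radius in cells (0 = raw counts).
#' @param floor_frac positive floor as a fraction of the maximum bias.
#' @return an [env_grid()] with variable `"bias"`.
#' @export
build_bias_grid <- function(records, grid, smooth_radius = 0,
                            floor_frac = 1e-6) {
  if (nrow(records) == 0L) stop("input error: no records", call. = FALSE)
  rc <- cell_of(grid, records$lon, records$lat)
  counts <- matrix(0, length(grid$lat), length(grid$lon))
  ok <- !is.na(rc[, 1]) & !is.na(rc[, 2])
  for (i in which(ok)) counts[rc[i, 1], rc[i, 2]] <- counts[rc[i, 1], rc[i, 2]] + 1
  if (smooth_radius > 0) {
    r <- as.integer(smooth_radius)
    sm <- matrix(0, nrow(counts), ncol(counts))
    for (i in seq_len(nrow(counts))) {
      ri <- max(1, i - r):min(nrow(counts), i + r)
      for (j in seq_len(ncol(counts))) {
        cj <- max(1, j - r):min(ncol(counts), j + r)
        sm[i, j] <- mean(counts[ri, cj])
      }
    }
    counts <- sm
  }
  mx <- max(counts[grid$mask], 0)
  if (mx > 0) counts <- pmax(counts, floor_frac * mx) else counts[] <- 1
  env_grid("bias", "dimensionless", grid$lat, grid$lon,
           ifelse(grid$mask, counts, NA_real_), grid$mask)
}
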