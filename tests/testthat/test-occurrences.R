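# occurrence parsing, dedup bookkeeping, covariate extraction, background

test_that("read_occurrences parses months, dates and rejects bad coordinates", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("lon,lat,month,source",
               "10.5,-50.5,2,GBIF",
               "11.5,-51.5,,GDD",
               "12.5,95,3,GBIF",          # lat out of range -> rejected
               "200.5,-40.5,2001-08-15,HDC"), p)  # lon 200.5 -> -159.5; ISO date
  expect_message(occ <- read_occurrences(p), "rejected 1")
  expect_equal(nrow(occ), 3)
  expect_equal(occ$month, c(2L, NA, 8L))
  expect_equal(occ$lon[3], -159.5)
  expect_equal(attr(occ, "n_rejected"), 1L)
  expect_error(read_occurrences(tempfile()), "I/O error")
  writeLines("x,y\n1,2", p)
  expect_error(read_occurrences(p), "lon and lat")
  unlink(p)
})

test_that("dedupe mirrors the repeat-visit bookkeeping (yearly vs monthly)", {
  g <- env_grid("sst", "degC", seq(-59.5, -40.5, 1), seq(0.5, 19.5, 1),
                matrix(0, 20, 20))
  rec <- data.frame(lon = c(10.5, 10.5, 12.5), lat = c(-50.5, -50.5, -52.5),
                    month = c(2L, 8L, 2L), source = "t")
  y <- dedupe(rec, g, "yearly")
  m <- dedupe(rec, g, "monthly")
  expect_equal(nrow(y), 2)       # two distinct cells
  expect_equal(nrow(m), 3)       # (cell, month) all distinct
  # all in one cell, one month -> 1 in both modes
  rec1 <- data.frame(lon = rep(10.5, 4), lat = rep(-50.5, 4), month = 2L, source = "t")
  expect_equal(nrow(dedupe(rec1, g, "yearly")), 1)
  expect_equal(nrow(dedupe(rec1, g, "monthly")), 1)
  # unknown months: kept in yearly, dropped (and counted) in monthly
  rec2 <- data.frame(lon = c(10.5, 11.5), lat = c(-50.5, -50.5),
                     month = c(NA, 3L), source = "t")
  expect_equal(nrow(dedupe(rec2, g, "yearly")), 2)
  expect_message(m2 <- dedupe(rec2, g, "monthly"), "dropped 1")
  expect_equal(nrow(m2), 1)
  expect_equal(attr(m2, "n_dropped_unknown_month"), 1L)
})

test_that("dedupe equals brute-force binning and is idempotent on random input", {
  g <- env_grid("sst", "degC", seq(-77, 79, 2), seq(-179, 179, 2),
                matrix(0, 79, 180))
  set.seed(42)
  rec <- data.frame(lon = runif(500, -180, 179.9), lat = runif(500, -78, 80),
                    month = sample(12, 500, replace = TRUE), source = "r")
  y <- dedupe(rec, g, "yearly"); m <- dedupe(rec, g, "monthly")
  expect_equal(nrow(y), brute_bin_counts(rec$lon, rec$lat, rec$month, g, FALSE))
  expect_equal(nrow(m), brute_bin_counts(rec$lon, rec$lat, rec$month, g, TRUE))
  expect_gte(nrow(m), nrow(y))                    # the 210-vs-157 phenomenon
  expect_equal(nrow(dedupe(y, g, "yearly")), nrow(y))     # idempotent
  expect_equal(nrow(dedupe(m, g, "monthly")), nrow(m))
})

test_that("extract_covariates reads the right stack per mode and drops land", {
  w <- default_world()
  env <- w$env
  g <- env$annual$grids$sst
  # one ocean cell, visited in February
  oc <- which(g$mask & outer(g$lat < -60, rep(TRUE, length(g$lon))), arr.ind = TRUE)[1, ]
  rec <- data.frame(lon = g$lon[oc[2]], lat = g$lat[oc[1]], month = 2L, source = "t")
  dd <- dedupe(rec, g, "monthly")
  sm <- extract_covariates(dd, env$annual, env$monthly, "monthly")
  expect_equal(unname(sm$x[1, "sst"]), env$monthly[[2]]$grids$sst$values[oc[1], oc[2]])
  sm_y <- extract_covariates(dedupe(rec, g, "yearly"), env$annual, mode = "yearly")
  expect_equal(unname(sm_y$x[1, "sst"]), g$values[oc[1], oc[2]])
  # February anomaly separates the two modes wherever the floor is not active
  if (sm$x[1, "sst"] > -1.9 + 3)
    expect_gt(sm$x[1, "sst"], sm_y$x[1, "sst"])
  # record on land -> dropped with count
  land <- which(!g$mask, arr.ind = TRUE)[1, ]
  rec2 <- data.frame(lon = g$lon[land[2]], lat = g$lat[land[1]], month = 2L, source = "t")
  dd2 <- dedupe(rbind(rec, rec2), g, "monthly")
  expect_message(sm2 <- extract_covariates(dd2, env$annual, env$monthly, "monthly"),
                 "dropped 1")
  expect_equal(nrow(sm2$x), 1)
  expect_equal(sm2$n_dropped_masked, 1L)
})

test_that("background sampling: exhaustive draw, degenerate bias, bias ratio", {
  w <- default_world()
  env <- w$env
  n_ocean <- sum(env$annual$grids$sst$mask)
  all_bg <- sample_background(env$annual, n_ocean, seed = 1)
  expect_equal(length(unique(all_bg$cell_ids)), n_ocean)   # every cell exactly once
  expect_error(sample_background(env$annual, n_ocean + 1), "exceeds")

  ref <- env$annual$grids$sst
  bias_v <- matrix(NA_real_, length(ref$lat), length(ref$lon))
  bias_v[ref$mask] <- 0
  one <- which(ref$mask)[100]
  bias_v[one] <- 1
  bias <- env_grid("bias", "dimensionless", ref$lat, ref$lon, bias_v, ref$mask)
  b1 <- sample_background(env$annual, 1, bias = bias, seed = 2)
  expect_equal(b1$cell_ids, one)

  # 2:1 bias between southern and northern halves
  bias2_v <- ifelse(ref$mask, ifelse(outer(ref$lat < 0, rep(TRUE, length(ref$lon))), 2, 1), NA)
  bias2 <- env_grid("bias", "dimensionless", ref$lat, ref$lon, bias2_v, ref$mask)
  bb <- sample_background(env$annual, 10000, bias = bias2, seed = 3, replace = TRUE)
  south <- bias2$values[bb$cell_ids] == 2
  n_s <- sum(outer(ref$lat < 0, rep(TRUE, length(ref$lon))) & ref$mask)
  n_n <- n_ocean - n_s
  want <- 2 * n_s / (2 * n_s + n_n)
  expect_lt(abs(mean(south) - want) / want, 0.05)
  expect_error(sample_background(env$annual, 5,
                                 bias = env_grid("bias", "dimensionless", ref$lat, ref$lon,
                                                 ifelse(ref$mask, 0, NA), ref$mask)),
               "all-zero")
})

test_that("uniform background inclusion is exchangeable across cells", {
  w <- default_world()
  env <- w$env
  ref <- env$annual$grids$sst
  n_ocean <- sum(ref$mask)
  hits <- numeric(n_ocean)
  reps <- 60; n <- 500
  for (s in seq_len(reps)) {
    bg <- sample_background(env$annual, n, seed = 1000 + s)
    hits[match(bg$cell_ids, which(ref$mask))] <-
      hits[match(bg$cell_ids, which(ref$mask))] + 1
  }
  p_hat <- hits / reps
  expect_lt(abs(mean(p_hat) - n / n_ocean), 0.002)
  # no cell wildly over/under-included
  expect_lt(max(abs(p_hat - n / n_ocean)), 0.18)
})

test_that("build_bias_grid counts, smooths and floors", {
  g <- toy_grid(10, 10, step = 2, lat0 = -60, lon0 = 0, variable = "bias")
  rec <- data.frame(lon = c(4, 4, 6), lat = c(-50, -50, -50))
  b0 <- build_bias_grid(rec, g, smooth_radius = 0, floor_frac = 0)
  rc <- cell_of(g, 4, -50)
  expect_equal(b0$values[rc[1, 1], rc[1, 2]], 2)
  expect_equal(sum(b0$values > 0, na.rm = TRUE), 2)
  # flooring keeps the whole ocean admissible
  b1 <- build_bias_grid(rec, g, smooth_radius = 0)
  expect_true(all(b1$values[g$mask] > 0))
  # smoothing spreads mass but conserves the clustered concentration
  set.seed(5)
  clust <- data.frame(lon = runif(1000, 2, 8), lat = runif(1000, -54, -48))
  bs <- build_bias_grid(clust, g, smooth_radius = 1)
  latm <- outer(g$lat, rep(1, length(g$lon)))
  lonm <- outer(rep(1, length(g$lat)), g$lon)
  basin <- latm >= -56 & latm <= -46 & lonm >= 0 & lonm <= 10
  expect_gt(sum(bs$values[basin], na.rm = TRUE) / sum(bs$values, na.rm = TRUE), 0.8)
})
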