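# projection, thresholding, consensus, ensembles, boundaries, evaluation

test_that("projecting reproduces training-row scores and masks land", {
  w <- default_world()
  map <- project(w$model_y, w$env$annual)
  expect_true(all(map$grid$values >= 0 & map$grid$values <= 1, na.rm = TRUE))
  expect_identical(map$grid$mask, w$env$annual$grids$sst$mask)
  # scores at presence cells equal direct prediction on the training rows
  direct <- predict(w$model_y, w$pres_y$x)
  expect_equal(unname(map$grid$values[w$pres_y$cell_ids]), unname(direct),
               tolerance = 1e-12)
  # lambda = 0 model projects a constant
  m0 <- w$model_y; m0$lambda[] <- 0; m0$logZ <- log(m0$meta$n_background)
  map0 <- project(m0, w$env$annual)
  expect_equal(length(unique(round(map0$grid$values[map0$grid$mask], 12))), 1)
})

test_that("threshold_map: boundary convention, nestedness, brute-force area", {
  set.seed(10)
  v <- matrix(runif(48), 6, 8); v[1, 1] <- 0.2
  g <- toy_grid(6, 8, values = v)
  b <- threshold_map(g, 0.2)
  expect_equal(b$values[1, 1], 1)                   # >= convention at the cutoff
  b1 <- threshold_map(g, 0.1); b3 <- threshold_map(g, 0.3)
  expect_true(all(b3$values <= b1$values))          # nestedness
  expect_equal(sum(b$values), sum(v >= 0.2))        # brute-force count
})

test_that("consensus counts equal a per-cell brute-force tally", {
  set.seed(12)
  maps <- lapply(1:16, function(i) toy_grid(5, 6, values = matrix(runif(30), 5, 6)))
  cons <- consensus(maps, t = 0.2)
  expect_equal(cons$n_models, 16)
  tally <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6)
    for (m in maps) tally[i, j] <- tally[i, j] + (m$values[i, j] >= 0.2)
  expect_equal(cons$grid$values, tally)
  # all maps identical and above t -> count = n everywhere
  same <- lapply(1:4, function(i) toy_grid(3, 3, values = matrix(0.9, 3, 3)))
  expect_true(all(consensus(same, 0.2)$grid$values == 4))
  bad <- toy_grid(4, 6)
  expect_error(consensus(c(maps, list(bad)), 0.2), "alignment error")
})

test_that("ensemble of identical members has sd 0 and mean equal to each member", {
  w <- default_world()
  fut0 <- make_future(w$env$monthly, delta_sst = 0, nitrate_scale = 1,
                      n_gcms = 3, seed = 1, perturb_sd = 0)
  ens0 <- ensemble(w$model_m, lapply(fut0, `[[`, 2))
  expect_true(all(ens0$sd$values == 0, na.rm = TRUE))
  pres_map <- project(w$model_m, w$env$monthly[[2]])
  expect_equal(ens0$mean$values, pres_map$grid$values, tolerance = 1e-12)
  expect_error(ensemble(w$model_m, list(w$env$monthly[[1]], w$env$monthly[[2]])),
               "share month")
})

test_that("boundary_latitude finds the equatorward edge of the polar range", {
  v <- matrix(0, 10, 4)
  v[1:5, ] <- 0.9                                  # south of -45 suitable
  g <- toy_grid(10, 4, step = 2, lat0 = -53)       # lats -53..-35
  b <- boundary_latitude(env_grid("suitability", "dimensionless", g$lat, g$lon, v),
                         t = 0.2)
  expect_true(all(b$lat == -45))
  # empty column -> NA
  v2 <- v; v2[, 2] <- 0
  b2 <- boundary_latitude(env_grid("suitability", "dimensionless", g$lat, g$lon, v2), 0.2)
  expect_true(is.na(b2$lat[2]))
  expect_equal(b2$lat[1], -45)
  # a detached equatorward patch is ignored under contiguity
  v3 <- v; v3[9, 3] <- 0.9
  b3 <- boundary_latitude(env_grid("suitability", "dimensionless", g$lat, g$lon, v3), 0.2)
  expect_equal(b3$lat[3], -45)
  expect_equal(boundary_latitude(env_grid("suitability", "dimensionless",
                                          g$lat, g$lon, v3), 0.2,
                                 contiguous = FALSE)$lat[3], -37)
  # nested thresholds: higher cutoff is poleward or equal, per column
  set.seed(13)
  for (rep in 1:10) {
    prof <- plogis(seq(4, -6, length.out = 10) + rnorm(1))
    vm <- matrix(rep(prof, 4), 10, 4)
    gm <- env_grid("suitability", "dimensionless", g$lat, g$lon, vm)
    b01 <- boundary_latitude(gm, 0.1); b03 <- boundary_latitude(gm, 0.3)
    ok <- !is.na(b01$lat) & !is.na(b03$lat)
    expect_true(all(b03$lat[ok] <= b01$lat[ok]))
  }
})

test_that("auc matches hand cases", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(auc(numeric(0), 1), "empty")
})

test_that("cross_validate is deterministic and handles leave-one-out", {
  set.seed(14)
  pres <- make_sm(cbind(a = rnorm(8, 4)))
  bg <- make_sm(cbind(a = rnorm(60, 0, 2)), "background")
  cv1 <- cross_validate(pres, bg, k = 8, seed = 5, knots_per_variable = 4)
  cv2 <- cross_validate(pres, bg, k = 8, seed = 5, knots_per_variable = 4)
  expect_identical(cv1, cv2)
  expect_true(is.finite(cv1$mean) && is.finite(cv1$sd))
  expect_error(cross_validate(pres, bg, k = 9), "exceeds")
})

test_that("jackknife separates informative from noise variables", {
  set.seed(15)
  n_bg <- 250
  A_bg <- runif(n_bg, 0, 10); noise_bg <- runif(n_bg, 0, 10)
  pres <- make_sm(cbind(A = runif(30, 7, 10), noise = runif(30, 0, 10)))
  bg <- make_sm(cbind(A = A_bg, noise = noise_bg), "background")
  jk <- jackknife_variables(pres, bg, knots_per_variable = 8)
  gain_full <- attr(jk, "gain_full")
  g_only <- setNames(jk$gain_only, jk$variable)
  expect_lt(g_only["noise"], 0.15)                      # ~zero for pure noise
  expect_gt(g_only["A"], g_only["noise"])
  expect_true(all(jk$gain_without <= gain_full + 1e-6)) # nested-model property
})

test_that("response curves: flat for null model, monotone for a single forward hinge", {
  w <- default_world()
  m0 <- w$model_y; m0$lambda[] <- 0
  rc0 <- response_curve(m0, "nitrate", 20)
  expect_equal(length(unique(round(rc0$suitability, 12))), 1)
  ft <- data.frame(variable = "a", knot = 2, direction = "forward", lo = 0, hi = 10)
  m1 <- structure(list(features = ft, lambda = 2, beta = 0.1, beta_multiplier = 1,
                       logZ = 1, entropy = 1, tau = 0.5, variables = "a",
                       bg_means = c(a = 5),
                       gain_trace = list(feature = 1L, gain = 1),
                       objective = NA, converged = TRUE,
                       meta = list(n_presence = 5, n_background = 50)),
                  class = "maxent_model")
  rc1 <- response_curve(m1, "a", 30)
  expect_true(all(diff(rc1$suitability) >= 0))
  expect_error(response_curve(m1, "zz"), "unknown variable")
})

test_that("monthly projections follow the cell's SST seasonality", {
  w <- default_world()
  maps <- lapply(1:12, function(m) project(w$model_m, w$env$monthly[[m]]))
  # at a far-south cell the suitability ordering tracks the seasonal cycle:
  # warmest months (Dec-Feb) score higher than coldest (Jun-Aug)
  g <- w$env$annual$grids$sst
  cells <- which(g$mask & outer(g$lat < -65, rep(TRUE, length(g$lon))))
  summer <- sapply(c(12, 1, 2), function(m) mean(maps[[m]]$grid$values[cells]))
  winter <- sapply(6:8, function(m) mean(maps[[m]]$grid$values[cells]))
  expect_gt(min(summer), max(winter))
})
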