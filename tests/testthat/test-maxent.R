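# hinge features, L1-penalized fitting, raw/logistic outputs, contributions

test_that("hinge features hit their endpoint values and stay in [0,1]", {
  set.seed(1)
  pres <- make_sm(matrix(runif(40, 0, 10), 10, 4,
                         dimnames = list(NULL, c("sst", "salinity", "nitrate", "silicate"))))
  bg <- make_sm(matrix(runif(400, 0, 10), 100, 4,
                       dimnames = list(NULL, c("sst", "salinity", "nitrate", "silicate"))),
                "background")
  ft <- build_features(pres, bg, knots_per_variable = 30)
  expect_lte(nrow(ft), 240)
  f_all <- feature_matrix(ft, rbind(pres$x, bg$x), clamp = FALSE)
  expect_true(all(f_all >= 0 & f_all <= 1))
  # forward hinge: 0 at the knot, 1 at hi
  fwd <- ft[ft$direction == "forward", ][1, ]
  x1 <- matrix(c(fwd$knot, fwd$hi), 2, 1, dimnames = list(NULL, fwd$variable))
  x1 <- cbind(x1, sst = 0, salinity = 0, nitrate = 0, silicate = 0)[, c("sst", "salinity", "nitrate", "silicate")]
  x1[, fwd$variable] <- c(fwd$knot, fwd$hi)
  fv <- feature_matrix(fwd, x1, clamp = FALSE)
  expect_equal(as.numeric(fv), c(0, 1))
})

test_that("constant variables are skipped with a warning", {
  pres <- make_sm(cbind(sst = rep(5, 6), nitrate = 1:6))
  bg <- make_sm(cbind(sst = rep(5, 30), nitrate = runif(30, 0, 8)), "background")
  expect_warning(ft <- build_features(pres, bg, 5), "constant")
  expect_false("sst" %in% ft$variable)
  expect_true("nitrate" %in% ft$variable)
})

test_that("no-signal data yields the uniform model", {
  pres <- make_sm(cbind(sst = rep(3, 5)))
  bg <- make_sm(cbind(sst = rep(3, 20)), "background")
  model <- suppressWarnings(maxent_fit(pres, bg))
  expect_true(all(model$lambda == 0))
  raw <- predict(model, bg$x, type = "raw")
  expect_equal(raw, rep(1 / 20, 20))
  expect_equal(sum(raw), 1, tolerance = 1e-12)
})

test_that("an overwhelming beta multiplier shrinks every weight to exactly zero", {
  set.seed(2)
  pres <- make_sm(cbind(sst = rnorm(15, 2), nitrate = rnorm(15, 20, 3)))
  bg <- make_sm(cbind(sst = rnorm(200, 10, 5), nitrate = rnorm(200, 8, 6)), "background")
  model <- maxent_fit(pres, bg, beta_multiplier = 1e6, knots_per_variable = 10)
  expect_identical(unique(model$lambda), 0)
  expect_true(model$converged)
})

test_that("fitted objective matches a staged exhaustive grid search (unit case)", {
  set.seed(3)
  pres <- make_sm(cbind(v1 = rnorm(8, 3)))
  bg <- make_sm(cbind(v1 = rnorm(40, 0, 2)), "background")
  ft <- build_features(pres, bg, knots_per_variable = 2)  # 2 features
  model <- maxent_fit(pres, bg, features = ft)
  Fp <- feature_matrix(model$features, pres$x, clamp = FALSE)
  Fz <- rbind(feature_matrix(model$features, bg$x, clamp = FALSE), Fp)
  beta <- spec_betas(Fp, Fz)
  fitted_J <- maxent_objective_at(Fp, Fz, model$lambda, beta)
  oracle_J <- grid_search_objective(Fp, Fz, beta)
  expect_lte(fitted_J, oracle_J + 1e-3)
  expect_lt(abs(fitted_J - model$objective), 1e-8)   # reported objective honest
})

test_that("raw output is a distribution and rank order is monotone in eta", {
  w <- default_world()
  raw <- predict(w$model_y, w$bg_y$x, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_true(all(raw >= 0))
  # doubling lambda preserves ranking (single-feature model)
  pres <- make_sm(cbind(v1 = c(5, 6, 7)))
  bg <- make_sm(cbind(v1 = seq(0, 9, length.out = 30)), "background")
  ft <- build_features(pres, bg, 2)[1, ]
  m1 <- maxent_fit(pres, bg, features = ft)
  m2 <- m1; m2$lambda <- 2 * m1$lambda
  r1 <- predict(m1, bg$x, type = "raw"); r2 <- predict(m2, bg$x, type = "raw")
  expect_equal(order(r1), order(r2))
})

test_that("logistic link matches hand arithmetic on a 5-cell toy model", {
  ft <- data.frame(variable = "sst", knot = 2, direction = "forward",
                   lo = 0, hi = 10)
  model <- structure(list(features = ft, lambda = 1.5, beta = 0.1,
                          beta_multiplier = 1, logZ = 0.7, entropy = 1.2,
                          tau = 0.5, variables = "sst",
                          bg_means = c(sst = 5),
                          gain_trace = list(feature = 1L, gain = 0.5),
                          objective = NA, converged = TRUE,
                          meta = list(n_presence = 1, n_background = 5)),
                     class = "maxent_model")
  x <- cbind(sst = c(0, 2, 4, 8, 10))
  eta <- 1.5 * pmax(0, (x[, 1] - 2) / 8)
  q <- exp(eta - 0.7)
  want <- exp(1.2) * q / (1 + exp(1.2) * q)
  expect_equal(predict(model, x), want)
  # q = e^{-H} scores exactly 0.5 (pick H < logZ so the hinge can reach it)
  m2 <- model; m2$entropy <- 0.2
  eta_half <- m2$logZ - m2$entropy
  v_half <- 2 + 8 * eta_half / 1.5      # invert the single hinge
  expect_equal(predict(m2, cbind(sst = v_half)), 0.5)
  # out-of-range covariates clamp to the training range
  expect_equal(predict(model, cbind(sst = -50)), want[1])
  expect_equal(predict(model, cbind(sst = 99)), want[5])
})

test_that("contributions: single variable gets 100%, the true driver dominates", {
  pres <- make_sm(cbind(v1 = rnorm(10, 4)))
  bg <- make_sm(cbind(v1 = rnorm(60, 0, 2)), "background")
  m <- maxent_fit(pres, bg, knots_per_variable = 5)
  expect_equal(unname(variable_contributions(m)), 100)
  # two variables, only A drives truth; B is independent noise
  set.seed(9)
  n_bg <- 300
  A_bg <- runif(n_bg, 0, 10); B_bg <- runif(n_bg, 0, 10)
  keep <- A_bg > 6
  pres2 <- make_sm(cbind(A = A_bg[keep][1:40] + rnorm(40, 0, 0.2),
                         B = runif(40, 0, 10)))
  bg2 <- make_sm(cbind(A = A_bg, B = B_bg), "background")
  m2 <- maxent_fit(pres2, bg2, knots_per_variable = 10)
  contrib <- variable_contributions(m2)
  expect_gt(contrib["A"], contrib["B"])
  expect_equal(sum(contrib), 100, tolerance = 0.01)
})

test_that("KKT box condition holds at convergence (property over random fits)", {
  set.seed(11)
  for (rep in 1:5) {
    p <- make_sm(cbind(a = rnorm(12, 2), b = runif(12, 5, 9)))
    b <- make_sm(cbind(a = rnorm(80, 0, 2), b = runif(80, 0, 10)), "background")
    m <- maxent_fit(p, b, knots_per_variable = 6)
    Fp <- feature_matrix(m$features, p$x, clamp = FALSE)
    Fz <- rbind(feature_matrix(m$features, b$x, clamp = FALSE), Fp)
    eta <- as.numeric(Fz %*% m$lambda)
    wgt <- exp(eta - max(eta)); wgt <- wgt / sum(wgt)
    kkt <- abs(colMeans(Fp) - as.numeric(crossprod(Fz, wgt)))
    expect_true(all(kkt <= m$beta + 1e-4))
  }
})

test_that("model JSON serialization round trips predictions exactly", {
  w <- default_world()
  p <- tempfile(fileext = ".json")
  write_model(w$model_m, p)
  m2 <- read_model(p)
  x <- w$bg_m$x[1:50, ]
  expect_equal(predict(m2, x), predict(w$model_m, x), tolerance = 1e-12)
  expect_equal(variable_contributions(m2), variable_contributions(w$model_m))
  # envelope model round trip
  e <- fit_envelope(w$pres_y, "env_distance", "mahalanobis", background = w$bg_y)
  pe <- tempfile(fileext = ".json")
  write_model(e, pe)
  e2 <- read_model(pe)
  expect_equal(predict(e2, x), predict(e, x), tolerance = 1e-12)
  unlink(c(p, pe))
})
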