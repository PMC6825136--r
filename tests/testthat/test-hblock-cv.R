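test_that("h-block training indices obey the closed-ball exclusion rule", {
  meta <- data.frame(site_id = c("a", "b", "c"),
                     lon = c(25, 25, 30), lat = c(60, 60.9, 60),
                     elevation = 0)
  # h = 0: everything except the test site
  expect_equal(hblock_training_indices(meta, 1, 0), c(2L, 3L))
  # neighbour at exactly h km is excluded
  d_ab <- great_circle_km(c(25, 60), c(25, 60.9))
  expect_false(2L %in% hblock_training_indices(meta, 1, d_ab))
  expect_true(2L %in% hblock_training_indices(meta, 1, d_ab - 1e-9))
  expect_error(hblock_training_indices(meta, 1, 1e5), "no training sites")
  expect_error(hblock_training_indices(meta, 1, -1), "h must be")
})

test_that("h-block indices match a brute-force pairwise-distance oracle and nest", {
  cal <- cal_default_100()
  meta <- cal$meta[1:50, ]
  D <- great_circle_matrix(meta[, c("lon", "lat")])
  for (i in c(1, 17, 50)) {
    for (h in c(0, 150, 300)) {
      oracle <- setdiff(which(D[i, ] > h), i)
      expect_equal(hblock_training_indices(meta, i, h), oracle)
    }
    # nesting: training(h2) is a subset of training(h1) for h2 >= h1
    t300 <- hblock_training_indices(meta, i, 300)
    t150 <- hblock_training_indices(meta, i, 150)
    expect_true(all(t300 %in% t150))
  }
})

test_that("summary metrics match direct evaluation and independent oracles", {
  expect_equal(as.numeric(rmsep(c(0, 0, 0))), 0)
  expect_equal(as.numeric(rmsep(c(1, -1))), 1)
  expect_equal(as.numeric(rmsep(c(3, 4))), sqrt(12.5), tolerance = 1e-12)
  expect_equal(attr(rmsep(c(3, NA, 4)), "n_missing"), 1L)
  expect_error(rmsep(c(NA_real_, NA_real_)), "missing")

  expect_equal(r_squared(1:10, (1:10) * 2 + 3), 1)
  expect_equal(r_squared(1:10, -(1:10)), 1)
  set.seed(8)
  o <- rnorm(10); p <- rnorm(10)
  expect_equal(r_squared(o, p), cor(o, p)^2, tolerance = 1e-14)
  expect_error(r_squared(rep(1, 5), 1:5), "variance")

  # max bias: all zero, single loaded segment, and a binning oracle
  expect_equal(max_bias(rep(0, 20), seq(0, 10, length.out = 20)), 0)
  obs <- seq(0, 10, length.out = 200)
  res <- ifelse(obs < 1, 1, 0)
  expect_equal(max_bias(res, obs), 1)
  set.seed(17)
  obs <- runif(200, -3, 9); res <- rnorm(200)
  brk <- seq(min(obs), max(obs), length.out = 11)
  seg <- cut(obs, brk, include.lowest = TRUE)
  oracle <- max(abs(tapply(res, seg, mean)), na.rm = TRUE)
  expect_equal(max_bias(res, obs), oracle, tolerance = 1e-12)
  expect_error(max_bias(c(1, 2), c(5, 5)), "degenerate")
})

test_that("h = 0 cross-validation is identical to an independent leave-one-out loop", {
  cal <- cal_default_100()
  X <- cal$taxa$values
  y <- climate_response(cal, "T_jul")
  for (code in c("MAT", "WA", "WAPLS")) {
    spec <- method_spec(code)
    cv <- run_hblock_cv(cal, spec, "T_jul", h = 0)
    loo <- vapply(seq_len(nrow(X)), function(i)
      as.numeric(predict(fit_model(spec, X[-i, , drop = FALSE], y[-i]),
                         X[i, , drop = FALSE]))[1], numeric(1))
    expect_identical(cv$sites$predicted, loo)
    expect_equal(cv$sites$residual, loo - y)
  }
})

test_that("per-site h-block predictions match a per-site refit oracle", {
  cal <- cal_default_100()
  X <- cal$taxa$values
  y <- climate_response(cal, "T_jul")
  cv <- run_hblock_cv(cal, method_spec("MAT"), "T_jul", h = 200)
  for (i in c(3, 40, 77)) {
    idx <- hblock_training_indices(cal$meta, i, 200)
    fit <- fit_mat(X[idx, , drop = FALSE], y[idx])
    expect_equal(cv$sites$predicted[i],
                 as.numeric(predict(fit, X[i, , drop = FALSE])), tolerance = 1e-12)
    expect_equal(cv$sites$n_train[i], length(idx))
    d <- apply(X[idx, , drop = FALSE] / 100, 1,
               function(r) sq_chord(r, X[i, ] / 100))
    expect_equal(cv$sites$best_analog[i], min(d), tolerance = 1e-12)
  }
  # stored summaries are recomputable from the per-site records
  expect_equal(cv$summary$rmsep, as.numeric(rmsep(cv$sites$residual)))
  expect_equal(cv$summary$max_bias, max_bias(cv$sites$residual, cv$sites$observed))
  expect_equal(cv$summary$r2, r_squared(cv$sites$observed, cv$sites$predicted))
})

test_that("a dataset smaller than the exclusion radius yields only missing folds", {
  cal <- toy_cal()  # max pairwise distance well under 400 km
  expect_warning(cv <- run_hblock_cv(cal, method_spec("MAT", k = 1), "T_jul",
                                     h = 400),
                 "missing predictions")
  expect_true(all(is.na(cv$sites$predicted)))
})

test_that("CV series diagnostics are monotone in h and reduce to LOO at h = 0", {
  cal <- cal_default_100()
  spec <- cv_spec(h_grid = c(0, 200, 400, 800), methods = method_spec("MAT"),
                  response = "T_jul")
  series <- suppressWarnings(run_cv_series(cal, spec))
  s <- summary(series)
  expect_equal(nrow(s), 4)
  expect_true(all(diff(s$median_data_loss) >= 0))
  expect_true(all(diff(s$median_best_analog) >= 0))
  # h = 0 row equals a straight leave-one-out run
  loo <- run_hblock_cv(cal, method_spec("MAT"), "T_jul", h = 0)
  expect_identical(series[[1]]$sites$predicted, loo$sites$predicted)
  df <- as.data.frame(series)
  expect_equal(nrow(df), 4 * nrow(cal$meta))
  expect_error(cv_spec(h_grid = c(100, 100), methods = method_spec("MAT"),
                       response = "T_jul"), "strictly increasing")
})

test_that("the empirical variogram matches its definition", {
  # identical residuals: zero semivariance in every occupied bin
  cal <- cal_default_100()
  ev <- empirical_variogram(cal$meta, rep(2.5, 100))
  expect_true(all(ev$gamma[ev$n_pairs > 0] == 0))
  # two sites, residuals 0 and 2: single pair, gamma = 2
  coords <- data.frame(lon = c(10, 11), lat = c(50, 50))
  ev2 <- suppressWarnings(empirical_variogram(coords, c(0, 2), n_bins = 1,
                                              max_lag_km = 100))
  expect_equal(ev2$gamma[1], 2)
  expect_equal(ev2$n_pairs[1], 1L)
  # iid N(0,1) residuals: every bin near the sill of 1
  set.seed(40)
  meta <- data.frame(lon = runif(200, 0, 20), lat = runif(200, 40, 55))
  ev3 <- empirical_variogram(meta, rnorm(200))
  se <- 1 / sqrt(pmax(ev3$n_pairs, 1))
  occupied <- ev3$n_pairs > 30
  expect_true(all(abs(ev3$gamma[occupied] - 1) < 3 * 1.5 * se[occupied]))
  expect_error(empirical_variogram(coords[1, , drop = FALSE], 1), "at least 2")
})

test_that("the circular variogram fit recovers exact-model bins", {
  lags <- seq(25, 1000, by = 50)
  g <- paleotf:::circular_gamma(lags, 0.1, 0.9, 400)
  bins <- data.frame(lag = lags, gamma = g, n_pairs = 50L)
  fit <- fit_circular_variogram(bins)
  expect_equal(fit$nugget, 0.1, tolerance = 0.01)
  expect_equal(fit$partial_sill, 0.9, tolerance = 0.01)
  expect_equal(fit$range_km, 400, tolerance = 0.01 * 400)
  expect_false(fit$no_spatial_structure)
  # beyond the range the fitted curve sits exactly at the sill
  expect_equal(predict(fit, 2 * fit$range_km), fit$nugget + fit$partial_sill)
  # pure nugget: flagged, range collapses to the smallest candidate
  flat <- data.frame(lag = lags, gamma = 0.5, n_pairs = 50L)
  ffit <- fit_circular_variogram(flat, start_ranges = c(100, 400, 800))
  expect_true(ffit$no_spatial_structure)
  expect_equal(ffit$range_km, 100)
  expect_error(fit_circular_variogram(bins[1:3, ]), "at least 4")
})

test_that("estimate_best_h rounds the variogram range up to the grid", {
  cfg <- synthetic_config(n_sites = 150, prop_primary = 0, prop_secondary = 1,
                          seed = 5)
  cal <- gen_calibration(cfg)
  bh <- suppressWarnings(estimate_best_h(cal, "T_jul"))
  if (!bh$no_spatial_structure) {
    expect_equal(bh$h_km, ceiling(bh$range_km / 100) * 100)
    expect_gte(bh$h_km, bh$range_km)
  } else {
    expect_equal(bh$h_km, 0)
  }
})

test_that("spatially independent residuals give h = 0 with a structure flag", {
  # white-noise climate: zero-range planted structure
  cfg <- synthetic_config(n_sites = 150, range_km = c(5, 5), nugget = c(0.95, 0.95),
                          prop_primary = 0, prop_secondary = 1, seed = 8)
  cal <- gen_calibration(cfg)
  bh <- suppressWarnings(estimate_best_h(cal, "T_jul"))
  expect_true(bh$no_spatial_structure)
  expect_equal(bh$h_km, 0)
})
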