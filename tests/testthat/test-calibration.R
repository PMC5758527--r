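# Independent closed-form OLS oracle: direct formulas on sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

test_that("calibration fit equals the closed-form least-squares solution", {
  # noiseless line is recovered to machine precision
  x <- seq(11, 18, length.out = 20)
  cal <- fit_calibration(x, 18.207 + 0.666 * x)
  expect_equal(cal$intercept, 18.207, tolerance = 1e-10)
  expect_equal(cal$slope, 0.666, tolerance = 1e-10)
  expect_equal(cal$pearson_r, 1, tolerance = 1e-10)

  set.seed(17)
  for (i in 1:20) {
    xr <- runif(30, 5, 25); yr <- 3 + 0.5 * xr + rnorm(30)
    cal <- fit_calibration(xr, yr)
    oracle <- ols_oracle(xr, yr)
    expect_equal(cal$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
    expect_equal(cal$slope, unname(oracle["slope"]), tolerance = 1e-10)
    # F is the squared slope t, with (1, n-2) df
    expect_equal(cal$f_stat, (cal$slope / summary(cal$model)$coefficients[2, 2])^2,
                 tolerance = 1e-10)
    expect_identical(cal$df_num, 1L)
    expect_identical(cal$df_den, 28L)
    expect_equal(sign(cal$slope), sign(cal$pearson_r))
  }
  expect_error(fit_calibration(1:4, c(2, 3, 5, 8)), "n >= 5")
  expect_error(fit_calibration(rep(2, 10), rnorm(10)), "constant")
})

test_that("least-squares slope is unbiased at the study design", {
  slopes <- vapply(1:500, function(s)
    fit_calibration(simulate_sci_mst(seed = s)$mst20,
                    simulate_sci_mst(seed = s)$sci)$slope, numeric(1))
  expect_lt(abs(mean(slopes) - 0.666), 0.02)
})

test_that("published-coefficient predictions reproduce hand arithmetic", {
  eq1 <- calibration_from_coef(18.207, 0.666, "MST20", "SCI")
  eq2 <- calibration_from_coef(632.846, -19.122, "SCI", "A_max")
  expect_equal(predict(eq1, 15), 28.197)
  expect_equal(predict(eq2, 28.197), 93.66, tolerance = 1e-3)
  expect_equal(predict(eq2, 30.04), 58.42, tolerance = 1e-2)
})

test_that("parameter recovery at paper sample sizes has < 1% bias", {
  fits1 <- t(vapply(1:500, function(s) {
    d <- simulate_sci_mst(n = 49, seed = s)
    cal <- fit_calibration(d$mst20, d$sci)
    c(cal$intercept, cal$slope)
  }, numeric(2)))
  expect_lt(abs(mean(fits1[, 1]) / 18.207 - 1), 0.01)
  expect_lt(abs(mean(fits1[, 2]) / 0.666 - 1), 0.01)

  fits2 <- t(vapply(1:500, function(s) {
    d <- simulate_age_sci(n = 30, seed = s)
    cal <- fit_calibration(d$sci, d$a_max)
    c(cal$intercept, cal$slope)
  }, numeric(2)))
  expect_lt(abs(mean(fits2[, 1]) / 632.846 - 1), 0.01)
  expect_lt(abs(mean(fits2[, 2]) / -19.122 - 1), 0.01)
})

test_that("summer temperature ranks first among noisy proxy predictors", {
  set.seed(23)
  first <- vapply(1:200, function(i) {
    mst <- runif(49, 11, 18)
    sci <- 18.207 + 0.666 * mst + rnorm(49, 0, 1.1)
    proxies <- data.frame(mst_20 = mst,
                          annual = mst - 6 + rnorm(49, 0, 1.5),
                          spring = mst - 8 + rnorm(49, 0, 2),
                          winter = -mst / 2 + rnorm(49, 0, 3),
                          ets_5 = 100 * mst + rnorm(49, 0, 250))
    compare_predictors(proxies, sci)$variable[1] == "mst_20"
  }, logical(1))
  expect_gte(mean(first), 0.95)

  expect_warning(
    r <- compare_predictors(data.frame(a = 1:10 / 2, b = rep(1, 10)),
                            (1:10) + 0.1),
    "excluded")
  expect_identical(r$variable, "a")
})

test_that("MST window length barely changes the fitted coefficients", {
  # slow-varying synthetic climate: 20- to 50-year windows give similar slopes
  spec <- world_spec(seed = 31, climate = list(interannual_sd = 0.2),
                     lon_range = c(5, 12))
  g <- generate_climate(spec)
  w <- generate_populations(spec, g)
  rec <- w$populations[w$populations$period == "recent", ]
  pops <- aggregate_populations(filter_shells(w$shells))
  pops <- pops[match(rec$population_id, pops$population_id), ]
  slopes <- vapply(c(20, 30, 40, 50), function(k) {
    mst <- vapply(seq_len(nrow(rec)), function(i) {
      cell <- locate_cell(g, rec$lat[i], rec$lon[i])
      as.numeric(mst_window(g, cell, rec$year[i], k))
    }, numeric(1))
    fit_calibration(mst, pops$mean_sci)$slope
  }, numeric(1))
  expect_lt(max(slopes) / min(slopes) - 1, 0.10)
})

test_that("cross-validation accuracy measures match hand arithmetic", {
  obs <- c(10, 20); pred <- c(9, 22)
  expect_equal(musselclim:::mape(obs, pred), 10.0)
  expect_equal(musselclim:::minmax_accuracy(obs, pred), 0.90455, tolerance = 1e-4)
  expect_equal(musselclim:::tofallis_measure(obs, pred), 0.10034, tolerance = 1e-4)

  # perfect linear data: held-out predictions are exact
  x <- seq(1, 10); y <- 2 + 3 * x
  cv <- kfold_cv(x, y, k = 5, seed = 2)
  expect_equal(cv$mape, 0, tolerance = 1e-10)
  expect_equal(cv$tofallis, 0, tolerance = 1e-10)
  expect_equal(cv$minmax, 1, tolerance = 1e-10)
  expect_error(kfold_cv(x, y - 10, k = 5), "positive")
  expect_error(kfold_cv(1:3, 1:3, k = 4), "n >= k")
})

test_that("leave-one-out cross-validation is partition-independent", {
  d <- simulate_sci_mst(n = 20, seed = 9)
  a <- kfold_cv(d$mst20, d$sci, k = 20, seed = 1)
  b <- kfold_cv(d$mst20, d$sci, k = 20, seed = 999)
  expect_equal(a$mape, b$mape, tolerance = 1e-12)
  expect_equal(sort(a$predictions), sort(b$predictions), tolerance = 1e-12)
})

test_that("fold sizes differ by at most one and cover all points", {
  for (n in c(11, 49, 50)) {
    d <- simulate_sci_mst(n = n, seed = n)
    cv <- kfold_cv(d$mst20, d$sci, k = 5, seed = 4)
    expect_equal(sum(cv$folds$n_test), n)
    expect_lte(diff(range(cv$folds$n_test)), 1)
  }
})

test_that("Moran's I has expectation -1/(n-1) and detects latitudinal structure", {
  set.seed(41)
  for (n in c(5, 20, 49)) {
    m <- morans_i(rnorm(n), runif(n, 45, 70), runif(n, 5, 40))
    expect_equal(m$expected_i, -1 / (n - 1))
  }
  # values equal to latitude: strong positive autocorrelation
  lat <- runif(50, 45, 70); lon <- runif(50, 5, 40)
  m <- morans_i(lat, lat, lon)
  expect_gt(m$observed_i, m$expected_i)
  expect_gt(m$z_score, 1.96)

  expect_warning(morans_i(rnorm(6), c(60, 60, rep(61:64, 1)),
                          c(30, 30, rep(31, 4))), "capped")
  expect_error(morans_i(rnorm(3), 1:3, 1:3), "n >= 5")
})

test_that("Moran z-scores are calibrated on spatially independent data", {
  set.seed(43)
  z <- vapply(1:500, function(i)
    morans_i(rnorm(50), runif(50, 45, 70), runif(50, 5, 40))$z_score,
    numeric(1))
  cover <- mean(abs(z) <= 1.96)
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)
})

test_that("outlier handling supports explicit lists and studentized flags", {
  x <- seq(11, 18, length.out = 49)
  y <- 18.207 + 0.666 * x
  ids <- sprintf("s%02d", 1:49)
  y[c(10, 25, 40)] <- y[c(10, 25, 40)] + 5  # three displaced samples
  fl <- flag_outliers(x, y, ids)
  expect_setequal(fl$flagged_ids, ids[c(10, 25, 40)])
  expect_equal(nrow(fl$retained), 49)  # flagged but not excluded by default

  fl_auto <- flag_outliers(x, y, ids, auto = TRUE)
  expect_equal(nrow(fl_auto$retained), 46)

  # bounded smooth deviations: nothing crosses the studentized threshold
  clean <- flag_outliers(x, 18.207 + 0.666 * x + 0.1 * sin(1:49), ids)
  expect_length(clean$flagged_ids, 0)

  six <- ids[c(1, 2, 3, 30, 31, 32)]
  fl_list <- flag_outliers(x, y, ids, exclude_ids = six)
  expect_setequal(fl_list$excluded_ids, six)
  expect_equal(nrow(fl_list$retained), 43)
})
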