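test_that("convexity indices follow their defining formulas and identities", {
  expect_equal(shell_sci(100, 30), 30)
  expect_equal(shell_sci(104.5, 31.2), 29.8565, tolerance = 1e-4)
  expect_equal(shell_sci_integrated(100, 50, 30),
               30 / sqrt(pi * 100 * 50) * 100, tolerance = 1e-12)
  expect_equal(shell_sci_integrated(100, 50, 30), 23.937, tolerance = 1e-3)
  # cube-like shell: L = H = W gives 100/sqrt(pi)
  expect_equal(shell_sci_integrated(80, 80, 80), 100 / sqrt(pi))
  expect_error(shell_sci(0, 10), "positive")
  expect_error(shell_sci_integrated(100, -1, 10), "positive")

  # scale invariance and the SCI_I/SCI identity, across random shells
  set.seed(42)
  for (i in 1:25) {
    L <- runif(1, 60, 140); H <- runif(1, 0.4, 0.6) * L
    W <- runif(1, 0.2, 0.35) * L; c <- runif(1, 0.1, 10)
    expect_equal(shell_sci(c * L, c * W), shell_sci(L, W))
    expect_equal(shell_sci_integrated(c * L, c * H, c * W),
                 shell_sci_integrated(L, H, W))
    expect_equal(shell_sci_integrated(L, H, W),
                 shell_sci(L, W) * sqrt(L / (pi * H)), tolerance = 1e-12)
  }
})

test_that("the shell-length filter excludes below 50 mm, boundary inclusive", {
  sh <- shells_with_sci(c(28, 29, 30))
  sh$length_mm <- c(45, 50, 120)
  sh$width_mm <- sh$length_mm * 0.29
  expect_message(out <- filter_shells(sh), "removed 1")
  expect_equal(out$length_mm, c(50, 120))
  expect_silent(expect_identical(filter_shells(out), out))
  sh$length_mm <- c(30, 40, 49.9)
  sh$height_mm <- 15
  sh$width_mm <- 10
  expect_warning(suppressMessages(empty <- filter_shells(sh)), "no shells")
  expect_equal(nrow(empty), 0)
})

test_that("population aggregation averages per-shell indices, not the mean shell", {
  pops <- aggregate_populations(shells_with_sci(c(28, 30)))
  expect_equal(pops$mean_sci, 29)
  expect_equal(pops$sem_sci, 1)

  single <- suppressMessages(aggregate_populations(shells_with_sci(27)))
  expect_equal(single$mean_sci, 27)
  expect_true(is.na(single$sem_sci))

  many <- aggregate_populations(shells_with_sci(rep(27, 25)))
  expect_equal(many$mean_sci, 27)
  expect_equal(many$sem_sci, 0)

  # non-proportional shells: mean of per-shell SCI differs from the SCI of
  # the mean shell; the former must be reported
  sh <- shells_with_sci(c(20, 40))
  sh$length_mm <- c(60, 120)
  sh$width_mm <- c(60 * 0.20, 120 * 0.35)
  p <- aggregate_populations(sh)
  per_shell_mean <- mean(c(20, 35))
  of_mean_shell <- 100 * mean(sh$width_mm) / mean(sh$length_mm)
  expect_equal(p$mean_sci, per_shell_mean)
  expect_false(isTRUE(all.equal(p$mean_sci, of_mean_shell)))

  # sub-minimum samples are flagged
  expect_message(
    flagged <- aggregate_populations(shells_with_sci(rep(28, 6), year = 2000)),
    "below minimum")
  expect_true(flagged$excluded)
})

test_that("group comparison is a pooled-variance Student t-test", {
  set.seed(7)
  for (sizes in list(c(21, 24), c(5, 9), c(12, 30))) {
    r <- compare_group_means(rnorm(sizes[1], 28), rnorm(sizes[2], 29))
    expect_equal(r$df, sizes[1] + sizes[2] - 2)
  }
  same <- c(27.5, 28.2, 28.9, 29.4)
  r0 <- compare_group_means(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(compare_group_means(1:5, 3), "insufficient")

  # power at the separation typical of viable vs declining group means
  hits <- sum(vapply(1:500, function(i) {
    compare_group_means(rnorm(20, 28.0, 0.5), rnorm(20, 29.5, 0.5))$p < 0.001
  }, logical(1)))
  expect_gte(hits, 495)
})

test_that("Lilliefors check accepts normal and rejects exponential data", {
  set.seed(11)
  p_norm <- vapply(1:100, function(i)
    normality_check(rnorm(500), nsim = 400)$p, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- vapply(1:100, function(i)
    normality_check(rexp(500), nsim = 400)$p, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(normality_check(c(1, 2, 3)), "n >= 4")
  expect_error(normality_check(rep(5, 10)), "constant")
})

test_that("Lilliefors statistic agrees with the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(80)
    expect_equal(normality_check(x, nsim = 100)$statistic,
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-10)
  }
})

make_width_pops <- function(n_per_group, slope_v, slope_d, noise_sd,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- runif(2 * n_per_group, 60, 110)
  grp <- rep(c("viable", "declining"), each = n_per_group)
  slope <- ifelse(grp == "viable", slope_v, slope_d)
  data.frame(mean_length_mm = len,
             mean_width_mm = slope * len + rnorm(2 * n_per_group, 0, noise_sd),
             status = grp, stringsAsFactors = FALSE)
}

test_that("width GLM simplifies to the minimal adequate model", {
  # identical groups: only length survives
  g1 <- fit_width_glm(make_width_pops(12, 0.28, 0.28, 0.3, seed = 1))
  expect_identical(g1$retained_terms, "length")
  expect_gt(g1$r_squared, 0.9)

  # genuinely different relative width: status signal retained
  g2 <- fit_width_glm(make_width_pops(12, 0.28, 0.30, 0.05, seed = 2))
  expect_true(any(c("group", "length:group") %in% g2$retained_terms))
  p_grp <- g2$terms$p[g2$terms$term %in% c("group", "length:group")]
  expect_lt(min(p_grp), 0.001)

  expect_error(fit_width_glm(make_width_pops(2, 0.28, 0.28, 0.1, seed = 3)),
               "at least 3")
})

test_that("width GLM keeps only length in >= 90% of no-effect replicates", {
  set.seed(99)
  only_length <- vapply(1:200, function(i) {
    g <- fit_width_glm(make_width_pops(10, 0.28, 0.28, 0.4))
    identical(g$retained_terms, "length")
  }, logical(1))
  expect_gte(mean(only_length), 0.90)
})

test_that("separate-slopes model compares period-specific lines with 2 df", {
  sim_pops <- function(slope_recent, slope_hist, noise_sd = 0.8) {
    lat <- c(runif(25, 45, 70), runif(12, 45, 70))
    period <- rep(c("recent", "historical"), c(25, 12))
    slope <- ifelse(period == "recent", slope_recent, slope_hist)
    data.frame(mean_sci = 30 + slope * (lat - 57) + rnorm(37, 0, noise_sd),
               lat = lat, period = period, stringsAsFactors = FALSE)
  }
  set.seed(5)
  r <- separate_slopes_test(sim_pops(-0.35, 0))
  expect_identical(r$df_num, 2L)

  # null: both periods on one common line -> p uniform on (0, 1)
  p_null <- vapply(1:500, function(i)
    separate_slopes_test(sim_pops(0, 0))$p, numeric(1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)

  # power at the latitudinal divergence seen between periods
  p_alt <- vapply(1:200, function(i)
    separate_slopes_test(sim_pops(-0.35, 0))$p, numeric(1))
  expect_gte(mean(p_alt < 0.01), 0.95)

  bad <- sim_pops(0, 0); bad$lat[3] <- NA
  expect_error(separate_slopes_test(bad), "latitude")
})

test_that("rank and Pearson correlations behave on monotone, null and constant input", {
  x <- c(2, 5, 1, 9, 4, 7)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_error(rank_correlation(x, rep(1, 6)), "constant")
  expect_error(pearson_correlation(1:4, 1:4), "n >= 5")
  set.seed(21)
  small <- vapply(1:500, function(i)
    abs(rank_correlation(rnorm(100), rnorm(100))$rho) < 0.3, logical(1))
  expect_gte(mean(small), 0.99)
})

test_that("shell table validation enforces the measurement invariants", {
  sh <- shells_with_sci(c(28, 29))
  expect_identical(validate_shells(sh), sh)
  bad <- sh; bad$width_mm[1] <- 120  # wider than long
  expect_error(validate_shells(bad), "invalid measurement")
  bad2 <- sh; bad2$height_mm[2] <- 150  # taller than long
  expect_error(validate_shells(bad2), "invalid measurement")
  expect_error(validate_shells(sh[, -3]), "missing columns")
})
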