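#' Specification of a synthetic study world
#'
#' Bundles every parameter of the synthetic-data generators: a gridded
#' monthly temperature field with a latitudinal gradient and a
#' 20th-century warming trend, shell populations whose mean convexity
#' tracks the 20-year mean summer temperature through the fitted
#' calibration line, and von Bertalanffay ring series whose growth
#' constant increases with temperature. All randomness flows from `seed`;
#' identical specs produce identical outputs.
#'
#' Defaults emulate the structure of the continental shell dataset:
#' 49 recent populations (plus 13 historical museum samples), a
#' latitudinal summer-temperature span giving site MST20 values roughly
#' between 11 and 18 degrees C, population-level SCI noise of sd 1.1
#' (which yields a Pearson r near 0.76 at n = 49), shell length around
#' 80 +/- 10 mm so essentially nothing falls under the 50-mm filter, a
#' height/length ratio of 0.5 +/- 0.03, and ring series of at least 16
#' annual rings.
#'
#' @param seed Integer root seed.
#' @param n_populations Number of recent populations (default 49).
#' @param n_historical Number of historical samples (default 13).
#' @param lat_range,lon_range Extent of the grid in degrees.
#' @param years First and last grid year.
#' @param resolution Grid resolution in degrees (default 0.5).
#' @param climate List: `mst_ref` (summer mean at the southern edge, deg
#'   C), `lapse` (deg C decrease per degree latitude), `trend_per_decade`
#'   (warming, deg C/decade), `interannual_sd` (year-level noise, deg C),
#'   `seasonal_amplitude` (annual cycle half-range, deg C).
#' @param shells List: `n_per_pop`, `n_per_pop_historical`, `mean_length`,
#'   `length_sd` (mm, lognormal), `hl_ratio`, `hl_sd`, `sci_noise_sd`
#'   (population-level, SCI units), `shell_cv` (per-shell multiplicative
#'   width noise).
#' @param sci_cal List `intercept`, `slope`: the generative SCI-vs-MST20
#'   line (defaults to the fitted calibration 18.207 + 0.666 x MST20).
#' @param status_thresholds `c(viable = , declining = )`: true-mean-SCI
#'   cutoffs used to label population status.
#' @param growth List: `n_growth_pops`, `n_shells` per population,
#'   `n_rings`, `l_inf_range` (mm), `k0`, `k1` (growth constant
#'   `K = k0 + k1 * MST20`), `k_sd`, `length_noise_sd` (mm).
#' @return List of class `world_spec`.
#' @export
world_spec <- function(seed = 1,
                       n_populations = 49,
                       n_historical = 13,
                       lat_range = c(45, 70),
                       lon_range = c(5, 40),
                       years = c(1901, 2013),
                       resolution = 0.5,
                       climate = list(),
                       shells = list(),
                       sci_cal = list(intercept = 18.207, slope = 0.666),
                       status_thresholds = c(viable = 28.37, declining = 30.04),
                       growth = list()) {
  climate <- utils::modifyList(
    list(mst_ref = 18, lapse = 0.28, trend_per_decade = 0.1,
         interannual_sd = 0.5, seasonal_amplitude = 9), climate)
  shells <- utils::modifyList(
    list(n_per_pop = 30, n_per_pop_historical = 8, mean_length = 80,
         length_sd = 10, hl_ratio = 0.5, hl_sd = 0.03, sci_noise_sd = 1.1,
         shell_cv = 0.05), shells)
  growth <- utils::modifyList(
    list(n_growth_pops = 9, n_shells = 5, n_rings = 20,
         l_inf_range = c(90, 140), k0 = -0.02, k1 = 0.008, k_sd = 0.01,
         length_noise_sd = 0.3), growth)
  stopifnot(climate$interannual_sd >= 0, shells$sci_noise_sd >= 0,
            shells$shell_cv >= 0, growth$k_sd >= 0)
  structure(list(seed = as.integer(seed), n_populations = n_populations,
                 n_historical = n_historical, lat_range = lat_range,
                 lon_range = lon_range, years = years,
                 resolution = resolution, climate = climate,
                 shells = shells, sci_cal = sci_cal,
                 status_thresholds = status_thresholds, growth = growth),
            class = "world_spec")
}

# Deterministic summer-temperature level at (lat, year): the latitudinal
# profile plus the linear warming trend, before interannual noise.
summer_level <- function(spec, lat, year) {
  spec$climate$mst_ref - spec$climate$lapse * (lat - spec$lat_range[1]) +
    spec$climate$trend_per_decade * (year - spec$years[1]) / 10
}

#' Generate a synthetic monthly climate grid
#'
#' Monthly temperature = annual sinusoid (peak in July) around a mean
#' that decreases with latitude and warms linearly in time, plus a
#' year-level Gaussian noise term shared by all 12 months of a cell-year
#' (so the interannual sd applies directly to seasonal means). The
#' sinusoid is anchored so that the June-August mean equals the
#' deterministic summer level exactly when the noise sd is zero.
#'
#' @param spec A [world_spec()].
#' @return A [climate_grid()].
#' @export
generate_climate <- function(spec) {
  res <- spec$resolution
  lat <- seq(spec$lat_range[1] + res / 2, spec$lat_range[2] - res / 2, by = res)
  lon <- seq(spec$lon_range[1] + res / 2, spec$lon_range[2] - res / 2, by = res)
  years <- seq(spec$years[1], spec$years[2])
  nlat <- length(lat); nlon <- length(lon); nyr <- length(years)
  amp <- spec$climate$seasonal_amplitude
  # JJA mean of cos(2*pi*(m - 7)/12) over m = 6, 7, 8 is (1 + sqrt(3))/3
  month_effect <- amp * cos(2 * pi * ((1:12) - 7) / 12) - amp * (1 + sqrt(3)) / 3
  s_laty <- outer(lat, years, function(la, yr) summer_level(spec, la, yr))
  base <- aperm(array(s_laty, c(nlat, nyr, nlon)), c(1, 3, 2))
  eps <- local_seed(spec$seed, {
    array(stats::rnorm(nlat * nlon * nyr, sd = spec$climate$interannual_sd),
          c(nlat, nlon, nyr))
  })
  temp <- array(NA_real_, c(nlat, nlon, nyr, 12))
  for (m in 1:12) temp[, , , m] <- base + eps + month_effect[m]
  climate_grid(lat, lon, years, temp, res = res)
}

#' Generate synthetic shell populations over a climate grid
#'
#' Each population occupies its own grid cell (at most one population per
#' cell, keeping Moran's I well-defined). Its true mean SCI is the
#' generative calibration line evaluated at the site's MST20 plus
#' Normal(0, `sci_noise_sd`) population noise. Per-shell measurements are
#' drawn as: length lognormal; height = `hl_ratio` x length x (1 + eps);
#' width = trueSCI/100 x length x (1 + eps'), so the per-shell SCI is an
#' unbiased noisy copy of the population target. Recent populations are
#' labelled viable or declining by comparing their true mean SCI against
#' the spec's status thresholds; historical populations are drawn with
#' collection years in the early span (their temperature windows may
#' predate the grid, as for real museum samples).
#'
#' @param spec A [world_spec()].
#' @param grid The matching [generate_climate()] output.
#' @return List with `shells` (one row per shell, the shell-table CSV
#'   layout) and `populations` (one row per population, including the
#'   latent `true_sci` and the site `mst20`).
#' @export
generate_populations <- function(spec, grid) {
  local_seed(spec$seed + 1L, {
    n_rec <- spec$n_populations
    n_hist <- spec$n_historical
    n <- n_rec + n_hist
    ncell <- length(grid$lat) * length(grid$lon)
    if (n > ncell) stop("more populations than grid cells")
    cells <- sample.int(ncell, n)
    rows <- ((cells - 1) %% length(grid$lat)) + 1
    cols <- ((cells - 1) %/% length(grid$lat)) + 1
    yend <- spec$years[2]
    year_col <- c(sample(seq(yend - 29, yend), n_rec, replace = TRUE),
                  sample(seq(1905, 1940), n_hist, replace = TRUE))
    period <- rep(c("recent", "historical"), c(n_rec, n_hist))
    pops <- lapply(seq_len(n), function(i) {
      cell <- c(rows[i], cols[i])
      lat <- grid$lat[rows[i]]; lon <- grid$lon[cols[i]]
      mst <- as.numeric(mst_window(grid, cell, year_col[i], 20))
      # museum samples may predate the grid; fall back to the noise-free
      # summer level at the window midpoint
      mst_eff <- if (is.na(mst)) summer_level(spec, lat, year_col[i] - 10) else mst
      true_sci <- spec$sci_cal$intercept + spec$sci_cal$slope * mst_eff +
        stats::rnorm(1, sd = spec$shells$sci_noise_sd)
      status <- if (period[i] == "historical") "historical"
      else if (true_sci <= spec$status_thresholds[["viable"]]) "viable"
      else "declining"
      n_sh <- if (period[i] == "historical") spec$shells$n_per_pop_historical
      else spec$shells$n_per_pop
      sdlog <- sqrt(log(1 + (spec$shells$length_sd / spec$shells$mean_length)^2))
      meanlog <- log(spec$shells$mean_length) - sdlog^2 / 2
      L <- stats::rlnorm(n_sh, meanlog, sdlog)
      H <- spec$shells$hl_ratio * L *
        (1 + stats::rnorm(n_sh, sd = spec$shells$hl_sd))
      W <- true_sci / 100 * L * (1 + stats::rnorm(n_sh, sd = spec$shells$shell_cv))
      pid <- sprintf("pop%02d", i)
      list(shells = data.frame(
        shell_id = sprintf("%s_s%03d", pid, seq_len(n_sh)),
        population_id = pid, length_mm = L, height_mm = H, width_mm = W,
        year = year_col[i], lat = lat, lon = lon,
        altitude_m = stats::runif(1, 0, 150), status = status,
        stringsAsFactors = FALSE),
        pop = data.frame(population_id = pid, n_shells = n_sh,
                         true_sci = true_sci, mst20 = mst, status = status,
                         period = period[i], lat = lat, lon = lon,
                         year = year_col[i], stringsAsFactors = FALSE))
    })
    shells <- do.call(rbind, lapply(pops, `[[`, "shells"))
    populations <- do.call(rbind, lapply(pops, `[[`, "pop"))
    rownames(shells) <- rownames(populations) <- NULL
    validate_shells(shells)
    list(shells = shells, populations = populations)
  })
}

#' Generate synthetic von Bertalanffy ring series
#'
#' For the first `n_growth_pops` recent populations, draws `n_shells`
#' ring series per population with growth constant
#' `K = k0 + k1 * MST20 + Normal(0, k_sd)` and asymptotic length uniform
#' in `l_inf_range`. Measurement noise acts on the annual increments and
#' is floored so the cumulative series stays strictly increasing; every
#' series has at least 16 rings.
#'
#' @param spec A [world_spec()].
#' @param populations The `populations` table from
#'   [generate_populations()].
#' @return List with `rings` (long data frame: `shell_id, population_id,
#'   ring_index, cumulative_length_mm`) and `true_k` (per-population mean
#'   of the drawn growth constants).
#' @export
generate_growth <- function(spec, populations) {
  local_seed(spec$seed + 2L, {
    g <- spec$growth
    rec <- populations[populations$period == "recent" &
                         !is.na(populations$mst20), , drop = FALSE]
    if (nrow(rec) < g$n_growth_pops) stop("not enough recent populations with climate coverage")
    rec <- rec[seq_len(g$n_growth_pops), , drop = FALSE]
    n_rings <- max(16L, g$n_rings)
    out <- lapply(seq_len(nrow(rec)), function(i) {
      ks <- pmax(g$k0 + g$k1 * rec$mst20[i] +
                   stats::rnorm(g$n_shells, sd = g$k_sd), 0.01)
      series <- lapply(seq_len(g$n_shells), function(j) {
        l_inf <- stats::runif(1, g$l_inf_range[1], g$l_inf_range[2])
        ideal <- l_inf * (1 - exp(-ks[j] * seq_len(n_rings)))
        inc <- pmax(diff(c(0, ideal)) +
                      stats::rnorm(n_rings, sd = g$length_noise_sd), 0.05)
        data.frame(shell_id = sprintf("%s_g%d", rec$population_id[i], j),
                   population_id = rec$population_id[i],
                   ring_index = seq_len(n_rings),
                   cumulative_length_mm = cumsum(inc),
                   stringsAsFactors = FALSE)
      })
      list(rings = do.call(rbind, series), k = mean(ks))
    })
    list(rings = do.call(rbind, lapply(out, `[[`, "rings")),
         true_k = data.frame(population_id = rec$population_id,
                             mean_k = vapply(out, `[[`, numeric(1), "k"),
                             mst20 = rec$mst20,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate desk-scale SCI vs MST20 calibration data
#'
#' Draws `n` sites with MST20 uniform on `mst_range` and mean SCI from
#' the calibration line plus Normal(0, `noise_sd`) noise — the design
#' used for parameter-recovery and cross-validation experiments. The
#' default noise sd of 1.1 SCI units reproduces a Pearson r near 0.76 at
#' n = 49.
#'
#' @param n Number of sites (default 49).
#' @param seed Integer seed.
#' @param intercept,slope Generative line (defaults 18.207, 0.666).
#' @param mst_range MST20 range in degrees C (default `c(11, 18)`).
#' @param noise_sd Site-level noise sd in SCI units (default 1.1).
#' @return Data frame `mst20, sci`.
#' @export
simulate_sci_mst <- function(n = 49, seed = 1, intercept = 18.207,
                             slope = 0.666, mst_range = c(11, 18),
                             noise_sd = 1.1) {
  local_seed(seed, {
    mst <- stats::runif(n, mst_range[1], mst_range[2])
    data.frame(mst20 = mst,
               sci = intercept + slope * mst + stats::rnorm(n, sd = noise_sd))
  })
}

#' Simulate desk-scale maximum-age vs SCI calibration data
#'
#' Draws `n` populations with mean SCI uniform on `sci_range` and maximum
#' age from the age calibration line plus Normal(0, `noise_sd`) noise.
#' The default noise sd of 29 years reproduces a Pearson r near -0.80 at
#' n = 30.
#'
#' @param n Number of populations (default 30).
#' @param seed Integer seed.
#' @param intercept,slope Generative line (defaults 632.846, -19.122).
#' @param sci_range Mean SCI range (default `c(24, 31)`).
#' @param noise_sd Noise sd in years (default 29).
#' @return Data frame `sci, a_max`.
#' @export
simulate_age_sci <- function(n = 30, seed = 1, intercept = 632.846,
                             slope = -19.122, sci_range = c(24, 31),
                             noise_sd = 29) {
  local_seed(seed, {
    sci <- stats::runif(n, sci_range[1], sci_range[2])
    data.frame(sci = sci,
               a_max = intercept + slope * sci + stats::rnorm(n, sd = noise_sd))
  })
}
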