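# Shared fixture builders: tiny climate grids and shell tables built in code.

# Grid with one cell, constant temperature everywhere.
constant_grid <- function(tc = 14, years = 1950:2010, lat = 60.25, lon = 30.25) {
  temp <- array(tc, c(length(lat), length(lon), length(years), 12))
  climate_grid(lat, lon, years, temp)
}

# Grid with a fixed per-month profile repeated every year.
monthly_grid <- function(profile, years = 1950:2010, lat = 60.25, lon = 30.25) {
  stopifnot(length(profile) == 12)
  temp <- array(rep(profile, each = length(lat) * length(lon) * length(years)),
                c(length(lat), length(lon), length(years), 12))
  climate_grid(lat, lon, years, temp)
}

# Grid warming linearly: all months = base + rate * (year - years[1]).
trend_grid <- function(base = 10, rate = 0.02, years = 1900:2012,
                       lat = 60.25, lon = 30.25) {
  temp <- array(NA_real_, c(length(lat), length(lon), length(years), 12))
  for (i in seq_along(years)) {
    temp[, , i, ] <- base + rate * (years[i] - years[1])
  }
  climate_grid(lat, lon, years, temp)
}

# Shell table with prescribed per-shell SCI values (L = 100, W = sci).
shells_with_sci <- function(sci, population_id = "p1", year = 2000,
                            lat = 60, lon = 30, status = "viable") {
  data.frame(shell_id = paste0(population_id, "_", seq_along(sci)),
             population_id = population_id, length_mm = 100,
             height_mm = 50, width_mm = sci, year = year, lat = lat,
             lon = lon, altitude_m = 100, status = status,
             stringsAsFactors = FALSE)
}

# Exact von Bertalanffy ring series.
bertalanffy_series <- function(k, l_inf, n_rings = 20) {
  l_inf * (1 - exp(-k * seq_len(n_rings)))
}

# A fast small synthetic world for pipeline-level tests.
small_world_spec <- function(seed = 1, ...) {
  world_spec(seed = seed, lat_range = c(55, 65), lon_range = c(5, 10),
             n_populations = 30, n_historical = 8,
             shells = list(n_per_pop = 15, n_per_pop_historical = 6), ...)
}
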