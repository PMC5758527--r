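#' @importFrom stats sd
NULL

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
SUMMER_MONTHS <- 6:8   # boreal June-August

#' Construct a regular monthly temperature grid
#'
#' A `climate_grid` holds monthly mean air temperature (degrees C) on a
#' regular lat/lon grid of cell centers, for a contiguous span of years.
#' This mirrors CRU TS-style 0.5 degree monthly series.
#'
#' @param lat,lon Ascending vectors of cell-center coordinates (degrees).
#' @param years Contiguous integer years covered.
#' @param temp 4-d array `[lat, lon, year, month]` of monthly mean
#'   temperature in degrees C; `NA` marks missing cells/months.
#' @param res Grid resolution in degrees (default 0.5).
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lat, lon, years, temp, res = 0.5) {
  stopifnot(length(dim(temp)) == 4,
            dim(temp)[1] == length(lat), dim(temp)[2] == length(lon),
            dim(temp)[3] == length(years), dim(temp)[4] == 12)
  if (any(diff(years) != 1)) stop("years must be contiguous")
  rng <- range(temp, na.rm = TRUE)
  if (rng[1] < -60 || rng[2] > 60) {
    stop("temperatures outside plausible range [-60, 60] degrees C")
  }
  structure(list(lat = lat, lon = lon, years = as.integer(years),
                 temp = temp, res = res),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid: %d x %d cells (%.2f deg), years %d-%d\n",
              length(x$lat), length(x$lon), x$res,
              min(x$years), max(x$years)))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f, %.1f%% missing\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              100 * mean(is.na(x$temp))))
  invisible(x)
}

#' Read a long-format monthly climate CSV
#'
#' Columns: `year, month, lat_center, lon_center, tmean_c`. Cells present
#' in the file define the grid; (cell, year, month) combinations absent
#' from the file are missing (`NA`). An optional `scenario` column is
#' carried through as an attribute.
#'
#' @param path CSV path.
#' @param res Grid resolution in degrees (default 0.5).
#' @return A [climate_grid()].
#' @export
read_climate_csv <- function(path, res = 0.5) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("year", "month", "lat_center", "lon_center", "tmean_c")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("climate CSV ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (any(x$month < 1 | x$month > 12)) {
    stop("climate CSV ", path, ": month outside 1..12")
  }
  lat <- sort(unique(x$lat_center))
  lon <- sort(unique(x$lon_center))
  years <- seq(min(x$year), max(x$year))
  temp <- array(NA_real_, c(length(lat), length(lon), length(years), 12))
  idx <- cbind(match(x$lat_center, lat), match(x$lon_center, lon),
               match(x$year, years), x$month)
  temp[idx] <- x$tmean_c
  g <- climate_grid(lat, lon, years, temp, res = res)
  if ("scenario" %in% names(x)) attr(g, "scenario") <- x$scenario[1]
  g
}

#' Write a climate grid as long-format CSV
#'
#' @param grid A [climate_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(grid, path) {
  d <- expand.grid(lat_center = grid$lat, lon_center = grid$lon,
                   year = grid$years, month = 1:12,
                   KEEP.OUT.ATTRS = FALSE)
  d$tmean_c <- as.vector(grid$temp)
  d <- d[!is.na(d$tmean_c), c("year", "month", "lat_center", "lon_center",
                              "tmean_c")]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Locate the grid cell containing a point
#'
#' Cell bounds are half-open, `[south, north) x [west, east)`: a point on
#' a boundary belongs to the cell north/east of the edge.
#'
#' @param grid A [climate_grid()].
#' @param lat,lon Point coordinates in decimal degrees.
#' @return Integer vector `c(row, col)` indexing `grid$lat` / `grid$lon`.
#' @export
locate_cell <- function(grid, lat, lon) {
  south <- grid$lat[1] - grid$res / 2
  west <- grid$lon[1] - grid$res / 2
  row <- floor((lat - south) / grid$res) + 1
  col <- floor((lon - west) / grid$res) + 1
  if (row < 1 || row > length(grid$lat) || col < 1 || col > length(grid$lon)) {
    stop(sprintf("location error: point (%.3f, %.3f) outside grid bounds",
                 lat, lon))
  }
  c(row = row, col = col)
}

# Missing-value result carrying the reason; consumed by site_climate etc.
missing_value <- function(reason) {
  structure(NA_real_, reason = reason)
}

window_years <- function(grid, collection_year, k) {
  yrs <- seq(collection_year - k, collection_year - 1)
  if (!all(yrs %in% grid$years)) {
    return(missing_value(sprintf(
      "window %d-%d not fully covered by grid years %d-%d",
      min(yrs), max(yrs), min(grid$years), max(grid$years))))
  }
  yrs
}

cell_months <- function(grid, cell, years, months) {
  grid$temp[cell[1], cell[2], match(years, grid$years), months, drop = FALSE]
}

#' Windowed mean summer temperature (MST)
#'
#' Mean of the June-August monthly means over the `k` calendar years
#' strictly before the collection year (the collection year itself is
#' excluded). Incomplete grid coverage yields `NA` with a `"reason"`
#' attribute, never a silent interpolation.
#'
#' @param grid A [climate_grid()].
#' @param cell Cell index from [locate_cell()].
#' @param collection_year Year the sample was collected.
#' @param k Window length in years (10, 20, 30, 40 or 50 in the standard
#'   battery; any positive integer accepted).
#' @return MST in degrees C, or `NA` with attribute `reason`.
#' @export
mst_window <- function(grid, cell, collection_year, k = 20) {
  yrs <- window_years(grid, collection_year, k)
  if (all(is.na(yrs))) return(yrs)
  v <- cell_months(grid, cell, yrs, SUMMER_MONTHS)
  if (anyNA(v)) return(missing_value("missing summer months in window"))
  mean(v)
}

#' Seasonal, annual and per-month means over a window
#'
#' Spring = MAM, summer = JJA, autumn = SON; winter = DJF where December
#' belongs to the preceding calendar year (so the window's first winter
#' reaches one year before the window). Annual = all 12 months; monthly =
#' per-calendar-month means over the window.
#'
#' @inheritParams mst_window
#' @return List with `spring`, `summer`, `autumn`, `winter`, `annual`, and
#'   `monthly` (length-12 vector); components are `NA` (with a `reason`
#'   attribute) where coverage is incomplete.
#' @export
seasonal_means <- function(grid, cell, collection_year, k = 20) {
  yrs <- window_years(grid, collection_year, k)
  if (all(is.na(yrs))) {
    return(list(spring = yrs, summer = yrs, autumn = yrs, winter = yrs,
                annual = yrs, monthly = rep(NA_real_, 12)))
  }
  season_mean <- function(months) {
    v <- cell_months(grid, cell, yrs, months)
    if (anyNA(v)) missing_value("missing months in window") else mean(v)
  }
  # DJF: December of year y-1 with Jan/Feb of year y
  winter <- if (!(min(yrs) - 1) %in% grid$years) {
    missing_value("winter lead-in December not covered by grid")
  } else {
    dec <- cell_months(grid, cell, yrs - 1, 12)
    janfeb <- cell_months(grid, cell, yrs, 1:2)
    if (anyNA(dec) || anyNA(janfeb)) {
      missing_value("missing winter months in window")
    } else {
      mean(c(dec, janfeb))
    }
  }
  monthly <- vapply(1:12, function(m) {
    v <- cell_months(grid, cell, yrs, m)
    if (anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  list(spring = season_mean(3:5), summer = season_mean(SUMMER_MONTHS),
       autumn = season_mean(9:11), winter = winter,
       annual = season_mean(1:12), monthly = monthly)
}

#' Effective temperature sum (degree-days above a base)
#'
#' Monthly approximation: every month whose mean exceeds the base
#' contributes `(T - base) * days_in_month`; the yearly sums are averaged
#' over the window. February counts 28 days in all years (the bias of
#' ignoring leap days is below 0.1% and keeps the measure deterministic).
#'
#' @inheritParams mst_window
#' @param base Base temperature in degrees C (5 or 10 in the standard
#'   battery).
#' @return Mean annual degree-days, or `NA` with a `reason` attribute.
#' @export
effective_temperature_sum <- function(grid, cell, collection_year, k = 20,
                                      base = 5) {
  yrs <- window_years(grid, collection_year, k)
  if (all(is.na(yrs))) return(yrs)
  v <- cell_months(grid, cell, yrs, 1:12)[1, 1, , ]
  v <- matrix(v, nrow = length(yrs), ncol = 12)
  if (anyNA(v)) return(missing_value("missing months in window"))
  excess <- pmax(sweep(v, 2, rep(base, 12)), 0)
  dd <- sweep(excess, 2, DAYS_IN_MONTH, `*`)
  mean(rowSums(dd * (v > base)))
}

#' Thermal growing season length (days above a base)
#'
#' Sum of `days_in_month` over months whose mean exceeds the base,
#' averaged over the window.
#'
#' @inheritParams effective_temperature_sum
#' @return Mean season length in days, or `NA` with a `reason` attribute.
#' @export
growing_season_length <- function(grid, cell, collection_year, k = 20,
                                  base = 5) {
  yrs <- window_years(grid, collection_year, k)
  if (all(is.na(yrs))) return(yrs)
  v <- matrix(cell_months(grid, cell, yrs, 1:12)[1, 1, , ],
              nrow = length(yrs), ncol = 12)
  if (anyNA(v)) return(missing_value("missing months in window"))
  mean(rowSums(sweep((v > base) * 1, 2, DAYS_IN_MONTH, `*`)))
}

#' Full climatic predictor battery for one site
#'
#' Computes, for the cell containing the site, the windowed mean summer
#' temperatures `mst_10 ... mst_50`, and (over the `k`-year window) the
#' seasonal/annual/monthly means, effective temperature sums above 5 and
#' 10 degrees C, and thermal growing season lengths above both bases.
#'
#' @param grid A [climate_grid()].
#' @param lat,lon Site coordinates (decimal degrees).
#' @param collection_year Year of sample collection.
#' @param windows MST window lengths (default `c(10, 20, 30, 40, 50)`).
#' @param k Window length for the non-MST variables (default 20).
#' @return Named list of predictor values (NA where the grid does not
#'   cover the window).
#' @export
site_climate <- function(grid, lat, lon, collection_year,
                         windows = c(10, 20, 30, 40, 50), k = 20) {
  cell <- locate_cell(grid, lat, lon)
  msts <- lapply(windows, function(w) mst_window(grid, cell, collection_year, w))
  names(msts) <- paste0("mst_", windows)
  sm <- seasonal_means(grid, cell, collection_year, k)
  monthly <- as.list(sm$monthly)
  names(monthly) <- paste0("tmean_m", 1:12)
  c(msts,
    list(spring = sm$spring, autumn = sm$autumn, winter = sm$winter,
         annual = sm$annual),
    monthly,
    list(ets_5 = effective_temperature_sum(grid, cell, collection_year, k, 5),
         ets_10 = effective_temperature_sum(grid, cell, collection_year, k, 10),
         growing_season_5 = growing_season_length(grid, cell, collection_year, k, 5),
         growing_season_10 = growing_season_length(grid, cell, collection_year, k, 10)))
}
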