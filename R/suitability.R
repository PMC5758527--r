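#' Derive the viable/declining/unsuitable SCI thresholds
#'
#' From the per-population mean SCI of the viable and declining groups:
#' `a4` = mean of the viable group, `a2` = mean of the declining group,
#' `a3 = (a2 + a4) / 2` (viable/declining boundary), and
#' `a1 = a2 + 1.96 * sem` (declining/unsuitable boundary; the 95% upper
#' confidence bound of the declining mean, with the normal 1.96
#' multiplier). No lower SCI bound for viability is set: the species is
#' cold-adapted and colder-than-viable-mean conditions are not penalised.
#'
#' @param viable,declining Population data frames (column `mean_sci`) or
#'   numeric vectors of population mean SCI, each with >= 2 populations.
#' @return Object of class `threshold_set`: `a1`, `a2`, `a3`, `a4`,
#'   `sem_declining`, `n`.
#' @export
derive_thresholds <- function(viable, declining) {
  v <- if (is.data.frame(viable)) viable$mean_sci else viable
  d <- if (is.data.frame(declining)) declining$mean_sci else declining
  if (length(v) < 2 || length(d) < 2) {
    stop("each group needs at least 2 populations")
  }
  a4 <- mean(v)
  a2 <- mean(d)
  sem <- stats::sd(d) / sqrt(length(d))
  if (a4 >= a2) {
    stop(sprintf(
      "threshold derivation error: viable mean (%.2f) not below declining mean (%.2f); groups not separable",
      a4, a2))
  }
  if (sem == 0) {
    warning("declining-group s.e.m. is zero: declining/unsuitable boundary collapses to the group mean")
  }
  structure(list(a1 = a2 + 1.96 * sem, a2 = a2, a3 = (a2 + a4) / 2, a4 = a4,
                 sem_declining = sem, n = length(v) + length(d)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("SCI suitability thresholds\n")
  cat(sprintf("  viable mean (a4)            = %.2f\n", x$a4))
  cat(sprintf("  viable/declining (a3)       = %.2f\n", x$a3))
  cat(sprintf("  declining mean (a2)         = %.2f (s.e.m. %.3f)\n",
              x$a2, x$sem_declining))
  cat(sprintf("  declining/unsuitable (a1)   = %.2f\n", x$a1))
  cat(sprintf("  classes: SCI <= %.2f viable; %.2f < SCI <= %.2f declining; SCI > %.2f unsuitable\n",
              x$a3, x$a3, x$a1, x$a1))
  invisible(x)
}

#' Read a range-mask cell list
#'
#' CSV of cell centers, columns `lat_center, lon_center`, listing the
#' grid cells inside the species range model.
#'
#' @param path CSV path.
#' @return Data frame with columns `lat`, `lon`.
#' @export
read_mask <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("lat_center", "lon_center"), names(x))
  if (length(miss) > 0) {
    stop("mask CSV ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  data.frame(lat = x$lat_center, lon = x$lon_center)
}

period_mst <- function(grid, cell, period) {
  yrs <- seq(period[1], period[2])
  if (!all(yrs %in% grid$years)) {
    return(missing_value(sprintf("period %d-%d not covered by grid",
                                 period[1], period[2])))
  }
  v <- cell_months(grid, cell, yrs, SUMMER_MONTHS)
  if (anyNA(v)) return(missing_value("missing summer months in period"))
  mean(v)
}

#' Project mean SCI onto a climate grid for a fixed period
#'
#' For every mask cell, the period mean summer temperature (all summer
#' months of the period pooled, which for complete data equals the mean
#' of per-year summer means) is fed through the SCI-vs-MST calibration.
#' Scenario grids supplied at a different resolution are matched to mask
#' cells by nearest-neighbor cell lookup.
#'
#' @param grid A [climate_grid()] (observed or scenario).
#' @param mask Data frame of mask cell centers (`lat`, `lon`).
#' @param period Length-2 integer vector, first and last year.
#' @param cal SCI-vs-MST [fit_calibration()] (or published coefficients
#'   via [calibration_from_coef()]).
#' @param label Optional period/scenario label (e.g. `"1901-1920"`).
#' @return Data frame `lat, lon, mst, sci` (one row per mask cell; `NA`
#'   where the cell has missing months).
#' @export
project_sci <- function(grid, mask, period, cal, label = NULL) {
  out <- mask
  out$mst <- vapply(seq_len(nrow(mask)), function(i) {
    cell <- tryCatch(locate_cell(grid, mask$lat[i], mask$lon[i]),
                     error = function(e) NULL)
    if (is.null(cell)) return(NA_real_)
    as.numeric(period_mst(grid, cell, period))
  }, numeric(1))
  out$sci <- predict(cal, out$mst)
  attr(out, "period") <- if (is.null(label))
    paste(period, collapse = "-") else label
  out
}

#' Classify grid cells into suitability classes
#'
#' Monotone step classification of predicted mean SCI:
#' `SCI <= a3` viable; `a3 < SCI <= a1` declining; `SCI > a1` unsuitable;
#' missing SCI is `no-data`. Boundaries are inclusive on the cool side.
#'
#' @param sci_map Output of [project_sci()] (or any data frame with an
#'   `sci` column).
#' @param thresholds A [derive_thresholds()] result.
#' @return The input with a `class` factor column added
#'   (`viable < declining < unsuitable`, plus `no-data`); class
#'   `suitability_map`.
#' @export
classify_cells <- function(sci_map, thresholds) {
  cls <- ifelse(is.na(sci_map$sci), "no-data",
                ifelse(sci_map$sci <= thresholds$a3, "viable",
                       ifelse(sci_map$sci <= thresholds$a1, "declining",
                              "unsuitable")))
  sci_map$class <- factor(cls, levels = c("viable", "declining",
                                          "unsuitable", "no-data"))
  class(sci_map) <- c("suitability_map", class(sci_map))
  sci_map
}

#' Per-period class shares, area-weighted by latitude
#'
#' Fraction of masked cells in each suitability class for each supplied
#' map, weighted by `cos(latitude)` so shares reflect physical area on
#' the sphere rather than cell counts. All maps must share one mask.
#'
#' @param maps List of [classify_cells()] outputs (named or labelled via
#'   their `period` attribute).
#' @return Data frame `period, viable, declining, unsuitable, no_data`
#'   (shares summing to 1 per period).
#' @export
area_summary <- function(maps) {
  if (!is.list(maps) || inherits(maps, "data.frame")) maps <- list(maps)
  ref <- maps[[1]][, c("lat", "lon")]
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    if (!isTRUE(all.equal(m[, c("lat", "lon")], ref, check.attributes = FALSE))) {
      stop("mask mismatch between suitability maps")
    }
    w <- cos(m$lat * pi / 180)
    shares <- vapply(c("viable", "declining", "unsuitable", "no-data"),
                     function(cl) sum(w[m$class == cl]) / sum(w), numeric(1))
    lab <- if (!is.null(names(maps)) && nzchar(names(maps)[i])) names(maps)[i]
    else if (!is.null(attr(m, "period"))) attr(m, "period")
    else as.character(i)
    data.frame(period = lab, viable = shares[1], declining = shares[2],
               unsuitable = shares[3], no_data = shares[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconstruct per-population SCI and maximum-age time series
#'
#' For each year `y` in `years`, predicts the population mean SCI from
#' the 20-year mean summer temperature ending in year `y - 1` via the
#' SCI-vs-MST calibration, and (optionally) the maximum age from that SCI
#' via the age-vs-SCI calibration. Years whose 20-year lead-in is not
#' covered by the grid are dropped with a warning.
#'
#' @param lat,lon Population coordinates (decimal degrees).
#' @param grid A [climate_grid()].
#' @param years Integer years to reconstruct (default 1901:2010).
#' @param cal_sci SCI-vs-MST calibration.
#' @param cal_age Optional age-vs-SCI calibration (default `NULL`: the
#'   `a_max` column is `NA`).
#' @param k MST window length (default 20).
#' @return Data frame `year, mst, sci, a_max`.
#' @export
reconstruct_timeseries <- function(lat, lon, grid, years = 1901:2010,
                                   cal_sci, cal_age = NULL, k = 20) {
  cell <- locate_cell(grid, lat, lon)
  mst <- vapply(years, function(y)
    as.numeric(mst_window(grid, cell, y, k)), numeric(1))
  if (anyNA(mst)) {
    warning(sprintf("reconstruction truncated: %d year(s) lack the %d-year lead-in",
                    sum(is.na(mst)), k))
    keep <- !is.na(mst)
    years <- years[keep]
    mst <- mst[keep]
  }
  sci <- predict(cal_sci, mst)
  a_max <- if (is.null(cal_age)) rep(NA_real_, length(sci))
  else predict(cal_age, sci)
  data.frame(year = years, mst = mst, sci = sci, a_max = a_max)
}
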