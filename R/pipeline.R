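#' Assemble a pipeline run configuration
#'
#' @param shells_csv Path to the shell measurement CSV (required).
#' @param climate_csv Path to the long-format monthly climate CSV
#'   (required).
#' @param rings_csv Optional path to the growth-ring CSV; when absent the
#'   growth stage is skipped with a warning.
#' @param mask_csv Optional range-mask CSV; when absent the mask defaults
#'   to every grid cell.
#' @param out_dir Output directory (created if needed).
#' @param k MST window length in years, one of 10/20/30/40/50 (default
#'   20).
#' @param cv_k Number of cross-validation folds (default 5).
#' @param seed Root seed for all randomness in the run (default 1).
#' @param exclude_ids Population ids excluded from the calibration
#'   (anomalous samples).
#' @param periods Named list of length-2 year vectors for the suitability
#'   maps.
#' @param reconstruct_years Years for the per-population reconstructions.
#' @param min_length_mm Shell filter boundary (default 50 mm).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(shells_csv, climate_csv, rings_csv = NULL,
                            mask_csv = NULL, out_dir = tempfile("musselclim_run_"),
                            k = 20, cv_k = 5, seed = 1,
                            exclude_ids = character(),
                            periods = list(`1901-1920` = c(1901, 1920),
                                           `1991-2010` = c(1991, 2010)),
                            reconstruct_years = 1921:2010,
                            min_length_mm = 50) {
  if (!k %in% c(10, 20, 30, 40, 50)) stop("k must be one of 10, 20, 30, 40, 50")
  for (p in c(shells_csv, climate_csv, rings_csv, mask_csv)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(shells_csv = shells_csv, climate_csv = climate_csv,
                 rings_csv = rings_csv, mask_csv = mask_csv,
                 out_dir = out_dir, k = k, cv_k = cv_k, seed = seed,
                 exclude_ids = exclude_ids, periods = periods,
                 reconstruct_years = reconstruct_years,
                 min_length_mm = min_length_mm),
            class = "run_config")
}

stage_log <- function(stage, ..., n_in = NA, n_out = NA) {
  message(sprintf("[%s] %s (n_in=%s, n_out=%s)", stage,
                  paste0(..., collapse = ""), format(n_in), format(n_out)))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: shell morphometrics (read, filter, aggregate) ->
#' climatic predictor extraction -> SCI-vs-MST calibration with k-fold
#' cross-validation, Moran's I residual diagnostics and outlier handling
#' -> growth estimation (when ring series are supplied) and the
#' age-vs-SCI calibration -> suitability thresholds -> gridded projection
#' and classification per period -> per-population reconstructions.
#' Every stage writes its table under `out_dir` and is recorded in a
#' machine-readable JSON manifest (`manifest.json`) together with the
#' inputs, seed and package version. A stage failure halts the run with a
#' stage-labelled error; tables already written are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`populations`,
#'   `site_climate`, `calibration`, `cv`, `moran`, `predictor_ranking`,
#'   `growth`, `thresholds`, `maps`, `area_summary`, `reconstructions`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "musselclim",
                   version = as.character(utils::packageVersion("musselclim")),
                   seed = config$seed,
                   inputs = list(shells = config$shells_csv,
                                 climate = config$climate_csv,
                                 rings = config$rings_csv,
                                 mask = config$mask_csv),
                   settings = list(k = config$k, cv_k = config$cv_k,
                                   min_length_mm = config$min_length_mm,
                                   exclude_ids = config$exclude_ids),
                   stages = list())
  results <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = res$status, detail = res$detail)
    res$value
  }

  # -- morphometrics ---------------------------------------------------
  results$populations <- run_stage("morpho", function() {
    shells <- read_shells(config$shells_csv)
    n0 <- nrow(shells)
    shells <- filter_shells(shells, config$min_length_mm)
    pops <- aggregate_populations(shells)
    utils::write.csv(pops, file.path(config$out_dir, "populations.csv"),
                     row.names = FALSE)
    stage_log("morpho", "aggregated shell records into population samples",
              n_in = n0, n_out = nrow(pops))
    list(value = pops, status = "complete",
         detail = sprintf("%d shells -> %d populations", n0, nrow(pops)))
  })
  pops <- results$populations
  grid <- read_climate_csv(config$climate_csv)

  # -- climate extraction ----------------------------------------------
  results$site_climate <- run_stage("climate-extract", function() {
    sc <- lapply(seq_len(nrow(pops)), function(i) {
      v <- site_climate(grid, pops$lat[i], pops$lon[i], pops$year[i],
                        k = config$k)
      as.data.frame(lapply(v, as.numeric))
    })
    sc <- cbind(population_id = pops$population_id, do.call(rbind, sc))
    utils::write.csv(sc, file.path(config$out_dir, "site_climate.csv"),
                     row.names = FALSE)
    stage_log("climate-extract", "extracted climatic predictor battery",
              n_in = nrow(pops), n_out = nrow(sc))
    list(value = sc, status = "complete",
         detail = sprintf("%d sites", nrow(sc)))
  })
  sc <- results$site_climate

  # -- calibration -----------------------------------------------------
  cal_stage <- run_stage("calibrate", function() {
    mst_col <- paste0("mst_", config$k)
    use <- pops$period == "recent" & !pops$excluded & is.finite(sc[[mst_col]])
    d <- data.frame(id = pops$population_id[use], mst = sc[[mst_col]][use],
                    sci = pops$mean_sci[use], lat = pops$lat[use],
                    lon = pops$lon[use], stringsAsFactors = FALSE)
    fl <- flag_outliers(d$mst, d$sci, d$id, exclude_ids = config$exclude_ids)
    d <- d[d$id %in% fl$retained$id, ]
    cal <- fit_calibration(d$mst, d$sci, xlab = sprintf("MST%d", config$k),
                           ylab = "SCI")
    cv <- kfold_cv(d$mst, d$sci, k = config$cv_k, seed = config$seed)
    mi <- morans_i(stats::residuals(cal$model), d$lat, d$lon)
    sc_use <- sc[use, , drop = FALSE]
    sc_use <- sc_use[sc_use$population_id %in% d$id, , drop = FALSE]
    ranking <- compare_predictors(
      sc_use[, setdiff(names(sc_use), "population_id"), drop = FALSE], d$sci)
    utils::write.csv(cv$folds, file.path(config$out_dir, "cv_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(config$out_dir, "predictor_ranking.csv"),
                     row.names = FALSE)
    summary_txt <- c(utils::capture.output(print(cal)),
                     utils::capture.output(print(cv)),
                     utils::capture.output(print(mi)),
                     sprintf("seed: %d", config$seed),
                     sprintf("excluded ids: %s",
                             paste(fl$excluded_ids, collapse = ", ")),
                     sprintf("auto-flagged ids: %s",
                             paste(fl$flagged_ids, collapse = ", ")))
    writeLines(summary_txt, file.path(config$out_dir, "calibration.txt"))
    stage_log("calibrate", "fitted SCI calibration",
              n_in = sum(use), n_out = cal$n)
    list(value = list(calibration = cal, cv = cv, moran = mi,
                      ranking = ranking, outliers = fl, data = d),
         status = "complete",
         detail = sprintf("n=%d, r=%.2f", cal$n, cal$pearson_r))
  })
  results$calibration <- cal_stage$calibration
  results$cv <- cal_stage$cv
  results$moran <- cal_stage$moran
  results$predictor_ranking <- cal_stage$ranking

  # -- growth ----------------------------------------------------------
  cal_age <- NULL
  results$growth <- run_stage("growth", function() {
    if (is.null(config$rings_csv)) {
      warning("no ring series supplied: growth stage skipped")
      stage_log("growth", "skipped (no rings file)")
      return(list(value = NULL, status = "skipped", detail = "no rings file"))
    }
    rings <- read_rings(config$rings_csv)
    fits <- lapply(rings, fit_growth)
    ok <- vapply(fits, function(f) inherits(f, "growth_fit"), logical(1))
    per_shell <- data.frame(
      shell_id = names(fits)[ok],
      k_const = vapply(fits[ok], `[[`, numeric(1), "k_const"),
      l_inf_mm = vapply(fits[ok], `[[`, numeric(1), "l_inf_mm"),
      r_squared = vapply(fits[ok], `[[`, numeric(1), "r_squared"),
      stringsAsFactors = FALSE)
    per_shell$population_id <- sub("_g\\d+$", "", per_shell$shell_id)
    by_pop <- do.call(rbind, lapply(split(per_shell, per_shell$population_id),
                                    function(p) data.frame(
                                      population_id = p$population_id[1],
                                      mean_k = mean(p$k_const),
                                      mean_l_inf = mean(p$l_inf_mm),
                                      n_shells = nrow(p))))
    rownames(by_pop) <- NULL
    utils::write.csv(per_shell, file.path(config$out_dir, "growth_fits.csv"),
                     row.names = FALSE)
    stage_log("growth", "fitted growth constants",
              n_in = length(fits), n_out = nrow(by_pop))
    list(value = list(per_shell = per_shell, by_pop = by_pop,
                      n_fallback = sum(!ok)),
         status = "complete",
         detail = sprintf("%d shells, %d populations, %d fallback fits",
                          length(fits), nrow(by_pop), sum(!ok)))
  })

  # age-vs-SCI calibration from growth-derived maximum ages
  if (!is.null(results$growth)) {
    amax <- merge(results$growth$by_pop,
                  pops[, c("population_id", "mean_sci")], by = "population_id")
    amax$a_max <- vapply(seq_len(nrow(amax)), function(i) {
      -log(1 - 0.95) / amax$mean_k[i]  # age at 95% of asymptotic length
    }, numeric(1))
    if (nrow(amax) >= 5) {
      cal_age <- fit_calibration(amax$mean_sci, amax$a_max,
                                 xlab = "SCI", ylab = "A_max")
    }
  }

  # -- thresholds ------------------------------------------------------
  results$thresholds <- run_stage("thresholds", function() {
    viable <- pops[pops$status == "viable" & !pops$excluded, ]
    declining <- pops[pops$status == "declining" & !pops$excluded, ]
    if (nrow(viable) == 0 || nrow(declining) == 0) {
      stop("a status group is empty; thresholds cannot be derived")
    }
    th <- derive_thresholds(viable, declining)
    utils::write.csv(data.frame(a1 = th$a1, a2 = th$a2, a3 = th$a3,
                                a4 = th$a4, sem_declining = th$sem_declining,
                                n = th$n),
                     file.path(config$out_dir, "thresholds.csv"),
                     row.names = FALSE)
    stage_log("thresholds", "derived SCI suitability thresholds",
              n_in = nrow(viable) + nrow(declining), n_out = 4)
    list(value = th, status = "complete",
         detail = sprintf("a3=%.2f, a1=%.2f", th$a3, th$a1))
  })

  # -- suitability maps ------------------------------------------------
  map_stage <- run_stage("map", function() {
    mask <- if (is.null(config$mask_csv)) {
      expand.grid(lat = grid$lat, lon = grid$lon, KEEP.OUT.ATTRS = FALSE)
    } else read_mask(config$mask_csv)
    maps <- lapply(config$periods, function(p) {
      classify_cells(project_sci(grid, mask, p, results$calibration),
                     results$thresholds)
    })
    for (nm in names(maps)) {
      utils::write.csv(maps[[nm]],
                       file.path(config$out_dir,
                                 paste0("suitability_", nm, ".csv")),
                       row.names = FALSE)
    }
    shares <- area_summary(maps)
    utils::write.csv(shares, file.path(config$out_dir, "area_summary.csv"),
                     row.names = FALSE)
    stage_log("map", "classified suitability maps",
              n_in = nrow(mask), n_out = length(maps))
    list(value = list(maps = maps, shares = shares), status = "complete",
         detail = sprintf("%d periods x %d cells", length(maps), nrow(mask)))
  })
  results$maps <- map_stage$maps
  results$area_summary <- map_stage$shares

  # -- reconstruction --------------------------------------------------
  results$reconstructions <- run_stage("reconstruct", function() {
    rec_pops <- pops[pops$period == "recent" & !pops$excluded, ]
    recs <- lapply(seq_len(nrow(rec_pops)), function(i) {
      r <- suppressWarnings(
        reconstruct_timeseries(rec_pops$lat[i], rec_pops$lon[i], grid,
                               years = config$reconstruct_years,
                               cal_sci = results$calibration,
                               cal_age = cal_age, k = config$k))
      cbind(population_id = rec_pops$population_id[i], r)
    })
    recs <- do.call(rbind, recs)
    utils::write.csv(recs, file.path(config$out_dir, "reconstructions.csv"),
                     row.names = FALSE)
    stage_log("reconstruct", "reconstructed SCI/longevity series",
              n_in = nrow(rec_pops), n_out = nrow(recs))
    list(value = recs, status = "complete",
         detail = sprintf("%d populations x %d years", nrow(rec_pops),
                          length(unique(recs$year))))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
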