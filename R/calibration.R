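#' Fit a simple linear calibration by ordinary least squares
#'
#' Wraps an OLS fit of `y ~ x` and reports the quantities used throughout
#' the pipeline: intercept, slope, Pearson r, the slope F statistic with
#' (1, n - 2) degrees of freedom, its two-sided p-value, and the residual
#' standard deviation. This is the machinery behind both the shell
#' convexity vs. summer temperature calibration and the maximum age vs.
#' convexity calibration.
#'
#' @param x,y Paired numeric vectors, n >= 5; `x` must not be constant.
#' @param xlab,ylab Optional variable labels carried into printing.
#' @return Object of class `linear_calibration` with fields `intercept`,
#'   `slope`, `pearson_r`, `f_stat`, `df_num`, `df_den`, `p`, `n`,
#'   `residual_sd`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(x, y, xlab = "x", ylab = "y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("fit_calibration requires n >= 5 complete pairs")
  if (stats::sd(x) == 0) stop("design error: x is constant")
  m <- stats::lm(y ~ x)
  # noiseless input (exact recovery checks) is legitimate: quiet the
  # perfect-fit notice from summary.lm
  sm <- suppressWarnings(summary(m))
  tval <- sm$coefficients["x", "t value"]
  structure(list(intercept = unname(stats::coef(m)[1]),
                 slope = unname(stats::coef(m)[2]),
                 pearson_r = unname(stats::cor(x, y)),
                 f_stat = unname(tval^2),
                 df_num = 1L, df_den = n - 2L,
                 p = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 n = n, residual_sd = sm$sigma,
                 xlab = xlab, ylab = ylab, model = m),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration: %s = %.3f + (%.3f x %s)\n",
              x$ylab, x$intercept, x$slope, x$xlab))
  cat(sprintf("  Pearson r = %.2f, F(%d,%d) = %.1f, p = %.3g, n = %d, residual sd = %.3f\n",
              x$pearson_r, x$df_num, x$df_den, x$f_stat, x$p, x$n,
              x$residual_sd))
  invisible(x)
}

#' Predict from a linear calibration
#'
#' @param object A [fit_calibration()] result, or a list with `intercept`
#'   and `slope` (e.g. published coefficients).
#' @param x New predictor values.
#' @param ... Unused.
#' @return `intercept + slope * x`.
#' @export
predict.linear_calibration <- function(object, x, ...) {
  object$intercept + object$slope * x
}

#' Build a calibration object from known coefficients
#'
#' Useful for applying published regression coefficients without refitting.
#'
#' @param intercept,slope Line coefficients.
#' @param xlab,ylab Optional labels.
#' @return A minimal `linear_calibration`.
#' @export
calibration_from_coef <- function(intercept, slope, xlab = "x", ylab = "y") {
  structure(list(intercept = intercept, slope = slope, pearson_r = NA_real_,
                 f_stat = NA_real_, df_num = 1L, df_den = NA_integer_,
                 p = NA_real_, n = NA_integer_, residual_sd = NA_real_,
                 xlab = xlab, ylab = ylab, model = NULL),
            class = "linear_calibration")
}

#' Rank candidate climatic predictors by correlation with mean SCI
#'
#' Computes Pearson r between each candidate variable and the population
#' mean SCI, and ranks candidates by decreasing absolute r (ties broken
#' alphabetically by variable name). Constant or all-missing candidates
#' are excluded with a warning.
#'
#' @param predictors Data frame, one row per site, one column per
#'   candidate climatic variable (e.g. from [site_climate()]).
#' @param sci Numeric vector of population mean SCI values (same order).
#' @return Data frame `variable, r, n`, ranked; best predictor first.
#' @export
compare_predictors <- function(predictors, sci) {
  if (ncol(predictors) < 2) stop("need at least 2 candidate variables")
  rows <- lapply(names(predictors), function(v) {
    x <- predictors[[v]]
    ok <- is.finite(x) & is.finite(sci)
    if (sum(ok) < 5 || stats::sd(x[ok]) == 0) {
      warning(sprintf("predictor '%s' excluded (constant or insufficient data)", v))
      return(NULL)
    }
    data.frame(variable = v, r = stats::cor(x[ok], sci[ok]), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no usable predictors")
  out <- out[order(-abs(out$r), out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mape <- function(obs, pred) mean(abs(pred - obs) / obs) * 100
tofallis_measure <- function(obs, pred) mean(abs(log(pred / obs)))
minmax_accuracy <- function(obs, pred) mean(pmin(obs, pred) / pmax(obs, pred))

#' k-fold cross-validation of a linear calibration
#'
#' Seeded uniform random partition into `k` folds (fold sizes differ by at
#' most one; remainder observations are spread one per fold). Each fold is
#' predicted by the line fitted on the other k - 1 folds. Three accuracy
#' measures are reported per fold and pooled over all held-out points:
#' MAPE (`mean(|pred - obs| / obs) * 100`), Tofallis's log accuracy ratio
#' (`mean(|ln(pred / obs)|)`), and min-max accuracy
#' (`mean(min(obs, pred) / max(obs, pred))`). All require positive `y`.
#'
#' @param x,y Paired numeric vectors.
#' @param k Number of folds (default 5); `k = n` gives leave-one-out,
#'   which is partition-independent and hence fully deterministic.
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_report` with `k`, `folds` (per-fold data
#'   frame with coefficients and measures), and pooled `mape`, `tofallis`,
#'   `minmax`.
#' @export
kfold_cv <- function(x, y, k = 5, seed = 1) {
  n <- length(x)
  if (k < 2 || k > n) stop("need n >= k >= 2")
  if (any(y <= 0)) stop("measure undefined: y must be positive for percentage accuracy")
  fold <- local_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  per_fold <- lapply(seq_len(k), function(f) {
    test <- fold == f
    m <- stats::lm(y[!test] ~ x[!test])
    p <- stats::coef(m)[1] + stats::coef(m)[2] * x[test]
    pred[test] <<- p
    data.frame(fold = f, n_test = sum(test),
               intercept = unname(stats::coef(m)[1]),
               slope = unname(stats::coef(m)[2]),
               mape = mape(y[test], p),
               tofallis = tofallis_measure(y[test], p),
               minmax = minmax_accuracy(y[test], p))
  })
  structure(list(k = k, seed = seed,
                 folds = do.call(rbind, per_fold),
                 mape = mape(y, pred),
                 tofallis = tofallis_measure(y, pred),
                 minmax = minmax_accuracy(y, pred),
                 predictions = pred),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %s)\n", x$k, format(x$seed)))
  cat(sprintf("  pooled MAPE = %.2f%%, Tofallis = %.4f, min-max accuracy = %.4f\n",
              x$mape, x$tofallis, x$minmax))
  print(x$folds, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Moran's I spatial autocorrelation with inverse-distance weights
#'
#' Weights are unstandardized inverse great-circle distances in km,
#' `w_ij = 1 / d_ij`. Coincident sites (distance below `min_dist_km`) have
#' their distance capped at `min_dist_km` with a warning. The expectation
#' is `-1/(n-1)`; the variance and z-score follow the normality
#' assumption; the p-value is two-sided normal.
#'
#' @param values Numeric vector of the variable tested (e.g. calibration
#'   residuals or mean SCI), n >= 5.
#' @param lat,lon Site coordinates in decimal degrees.
#' @param min_dist_km Minimum pairwise distance in km (default 1).
#' @return Object of class `moran_result`: `observed_i`, `expected_i`,
#'   `variance`, `z_score`, `p`, `n`.
#' @export
morans_i <- function(values, lat, lon, min_dist_km = 1) {
  n <- length(values)
  if (n < 5) stop("morans_i requires n >= 5")
  if (length(lat) != n || length(lon) != n) {
    stop("coordinate vectors must match values in length")
  }
  pts <- cbind(lon, lat)
  if (nrow(unique(pts)) < 2) stop("need at least 2 distinct locations")
  d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  off <- d[upper.tri(d)]
  if (any(off < min_dist_km)) {
    warning(sprintf("coincident/near-coincident sites: %d pair distance(s) capped at %g km",
                    sum(off < min_dist_km), min_dist_km))
    d[d < min_dist_km] <- min_dist_km
  }
  w <- 1 / d
  diag(w) <- 0
  z <- values - mean(values)
  s0 <- sum(w)
  obs <- (n / s0) * sum(w * outer(z, z)) / sum(z^2)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  zs <- (obs - e_i) / sqrt(var_i)
  structure(list(observed_i = obs, expected_i = e_i, variance = var_i,
                 z_score = zs, p = 2 * stats::pnorm(-abs(zs)), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I (inverse great-circle distance weights), n = %d\n", x$n))
  cat(sprintf("  observed I = %.2f, expected I = %.2f, variance = %.2f, z = %.2f, p = %.2f\n",
              x$observed_i, x$expected_i, x$variance, x$z_score, x$p))
  invisible(x)
}

#' Flag and/or exclude calibration outliers
#'
#' Two mechanisms, matching how anomalous samples are handled: (a) an
#' explicit exclusion list of sample ids (removed unconditionally), and
#' (b) automatic flagging of points whose externally studentized residual
#' from the x-y line exceeds `threshold` in absolute value. Auto-flagged
#' points are removed only when `auto = TRUE`.
#'
#' @param x,y Paired numeric calibration data.
#' @param ids Sample identifiers (same order as `x`).
#' @param exclude_ids Ids to exclude unconditionally (default none).
#' @param auto If `TRUE`, also exclude auto-flagged points.
#' @param threshold Studentized-residual threshold (default 2.5).
#' @return List with `retained` (data frame id, x, y), `flagged_ids`
#'   (auto-detected outliers among the non-listed points), `excluded_ids`.
#' @export
flag_outliers <- function(x, y, ids, exclude_ids = character(),
                          auto = FALSE, threshold = 2.5) {
  keep <- !(ids %in% exclude_ids)
  m <- stats::lm(y[keep] ~ x[keep])
  rs <- stats::rstudent(m)
  flagged <- ids[keep][abs(rs) > threshold]
  excluded <- ids[!keep]
  if (auto && length(flagged) > 0) {
    keep <- keep & !(ids %in% flagged)
    excluded <- c(excluded, flagged)
  }
  list(retained = data.frame(id = ids[keep], x = x[keep], y = y[keep],
                             stringsAsFactors = FALSE),
       flagged_ids = flagged, excluded_ids = excluded)
}
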