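#' Read annual growth-ring series
#'
#' CSV with columns `shell_id, ring_index` and either
#' `cumulative_length_mm` (shell length at each annual ring) or
#' `increment_mm` (annual increments, converted by cumulative sum).
#' Cumulative series must be strictly increasing within each shell.
#'
#' @param path CSV path.
#' @param format `"cumulative"` or `"increment"`.
#' @return Named list of numeric vectors (cumulative lengths, ordered by
#'   ring index), one per shell.
#' @export
read_rings <- function(path, format = c("cumulative", "increment")) {
  format <- match.arg(format)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  value_col <- if (format == "cumulative") "cumulative_length_mm" else "increment_mm"
  need <- c("shell_id", "ring_index", value_col)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("ring CSV ", path, " is missing columns: ", paste(miss, collapse = ", "))
  }
  out <- lapply(split(x, x$shell_id), function(d) {
    d <- d[order(d$ring_index), ]
    v <- d[[value_col]]
    if (format == "increment") v <- cumsum(v)
    if (any(diff(v) <= 0)) {
      stop("ring series for shell ", d$shell_id[1],
           " is not strictly increasing")
    }
    v
  })
  out
}

#' Ford-Walford estimation of von Bertalanffy growth constants
#'
#' Regresses length at ring t+1 on length at ring t
#' (`L_{t+1} = a + b * L_t`, the recursive form of the von Bertalanffy
#' equation) and recovers the growth constant `K = -ln(b)` and asymptotic
#' length `L_inf = a / (1 - b)`. Requires `0 < b < 1`; otherwise growth is
#' not asymptotic and an error is raised (callers may fall back to
#' [log_trend_age()]).
#'
#' @param lengths Strictly increasing cumulative shell lengths at
#'   successive annual rings (mm); at least 5 rings (4 Ford-Walford pairs).
#' @return Object of class `growth_fit`: `k_const` (per year), `l_inf_mm`,
#'   `r_squared`, `method = "ford_walford"`, and the Walford line
#'   coefficients `a`, `b`.
#' @export
ford_walford <- function(lengths) {
  t0 <- lengths[-length(lengths)]
  t1 <- lengths[-1]
  if (length(t0) < 4) stop("ford_walford requires at least 4 ring pairs")
  m <- stats::lm(t1 ~ t0)
  a <- unname(stats::coef(m)[1])
  b <- unname(stats::coef(m)[2])
  if (!is.finite(b) || b >= 1 || b <= 0) {
    stop(sprintf("non-asymptotic growth: Walford slope b = %.4f not in (0, 1)", b))
  }
  fit <- structure(list(k_const = -log(b), l_inf_mm = a / (1 - b),
                        r_squared = suppressWarnings(summary(m))$r.squared,
                        method = "ford_walford", a = a, b = b),
                   class = "growth_fit")
  if (fit$l_inf_mm < max(lengths)) {
    warning(sprintf("estimated L_inf (%.1f mm) below largest observed ring (%.1f mm)",
                    fit$l_inf_mm, max(lengths)))
  }
  fit
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("von Bertalanffy fit (%s): K = %.4f /yr, L_inf = %.1f mm, R2 = %.3f\n",
              x$method, x$k_const, x$l_inf_mm, x$r_squared))
  invisible(x)
}

#' Age of a shell of given length under a fitted growth curve
#'
#' Inverts the von Bertalanffy curve: `t = -ln(1 - L / L_inf) / K`.
#' The maximum age of a population sample is obtained by applying this to
#' the longest shell in the sample.
#'
#' @param fit A [ford_walford()] result (or list with `k_const`,
#'   `l_inf_mm`).
#' @param length_mm Shell length in mm, strictly below `l_inf_mm`.
#' @return Estimated age in years.
#' @export
age_from_length <- function(fit, length_mm) {
  if (any(length_mm >= fit$l_inf_mm)) {
    stop(sprintf("age undefined: length %.1f mm >= asymptotic length %.1f mm",
                 max(length_mm), fit$l_inf_mm))
  }
  -log(1 - length_mm / fit$l_inf_mm) / fit$k_const
}

#' Logarithmic trend of annual growth increments
#'
#' Fits `increment_t = c + d * ln(t)` on the annual growth increments
#' (first increment = length at ring 1). Used as the fallback description
#' of the growth trajectory when the Ford-Walford fit is degenerate
#' (non-asymptotic series). Non-positive increments are excluded with a
#' warning.
#'
#' @param lengths Cumulative ring lengths (mm), at least 5 rings.
#' @return Object of class `growth_trend`: coefficients `c`, `d`,
#'   `r_squared`, `method = "log_trend"`.
#' @export
log_trend_age <- function(lengths) {
  if (length(lengths) < 5) stop("log_trend_age requires at least 5 rings")
  inc <- diff(c(0, lengths))
  t <- seq_along(inc)
  ok <- inc > 0
  if (any(!ok)) {
    warning(sprintf("%d non-positive increment(s) excluded", sum(!ok)))
  }
  m <- stats::lm(inc[ok] ~ log(t[ok]))
  structure(list(c = unname(stats::coef(m)[1]), d = unname(stats::coef(m)[2]),
                 r_squared = suppressWarnings(summary(m))$r.squared,
                 method = "log_trend"),
            class = "growth_trend")
}

#' Fit growth with automatic fallback
#'
#' Tries [ford_walford()]; on a non-asymptotic series falls back to
#' [log_trend_age()] and marks the result growth-uncertain.
#'
#' @param lengths Cumulative ring lengths (mm).
#' @return A `growth_fit` or (fallback) `growth_trend` object; the latter
#'   carries attribute `growth_uncertain = TRUE`.
#' @export
fit_growth <- function(lengths) {
  tryCatch(ford_walford(lengths), error = function(e) {
    out <- log_trend_age(lengths)
    attr(out, "growth_uncertain") <- TRUE
    out
  })
}

#' Correlate per-population growth constant with mean SCI
#'
#' Spearman rank correlation of the per-population mean von Bertalanffy
#' growth constant K against the population mean SCI. A positive
#' correlation reflects faster shell growth (wider annual increments,
#' more convex shells) in warmer environments.
#'
#' @param k_values Per-population mean growth constants.
#' @param sci_values Per-population mean SCI, same order.
#' @return List with `rho`, `p`, `n` (see [rank_correlation()]).
#' @export
growth_vs_sci <- function(k_values, sci_values) {
  rank_correlation(k_values, sci_values)
}
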