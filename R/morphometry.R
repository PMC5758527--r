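#' Shell convexity index (SCI)
#'
#' The basic morphometric index of shell shape: the width-to-length ratio
#' scaled to percent, `100 * W / L`. Higher values indicate more convex
#' (inflated) shells, which in *Margaritifera margaritifera* track warmer
#' summer conditions.
#'
#' @param length_mm Shell length L in mm (vectorised).
#' @param width_mm Shell width W in mm (vectorised).
#' @return Numeric vector of SCI values (dimensionless, scaled by 100).
#' @examples
#' shell_sci(100, 30) # 30
#' @export
shell_sci <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop("invalid measurement: shell length must be positive and finite")
  }
  100 * width_mm / length_mm
}

#' Integrated shell convexity index (SCI_I)
#'
#' Width relative to the square root of the sagittal area,
#' `100 * W / sqrt(pi * L * H)`. The sagittal area is taken as
#' `pi * L * H`; the conventional 1/4 ellipse factor is deliberately
#' absorbed into the index scale, so SCI_I is comparable across shells but
#' not an areal ratio in the strict geometric sense. SCI_I is an exact
#' algebraic function of SCI: `SCI_I = SCI * sqrt(L / (pi * H))`.
#'
#' @param length_mm,height_mm,width_mm Shell dimensions in mm (vectorised).
#' @return Numeric vector of SCI_I values.
#' @export
shell_sci_integrated <- function(length_mm, height_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0) ||
      any(!is.finite(height_mm)) || any(height_mm <= 0)) {
    stop("invalid measurement: shell length and height must be positive and finite")
  }
  100 * width_mm / sqrt(pi * length_mm * height_mm)
}

#' Read a shell measurement table
#'
#' Reads a CSV with one row per measured shell. Required columns:
#' `shell_id, population_id, length_mm, height_mm, width_mm, year, lat,
#' lon, altitude_m, status`. Measurement invariants
#' (`length_mm >= height_mm > 0`, `0 < width_mm < length_mm`) are checked
#' and violations raise an error naming the offending shells.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of shell records.
#' @export
read_shells <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_shells(x)
}

#' Validate shell records
#'
#' @param shells Data frame of shell records (see [read_shells()]).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_shells <- function(shells) {
  need <- c("shell_id", "population_id", "length_mm", "height_mm",
            "width_mm", "year", "lat", "lon", "altitude_m", "status")
  miss <- setdiff(need, names(shells))
  if (length(miss) > 0) {
    stop("shell table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- with(shells, !(length_mm >= height_mm & height_mm > 0 &
                          width_mm > 0 & width_mm < length_mm))
  if (any(bad)) {
    stop("invalid measurement for shell(s): ",
         paste(utils::head(shells$shell_id[bad], 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "")
  }
  shells
}

#' Exclude small (ontogenetically immature) shells
#'
#' Shells shorter than `min_length_mm` are removed before any index is
#' aggregated, to limit ontogenetic heterogeneity between populations.
#' The boundary is inclusive: a shell of exactly `min_length_mm` is kept.
#'
#' @param shells Data frame of shell records.
#' @param min_length_mm Minimum retained length in mm (default 50).
#' @return The filtered data frame; the number of removed rows is reported
#'   via `message()`, and an empty result raises a warning (not an error).
#' @export
filter_shells <- function(shells, min_length_mm = 50) {
  keep <- shells$length_mm >= min_length_mm
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_shells: removed %d of %d shells (length < %g mm)",
                    n_removed, nrow(shells), min_length_mm))
  }
  out <- shells[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("filter_shells: no shells retained")
  }
  out
}

#' Aggregate shells into population samples
#'
#' Population means are the unit of all inter-population inference: the
#' population mean SCI is the arithmetic mean of per-shell SCI values (not
#' the SCI of the mean shell), and its s.e.m. is the sample standard
#' deviation over sqrt(n). Samples below the status-specific minimum size
#' (historical >= 5 shells, recent >= 11) are flagged via the `excluded`
#' column and should be left out of inference.
#'
#' @param shells Data frame of (already filtered) shell records.
#' @param historical_cutoff Collection year at or before which a sample is
#'   labelled `historical` (default 1950); `status == "historical"` also
#'   forces the label.
#' @param min_n Named minimum sample sizes, `c(historical = 5, recent = 11)`.
#' @return A `data.frame` with one row per population: `population_id,
#'   n_shells, mean_sci, sem_sci, mean_length_mm, mean_height_mm,
#'   mean_width_mm, status, period, lat, lon, altitude_m, year, excluded`.
#' @export
aggregate_populations <- function(shells, historical_cutoff = 1950,
                                  min_n = c(historical = 5, recent = 11)) {
  if (nrow(shells) == 0) stop("no shell records to aggregate")
  shells$sci <- shell_sci(shells$length_mm, shells$width_mm)
  agg <- lapply(split(shells, shells$population_id), function(d) {
    n <- nrow(d)
    period <- if (d$status[1] == "historical" || d$year[1] <= historical_cutoff)
      "historical" else "recent"
    data.frame(
      population_id = d$population_id[1],
      n_shells = n,
      mean_sci = mean(d$sci),
      sem_sci = if (n > 1) stats::sd(d$sci) / sqrt(n) else NA_real_,
      mean_length_mm = mean(d$length_mm),
      mean_height_mm = mean(d$height_mm),
      mean_width_mm = mean(d$width_mm),
      status = d$status[1],
      period = period,
      lat = d$lat[1],
      lon = d$lon[1],
      altitude_m = d$altitude_m[1],
      year = d$year[1],
      excluded = n < unname(min_n[period]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (any(out$excluded)) {
    message(sprintf("aggregate_populations: %d sample(s) below minimum n, flagged",
                    sum(out$excluded)))
  }
  out
}

#' Pooled-variance two-sample t-test on population mean SCI
#'
#' Student's t-test with pooled variance (not Welch), so the degrees of
#' freedom are `n_a + n_b - 2`. Inputs may be numeric vectors of
#' population means or population data frames (column `mean_sci`).
#'
#' @param group_a,group_b Numeric vectors or population data frames.
#' @return List with `t`, `df`, `p`, and the two group means.
#' @export
compare_group_means <- function(group_a, group_b) {
  a <- if (is.data.frame(group_a)) group_a$mean_sci else group_a
  b <- if (is.data.frame(group_b)) group_b$mean_sci else group_b
  if (length(a) < 2 || length(b) < 2) {
    stop("insufficient data: each group needs at least 2 population means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p_hat <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(p_hat - (i - 1) / n, i / n - p_hat))
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' KS statistic against a normal with estimated mean and sd; the p-value
#' is obtained by Monte-Carlo simulation of the null distribution (default
#' 10^4 draws under an internal fixed seed, so repeated calls agree),
#' because closed-form Lilliefors p approximations are inexact.
#'
#' @param values Numeric vector, n >= 4 and not constant.
#' @param nsim Number of Monte-Carlo null draws (default 10000).
#' @return List with `statistic`, `p`, and `n`.
#' @export
normality_check <- function(values, nsim = 10000) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("normality_check requires n >= 4")
  if (stats::sd(values) == 0) stop("degenerate distribution: input is constant")
  d_obs <- lilliefors_stat(values)
  # null distribution is location/scale free: simulate standard normals
  d_null <- local_seed(20160101, {
    vapply(seq_len(nsim), function(i) lilliefors_stat(stats::rnorm(n)),
           numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (nsim + 1)
  list(statistic = d_obs, p = p, n = n)
}

#' ANCOVA-style GLM of shell width on length and a population grouping
#'
#' Fits `mean_width ~ mean_length * group` on population means, reports
#' Type III (marginal) sums of squares per term, and simplifies to the
#' minimal adequate model by sequential exclusion of non-significant terms
#' (interaction first, then main effects) at `alpha`.
#'
#' @param populations Population data frame (columns `mean_width_mm`,
#'   `mean_length_mm`, and the grouping column).
#' @param group_col Name of the two-level grouping column (default
#'   `"status"`).
#' @param alpha Exclusion threshold (default 0.05).
#' @return List of class `width_glm`: `terms` (term, ss, df, f, p for the
#'   final model), `r_squared`, `retained_terms`, `model` (the `lm` fit).
#' @export
fit_width_glm <- function(populations, group_col = "status", alpha = 0.05) {
  d <- data.frame(width = populations$mean_width_mm,
                  length = populations$mean_length_mm,
                  group = factor(populations[[group_col]]))
  if (nlevels(d$group) != 2) stop("grouping factor must have exactly two levels")
  if (any(table(d$group) < 3)) {
    stop("model-fit error: need at least 3 populations per group level")
  }
  fit_terms <- function(formula) {
    m <- stats::lm(formula, data = d,
                   contrasts = if (grepl("group", deparse(formula)))
                     list(group = "contr.sum") else NULL)
    a <- car::Anova(m, type = 3)
    tab <- data.frame(term = rownames(a),
                      ss = a[["Sum Sq"]],
                      df = a[["Df"]],
                      f = a[["F value"]],
                      p = a[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
    list(model = m, table = tab)
  }
  candidates <- c("length:group", "length", "group")
  current <- c("length", "group", "length:group")
  repeat {
    f <- stats::reformulate(if (length(current)) current else "1",
                            response = "width")
    ft <- fit_terms(f)
    tab <- ft$table
    droppable <- intersect(current, tab$term[!is.na(tab$p) & tab$p >= alpha])
    # marginality: main effects cannot leave while the interaction stays
    if ("length:group" %in% current) {
      droppable <- intersect(droppable, "length:group")
    }
    if (length(droppable) == 0) break
    # drop the least significant droppable term, interaction first
    droppable <- droppable[order(match(droppable, candidates))]
    worst <- droppable[which.max(tab$p[match(droppable, tab$term)])]
    current <- setdiff(current, worst)
  }
  if (any(is.na(ft$table$f[ft$table$term != "(Intercept)"]) &
          ft$table$df[ft$table$term != "(Intercept)"] == 0)) {
    stop("model-fit error: degenerate (collinear) design")
  }
  structure(list(terms = ft$table,
                 r_squared = summary(ft$model)$r.squared,
                 retained_terms = current,
                 model = ft$model),
            class = "width_glm")
}

#' @export
print.width_glm <- function(x, ...) {
  cat("Shell-width GLM (Type III SS), minimal adequate model\n")
  cat("Retained terms:", if (length(x$retained_terms))
    paste(x$retained_terms, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Separate-slopes test: does latitude act differently by period?
#'
#' Compares the full model (period-specific intercepts and latitude
#' slopes for the population mean SCI) against the common single-line
#' model by an F-test with 2 numerator degrees of freedom.
#'
#' @param populations Population data frame with columns `mean_sci`,
#'   `lat`, and a two-level `period` column.
#' @return List with `f`, `df_num` (always 2), `df_den`, `p`, and the two
#'   fitted models.
#' @export
separate_slopes_test <- function(populations) {
  if (any(is.na(populations$lat))) stop("missing latitude")
  d <- data.frame(sci = populations$mean_sci,
                  latitude = populations$lat,
                  period = factor(populations$period))
  if (nlevels(d$period) != 2) stop("period must have exactly two levels")
  if (any(table(d$period) < 3)) stop("need at least 3 populations per period")
  full <- stats::lm(sci ~ period + period:latitude, data = d)
  common <- stats::lm(sci ~ latitude, data = d)
  av <- stats::anova(common, full)
  list(f = av$F[2], df_num = as.integer(av$Df[2]),
       df_den = stats::df.residual(full),
       p = av$`Pr(>F)`[2], full = full, common = common)
}

#' Spearman rank correlation (average-rank ties)
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @return List with `rho`, `p`, `n`.
#' @export
rank_correlation <- function(x, y) {
  check_corr_input(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  check_corr_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5) stop("correlation requires n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  invisible(NULL)
}

# Evaluate expr under a temporary RNG state, restoring the caller's stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
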