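#' Two-way ANOVA of the fractionation factor (time x shed)
#'
#' Classical two-way analysis of variance without replication on a complete
#' matrix of fractionation factors, rows = sampling times (months), columns
#' = sheds. The mean squares partition the variance of alpha between the
#' seasonal signal (rows), persistent shed differences (columns) and the
#' residual (analytical error plus metabolic fluctuation). On herd-survey
#' data the seasonal component dominates.
#'
#' @param alpha_matrix Numeric matrix, rows = sampling times, columns =
#'   sheds, one observation per cell, no missing values.
#' @return An object of class `alpha_anova`: a list with `table` (data frame
#'   of df, sum of squares and mean squares for rows, columns and error) and
#'   the variance components `s2_row`, `s2_col`, `s2_error` (the mean
#'   squares).
#' @export
two_way_anova <- function(alpha_matrix) {
  m <- as.matrix(alpha_matrix)
  if (!is.numeric(m)) stop("`alpha_matrix` must be numeric", call. = FALSE)
  if (anyNA(m)) {
    stop("incomplete design: `alpha_matrix` has missing cells", call. = FALSE)
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  d <- data.frame(
    y = as.vector(m),
    row = factor(as.vector(row(m))),
    col = factor(as.vector(col(m)))
  )
  fit <- stats::aov(y ~ row + col, data = d)
  tab <- summary(fit)[[1]]
  out <- list(
    table = data.frame(
      term = c("time (rows)", "shed (columns)", "error"),
      df = tab[["Df"]],
      sum_sq = tab[["Sum Sq"]],
      mean_sq = tab[["Mean Sq"]]
    ),
    s2_row = tab[["Mean Sq"]][1L],
    s2_col = tab[["Mean Sq"]][2L],
    s2_error = tab[["Mean Sq"]][3L]
  )
  class(out) <- "alpha_anova"
  out
}

#' @export
print.alpha_anova <- function(x, ...) {
  cat("Two-way ANOVA of the fractionation factor (no replication)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

.records_alpha <- function(records) {
  if (!is.null(records$alpha)) return(records$alpha)
  compute_alpha(records$d18O_M, records$d18O_W)
}

#' Per-shed regression of the fractionation factor on temperature
#'
#' Within one shed the oxygen fractionation factor rises linearly with the
#' mean air temperature of the two weeks before sampling (the time a cow
#' needs to equilibrate its body water with ingested water):
#' `alpha = B * T + A`. Herds kept outdoors in summer show markedly larger
#' slopes because grazing adds evapotranspirative enrichment.
#'
#' @param records Data frame of samples from a single shed with columns
#'   `d18O_M`, `d18O_W` (or a precomputed `alpha`) and `temp_2wk` (degrees
#'   Celsius). Rows with missing temperature are skipped and counted.
#' @return An object of class `alpha_temp_fit`: `shed_id`, `slope` (per
#'   degree Celsius), `slope_se`, `intercept`, `r` (correlation
#'   coefficient), `n`, `n_skipped`.
#' @export
fit_alpha_vs_temperature <- function(records) {
  if (!is.null(records$shed_id) && length(unique(records$shed_id)) > 1) {
    stop("`records` must come from a single shed", call. = FALSE)
  }
  alpha <- .records_alpha(records)
  temp <- records$temp_2wk
  if (is.null(temp)) {
    stop("insufficient data: no `temp_2wk` column", call. = FALSE)
  }
  ok <- is.finite(alpha) & is.finite(temp)
  n_skipped <- sum(!ok)
  alpha <- alpha[ok]
  temp <- temp[ok]
  if (length(alpha) < 3) {
    stop("insufficient data: fewer than 3 records with temperature",
         call. = FALSE)
  }
  fit <- stats::lm(alpha ~ temp)
  sm <- suppressWarnings(summary(fit))
  out <- list(
    shed_id = if (is.null(records$shed_id)) NA_character_
              else as.character(records$shed_id[1L]),
    slope = unname(stats::coef(fit)[2L]),
    slope_se = sm$coefficients[2L, 2L],
    intercept = unname(stats::coef(fit)[1L]),
    r = stats::cor(temp, alpha),
    n = length(alpha),
    n_skipped = n_skipped
  )
  class(out) <- "alpha_temp_fit"
  out
}

#' @export
print.alpha_temp_fit <- function(x, ...) {
  cat(sprintf(
    "alpha ~ temperature, shed %s: B = %.3g per degC (se %.2g), R = %.2f, n = %d\n",
    x$shed_id, x$slope, x$slope_se, x$r, x$n))
  if (x$n_skipped > 0) {
    cat("  skipped", x$n_skipped, "record(s) without temperature\n")
  }
  invisible(x)
}

#' Correlation of the deuterium-excess difference with temperature
#'
#' Pearson correlation between `d_ex,W - d_ex,M` (the deuterium excess of
#' farm water minus that of milk water, per mil) and the two-week mean
#' temperature. Metabolic enrichment of milk water behaves like evaporation,
#' so warmer periods depress the milk deuterium excess and the difference
#' grows with temperature.
#'
#' @param records Data frame with columns `d2H_W`, `d18O_W`, `d2H_M`,
#'   `d18O_M` and `temp_2wk`.
#' @return The correlation coefficient, or `NA` (with a warning) when it is
#'   not computable because either variable is constant.
#' @export
dex_temperature_correlation <- function(records) {
  need <- c("d2H_W", "d18O_W", "d2H_M", "d18O_M", "temp_2wk")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("insufficient data: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  diff_dex <- deuterium_excess(records$d2H_W, records$d18O_W) -
    deuterium_excess(records$d2H_M, records$d18O_M)
  temp <- records$temp_2wk
  ok <- is.finite(diff_dex) & is.finite(temp)
  if (sum(ok) < 3) {
    stop("insufficient data: fewer than 3 complete records", call. = FALSE)
  }
  if (stats::sd(temp[ok]) == 0 || stats::sd(diff_dex[ok]) == 0) {
    warning("correlation not computable: zero variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(diff_dex[ok], temp[ok])
}

#' Cold- and warm-period milk-on-water regressions
#'
#' Splits the herd records into the cold period (November-April) and warm
#' period (May-October), regresses the per-shed period-mean milk-water
#' delta18O on the per-shed period-mean farm-water delta18O in each period,
#' and tests the equality of the two slopes (t test on the slope difference
#' with pooled residual variance). For indoor herds the two lines are
#' parallel and differ only in intercept: summer enrichment shifts the milk
#' values upward without changing the milk-water coupling.
#'
#' @param records Data frame with `shed_id`, `d18O_W`, `d18O_M`, and either
#'   a `month` column (1..12) or a `t`/`date` column from which the month is
#'   derived.
#' @return An object of class `periodic_fits`: `cold` and `warm`
#'   ([fit_water_line()]-style fits of milk on water), `p_same_slope`, and
#'   `intercept_diff` (warm minus cold, per mil).
#' @export
periodic_regressions <- function(records) {
  month <- records$month
  if (is.null(month)) {
    t <- records$t
    if (is.null(t) && !is.null(records$date)) t <- day_number(records$date)
    if (is.null(t)) {
      stop("records need a `month`, `t` or `date` column", call. = FALSE)
    }
    month <- .month_of_day(t)
  }
  warm <- month %in% 5:10
  fit_period <- function(keep, label) {
    sub <- records[keep, , drop = FALSE]
    means <- stats::aggregate(sub[, c("d18O_W", "d18O_M")],
                              by = list(shed_id = sub$shed_id), FUN = mean)
    if (nrow(means) < 3) {
      stop("insufficient data: fewer than 3 sheds in the ", label,
           " period", call. = FALSE)
    }
    fit <- stats::lm(d18O_M ~ d18O_W, data = means)
    sm <- summary(fit)
    list(
      slope = unname(stats::coef(fit)[2L]),
      slope_se = sm$coefficients[2L, 2L],
      intercept = unname(stats::coef(fit)[1L]),
      intercept_se = sm$coefficients[1L, 2L],
      r_squared = sm$r.squared,
      s_yx = sm$sigma,
      n = nrow(means),
      sse = sum(stats::residuals(fit)^2),
      sxx = sum((means$d18O_W - mean(means$d18O_W))^2)
    )
  }
  cold <- fit_period(!warm, "cold")
  wrm <- fit_period(warm, "warm")
  df <- cold$n + wrm$n - 4L
  sp2 <- (cold$sse + wrm$sse) / df
  se_diff <- sqrt(sp2 * (1 / cold$sxx + 1 / wrm$sxx))
  tstat <- if (se_diff == 0) 0 else (wrm$slope - cold$slope) / se_diff
  out <- list(
    cold = cold,
    warm = wrm,
    p_same_slope = 2 * stats::pt(-abs(tstat), df),
    intercept_diff = wrm$intercept - cold$intercept
  )
  class(out) <- "periodic_fits"
  out
}

#' @export
print.periodic_fits <- function(x, ...) {
  line <- function(f, lab) {
    cat(sprintf("  %s: d18O_M = %.3f (+/- %.3f) d18O_W %+.2f (+/- %.2f), n = %d sheds\n",
                lab, f$slope, f$slope_se, f$intercept, f$intercept_se, f$n))
  }
  cat("Cold/warm-period milk-on-water regressions (per-shed means)\n")
  line(x$cold, "cold (Nov-Apr)")
  line(x$warm, "warm (May-Oct)")
  cat(sprintf("  equal-slope test: p = %.2f; intercept shift = %.2f permil\n",
              x$p_same_slope, x$intercept_diff))
  invisible(x)
}
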