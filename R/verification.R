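#' Combined standard uncertainty for the fractionation-factor comparison
#'
#' Because alpha and the delta values are all close to 1 (in ratio terms),
#' the uncertainty of the difference between a measured and a
#' calibration-predicted fractionation factor is, to good approximation, the
#' root sum of squares of the milk delta18O uncertainty, the farm-water
#' delta18O uncertainty and the calibration prediction uncertainty, all in
#' per mil.
#'
#' @param u_delta_M Milk-water delta18O measurement uncertainty (per mil).
#' @param u_delta_W Farm-water delta18O measurement uncertainty (per mil).
#' @param u_alpha_hat Prediction uncertainty of the alpha calibration
#'   (per mil), see [alpha_prediction_uncertainty()].
#' @return Combined uncertainty in per mil. With the default measurement
#'   uncertainties and the bundled indoor calibration this is 0.45 per mil.
#' @export
#' @examples
#' combined_uncertainty(0.15, 0.08, 0.42)
combined_uncertainty <- function(u_delta_M, u_delta_W, u_alpha_hat) {
  u <- c(u_delta_M, u_delta_W, u_alpha_hat)
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("invalid uncertainty: all inputs must be finite and >= 0",
         call. = FALSE)
  }
  sqrt(u_delta_M^2 + u_delta_W^2 + u_alpha_hat^2)
}

#' Step 1: seasonal-band check of the milk-water delta18O
#'
#' A milk sample declared to have been milked at day number `t` is
#' compatible with the region when its measured delta18O lies within
#' `coverage * s_yx` of the seasonal calibration prediction (about 90% of
#' the calibration population at the default coverage 1.645). Equality with
#' the threshold passes.
#'
#' @param delta18O_M Measured milk-water delta18O (per mil).
#' @param t Day number of milking (1..365).
#' @param calib Milk-water delta18O calibration (default: bundled regional
#'   calibration, threshold 1.645 x 0.92 = 1.51 per mil).
#' @param coverage Coverage factor.
#' @return A list with `measured`, `predicted`, `delta` (absolute
#'   difference, per mil), `threshold` (per mil) and `pass`.
#' @export
#' @examples
#' verify_step1(-8.16, 20)
verify_step1 <- function(delta18O_M, t,
                         calib = milk_calibration("milk_d18O"),
                         coverage = 1.645) {
  .check_delta(delta18O_M, "delta18O_M")
  predicted <- predict_milk_delta(t, calib, coverage = coverage)$fit
  delta <- abs(delta18O_M - predicted)
  threshold <- coverage * calib$s_yx
  list(measured = delta18O_M, predicted = predicted, delta = delta,
       threshold = threshold, pass = delta <= threshold)
}

#' Step 2: fractionation-factor compatibility with the farm water
#'
#' Computes the measured fractionation factor from the milk and farm-water
#' delta18O values, compares it with the calibration prediction at the same
#' day number, and passes when the absolute difference (reported in per mil,
#' i.e. x1000) does not exceed the combined uncertainty. Equality passes.
#'
#' @param delta18O_M Measured milk-water delta18O (per mil).
#' @param delta18O_W Measured farm-water (or regional groundwater) delta18O
#'   (per mil).
#' @param t Day number of milking (1..365).
#' @param calib Fractionation-factor calibration (default: bundled
#'   indoor-herd calibration).
#' @param threshold Decision threshold in per mil; by default the combined
#'   uncertainty of the measurements and the calibration (0.45 per mil for
#'   the defaults).
#' @param u_delta_M,u_delta_W Measurement uncertainties (per mil) used when
#'   `threshold` is not supplied.
#' @return A list with `alpha_measured`, `alpha_predicted`, `delta_permil`,
#'   `threshold` (per mil) and `pass`.
#' @export
#' @examples
#' verify_step2(-8.16, -8.78, 20)
verify_step2 <- function(delta18O_M, delta18O_W, t,
                         calib = milk_calibration("alpha_indoor"),
                         threshold = NULL,
                         u_delta_M = default_uncertainties()[["milk_water_O"]],
                         u_delta_W = default_uncertainties()[["farm_water_O"]]) {
  alpha_m <- compute_alpha(delta18O_M, delta18O_W)
  alpha_hat <- predict_alpha(t, calib)
  if (is.null(threshold)) {
    threshold <- combined_uncertainty(u_delta_M, u_delta_W,
                                      alpha_prediction_uncertainty(calib))
  }
  delta_permil <- 1000 * abs(alpha_m - alpha_hat)
  list(alpha_measured = alpha_m, alpha_predicted = alpha_hat,
       delta_permil = delta_permil, threshold = threshold,
       pass = delta_permil <= threshold)
}

#' Two-step provenance verification of a milk sample
#'
#' Runs the two-step regional-compatibility check on one sample record:
#' step 1 tests the milk-water delta18O against the seasonal band of the
#' regional calibration; step 2 tests the measured milk/farm-water
#' fractionation factor against the seasonal alpha calibration within the
#' propagated uncertainty. The sample is compatible with the region only if
#' both steps pass. When the farm water was not sampled, a regional
#' groundwater delta18O may be supplied in its place; without either, step 2
#' is skipped and the overall verdict is undetermined (`NA`), never a pass.
#'
#' @param record A list or one-row data frame with `d18O_M`, optionally
#'   `d18O_W`, and `t` (day number) or `date` (`DD/MM/YYYY`). An explicit
#'   `t` takes precedence over the date.
#' @param calib_delta Milk-water delta18O calibration for step 1.
#' @param calib_alpha Fractionation-factor calibration for step 2. Use
#'   `milk_calibration("alpha_all")` for herds grazing outdoors in summer.
#' @param groundwater_d18O Regional groundwater delta18O (per mil) used for
#'   step 2 when `record$d18O_W` is missing.
#' @param coverage Coverage factor for step 1.
#' @param threshold2 Step-2 threshold in per mil (default: combined
#'   uncertainty, see [verify_step2()]).
#' @return An object of class `milk_verification` with elements `step1`,
#'   `step2` (or the string reason when skipped), `overall` (`TRUE`,
#'   `FALSE`, or `NA` when undetermined), `water_source` and the calibration
#'   names used.
#' @export
#' @examples
#' verify(list(d18O_M = -8.16, d18O_W = -8.78, t = 20))
verify <- function(record,
                   calib_delta = milk_calibration("milk_d18O"),
                   calib_alpha = milk_calibration("alpha_indoor"),
                   groundwater_d18O = NULL,
                   coverage = 1.645,
                   threshold2 = NULL) {
  d18O_M <- record$d18O_M
  if (is.null(d18O_M) || !is.finite(d18O_M)) {
    stop("invalid record: missing milk-water d18O_M", call. = FALSE)
  }
  t <- record$t
  if (is.null(t) || !is.finite(t)) {
    if (is.null(record$date)) {
      stop("invalid record: needs `t` or `date`", call. = FALSE)
    }
    t <- day_number(record$date)
  }
  step1 <- verify_step1(d18O_M, t, calib_delta, coverage = coverage)

  d18O_W <- record$d18O_W
  water_source <- "farm_water"
  if (is.null(d18O_W) || !is.finite(d18O_W)) {
    if (!is.null(groundwater_d18O)) {
      d18O_W <- groundwater_d18O
      water_source <- "groundwater"
    } else {
      d18O_W <- NA_real_
      water_source <- "none"
    }
  }
  if (is.na(d18O_W)) {
    step2 <- "skipped: no water value"
    overall <- NA
  } else {
    step2 <- verify_step2(d18O_M, d18O_W, t, calib_alpha,
                          threshold = threshold2)
    overall <- step1$pass && step2$pass
  }
  out <- list(
    shed_id = if (is.null(record$shed_id)) NA_character_
              else as.character(record$shed_id),
    t = t,
    step1 = step1,
    step2 = step2,
    overall = overall,
    water_source = water_source,
    calib_delta = calib_delta$name,
    calib_alpha = calib_alpha$name
  )
  class(out) <- "milk_verification"
  out
}

#' @export
print.milk_verification <- function(x, ...) {
  cat(sprintf("Milk provenance check%s (t = %d)\n",
              if (is.na(x$shed_id)) "" else paste0(" for ", x$shed_id),
              as.integer(x$t)))
  cat(sprintf(
    "  step 1 (d18O_M vs '%s'): measured %.2f, predicted %.2f, |diff| %.2f <= %.2f permil: %s\n",
    x$calib_delta, x$step1$measured, x$step1$predicted, x$step1$delta,
    x$step1$threshold, ifelse(x$step1$pass, "PASS", "FAIL")))
  if (is.character(x$step2)) {
    cat("  step 2:", x$step2, "\n")
  } else {
    cat(sprintf(
      "  step 2 (alpha vs '%s', %s): measured %.6f, predicted %.6f, |diff| %.2f <= %.2f permil: %s\n",
      x$calib_alpha, x$water_source, x$step2$alpha_measured,
      x$step2$alpha_predicted, x$step2$delta_permil, x$step2$threshold,
      ifelse(x$step2$pass, "PASS", "FAIL")))
  }
  cat("  overall:",
      if (is.na(x$overall)) "UNDETERMINED (step 2 not performed)"
      else if (x$overall) "COMPATIBLE with the region"
      else "NOT compatible with the region", "\n")
  invisible(x)
}

#' Verify a table of milk samples
#'
#' Applies [verify()] to every row of a sample table and assembles a report
#' mirroring the columns of a verification table: inputs, calculated values,
#' per-step differences and verdicts.
#'
#' @param records Data frame of sample records (see [read_samples()]).
#' @param ... Passed to [verify()] (calibrations, groundwater fallback,
#'   coverage, thresholds).
#' @return Data frame with one row per sample: `shed_id`, `date`, `t`,
#'   `d18O_W`, `d18O_M`, `d18O_M_pred`, `delta1_permil`, `step1_pass`,
#'   `alpha_m`, `alpha_hat`, `delta2_permil`, `step2_pass`, `overall`.
#' @export
verify_samples <- function(records, ...) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("no records to verify", call. = FALSE)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- as.list(records[i, , drop = FALSE])
    v <- verify(rec, ...)
    skipped <- is.character(v$step2)
    data.frame(
      shed_id = v$shed_id,
      date = if (is.null(rec$date)) NA_character_ else as.character(rec$date),
      t = as.integer(v$t),
      d18O_W = if (is.null(rec$d18O_W)) NA_real_ else rec$d18O_W,
      d18O_M = rec$d18O_M,
      d18O_M_pred = v$step1$predicted,
      delta1_permil = v$step1$delta,
      step1_pass = v$step1$pass,
      alpha_m = if (skipped) NA_real_ else v$step2$alpha_measured,
      alpha_hat = if (skipped) NA_real_ else v$step2$alpha_predicted,
      delta2_permil = if (skipped) NA_real_ else v$step2$delta_permil,
      step2_pass = if (skipped) NA else v$step2$pass,
      overall = v$overall
    )
  })
  do.call(rbind, rows)
}
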