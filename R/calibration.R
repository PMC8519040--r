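#' Dual-isotope water line
#'
#' Ordinary least-squares regression of delta2H on delta18O, the standard
#' "water line" of isotope hydrology. Farm (drinking) waters fall close to
#' the local meteoric water line (slope near 8); milk waters define a line
#' of lower slope, the signature of evaporation-like metabolic enrichment.
#'
#' @param delta18O Oxygen delta values, per mil vs VSMOW (the predictor).
#' @param delta2H Hydrogen delta values, per mil vs VSMOW (the response).
#' @return An object of class `water_line`: a list with `slope`, `slope_se`,
#'   `intercept`, `intercept_se` (per mil), `r_squared`, `s_yx` (standard
#'   error of the regression, per mil) and `n`.
#' @export
#' @examples
#' x <- c(-11, -10, -9, -8)
#' fit_water_line(x, 8.3 * x + 16)
fit_water_line <- function(delta18O, delta2H) {
  .check_delta(delta18O, "delta18O")
  .check_delta(delta2H, "delta2H")
  n <- length(delta18O)
  if (length(delta2H) != n) {
    stop("`delta18O` and `delta2H` must have the same length", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 pairs to fit a water line", call. = FALSE)
  if (stats::var(delta18O) == 0) {
    stop("singular fit: all delta18O values are equal", call. = FALSE)
  }
  fit <- stats::lm(delta2H ~ delta18O)
  sm <- suppressWarnings(summary(fit)) # exact fits trip a summary.lm warning
  out <- list(
    slope = unname(stats::coef(fit)[2L]),
    slope_se = sm$coefficients[2L, 2L],
    intercept = unname(stats::coef(fit)[1L]),
    intercept_se = sm$coefficients[1L, 2L],
    r_squared = sm$r.squared,
    s_yx = sm$sigma,
    n = n,
    residuals = unname(stats::residuals(fit))
  )
  class(out) <- "water_line"
  out
}

#' @export
coef.water_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.water_line <- function(object, delta18O, ...) {
  object$intercept + object$slope * delta18O
}

#' @export
print.water_line <- function(x, ...) {
  cat(sprintf(
    "Water line: d2H = %.2f (+/- %.2f) d18O %+.1f (+/- %.1f) permil\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  n = %d, R^2 = %.2f, s(yx) = %.1f permil\n",
              x$n, x$r_squared, x$s_yx))
  invisible(x)
}

.poly_eval <- function(coefficients, t) {
  # Horner evaluation, coefficients in descending power order
  out <- rep(0, length(t))
  for (co in coefficients) out <- out * t + co
  out
}

#' Construct a seasonal quartic calibration
#'
#' A quartic (4th-order polynomial) in the day number `t` describing the
#' seasonal course of either the milk-water oxygen delta (per mil) or of the
#' milk/farm-water fractionation factor (dimensionless). Normally produced
#' by [fit_quartic()] or taken from the bundled defaults
#' ([milk_calibration()]); this constructor also lets users supply published
#' coefficients directly.
#'
#' @param coefficients Numeric length-5 vector, descending powers of `t`
#'   (t^4 coefficient first), in the natural units of the response.
#' @param n Number of observations behind the calibration.
#' @param s_yx Standard error of the regression, in per mil (for a
#'   fractionation-factor calibration this is `1000 *` the residual standard
#'   deviation of alpha).
#' @param response `"milk_d18O"` (response in per mil) or `"alpha"`
#'   (dimensionless response; per-mil quantities are scaled by 1000).
#' @param r_squared Coefficient of determination (optional, `NA` if unknown).
#' @param u_pred Prediction uncertainty in per mil. If `NULL`, computed as
#'   `s_yx * sqrt(1 + 1/n)`. Supply a published constant to reproduce a
#'   published decision threshold exactly.
#' @param excluded_sheds Character vector of shed labels omitted from the
#'   fit (for provenance records).
#' @param name Identifier written into calibration files and reports.
#' @return An object of class `quartic_calibration`.
#' @export
quartic_calibration <- function(coefficients, n, s_yx,
                                response = c("milk_d18O", "alpha"),
                                r_squared = NA_real_, u_pred = NULL,
                                excluded_sheds = character(), name = NULL) {
  response <- match.arg(response)
  if (length(coefficients) != 5L || any(!is.finite(coefficients))) {
    stop("`coefficients` must be 5 finite numbers (descending powers)",
         call. = FALSE)
  }
  if (n < 6) stop("a quartic calibration needs n >= 6", call. = FALSE)
  if (s_yx < 0) stop("`s_yx` must be non-negative", call. = FALSE)
  out <- list(
    coefficients = as.numeric(coefficients),
    n = as.integer(n),
    s_yx = as.numeric(s_yx),         # per mil, on the reporting scale
    r_squared = r_squared,
    response = response,
    scale = if (response == "alpha") 1000 else 1,
    u_pred = if (is.null(u_pred)) s_yx * sqrt(1 + 1 / n) else u_pred,
    u_shipped = !is.null(u_pred),
    excluded_sheds = excluded_sheds,
    name = if (is.null(name)) response else name
  )
  class(out) <- "quartic_calibration"
  out
}

#' Fit a seasonal quartic calibration
#'
#' Least-squares quartic of a response (milk-water delta18O in per mil, or
#' the fractionation factor alpha) on the day number. The residual standard
#' error uses the residual degrees of freedom, `s_yx = sqrt(SSE / (n - 5))`.
#'
#' @param t Day numbers (1..365).
#' @param y Response values (per mil for `response = "milk_d18O"`,
#'   dimensionless for `response = "alpha"`).
#' @param shed_id Optional shed labels, required when `exclude` is used.
#' @param exclude Shed labels to omit from the fit (e.g. herds kept
#'   outdoors in summer, which sit above the common seasonal trend).
#' @param response See [quartic_calibration()].
#' @param name Optional identifier for the fitted calibration.
#' @return A [quartic_calibration()] object; `s_yx` and `u_pred` are in per
#'   mil on the reporting scale (alpha differences x1000).
#' @export
#' @examples
#' t <- seq(10, 360, by = 30)
#' y <- -8 + 1e-5 * (t - 180)^2 / 10
#' fit_quartic(t, y)
fit_quartic <- function(t, y, shed_id = NULL, exclude = NULL,
                        response = c("milk_d18O", "alpha"), name = NULL) {
  response <- match.arg(response)
  .check_day(t)
  if (length(t) != length(y)) {
    stop("`t` and `y` must have the same length", call. = FALSE)
  }
  if (!is.null(exclude)) {
    if (is.null(shed_id)) {
      stop("`shed_id` is required when `exclude` is given", call. = FALSE)
    }
    keep <- !(shed_id %in% exclude)
    t <- t[keep]
    y <- y[keep]
  }
  n <- length(t)
  if (n < 6) {
    stop("need at least 6 points after exclusion to fit a quartic",
         call. = FALSE)
  }
  if (length(unique(t)) < 5) {
    stop("singular fit: fewer than 5 distinct day numbers", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(t, 4, raw = TRUE))
  if (any(is.na(stats::coef(fit)))) {
    stop("singular fit: rank-deficient quartic design", call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))
  scale <- if (response == "alpha") 1000 else 1
  quartic_calibration(
    coefficients = rev(unname(stats::coef(fit))),
    n = n,
    s_yx = sm$sigma * scale,
    response = response,
    r_squared = sm$r.squared,
    excluded_sheds = if (is.null(exclude)) character() else exclude,
    name = name
  )
}

#' @export
coef.quartic_calibration <- function(object, ...) {
  stats::setNames(object$coefficients, c("t4", "t3", "t2", "t1", "t0"))
}

#' Predict from a seasonal quartic calibration
#'
#' Exact polynomial evaluation at the requested day numbers, together with
#' the one-sigma band (`fit +/- s_yx`) and the `coverage * s_yx` band used
#' by the provenance check (about 90% of the calibration population for the
#' default coverage factor 1.645).
#'
#' @param object A [quartic_calibration()].
#' @param t Day numbers (0..365).
#' @param coverage Coverage factor for the outer band.
#' @param ... Unused.
#' @return A data frame with columns `t`, `fit`, `lower_s`, `upper_s`
#'   (one-sigma band) and `lower`, `upper` (coverage band), in the natural
#'   units of the response.
#' @export
predict.quartic_calibration <- function(object, t, coverage = 1.645, ...) {
  .check_day(t)
  fit <- .poly_eval(object$coefficients, t)
  s_nat <- object$s_yx / object$scale
  data.frame(
    t = t,
    fit = fit,
    lower_s = fit - s_nat,
    upper_s = fit + s_nat,
    lower = fit - coverage * s_nat,
    upper = fit + coverage * s_nat
  )
}

#' @export
print.quartic_calibration <- function(x, ...) {
  cat(sprintf("Seasonal quartic calibration '%s' (%s)\n", x$name, x$response))
  cat("  coefficients (t^4 .. t^0): ",
      paste(format(x$coefficients, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  n = %d, R^2 = %s, s(yx) = %.2f permil, u_pred = %.2f permil\n",
              x$n, ifelse(is.na(x$r_squared), "NA",
                          format(x$r_squared, digits = 2)),
              x$s_yx, x$u_pred))
  if (length(x$excluded_sheds)) {
    cat("  excluded sheds:", paste(x$excluded_sheds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predicted milk-water delta18O at a day number
#'
#' Evaluates a milk-water delta18O seasonal calibration and returns the
#' predicted value with its `+/- s_yx` and `+/- coverage * s_yx` bands.
#'
#' @param t Day number(s), 0..365.
#' @param calib A `quartic_calibration` with response `"milk_d18O"`;
#'   defaults to the bundled regional calibration.
#' @param coverage Coverage factor for the outer band (default 1.645,
#'   a two-sided 90% band under normal residuals).
#' @return Data frame as in [predict.quartic_calibration()], in per mil.
#' @export
#' @examples
#' predict_milk_delta(20)
predict_milk_delta <- function(t, calib = milk_calibration("milk_d18O"),
                               coverage = 1.645) {
  stopifnot(inherits(calib, "quartic_calibration"))
  if (calib$response != "milk_d18O") {
    stop("`calib` must be a milk_d18O calibration", call. = FALSE)
  }
  predict(calib, t, coverage = coverage)
}

#' Predicted fractionation factor at a day number
#'
#' Evaluates a fractionation-factor seasonal calibration at the given day
#' number(s) and returns the dimensionless alpha-hat.
#'
#' @param t Day number(s), 0..365.
#' @param calib A `quartic_calibration` with response `"alpha"`; defaults to
#'   the bundled indoor-herd calibration.
#' @return Numeric vector of predicted fractionation factors.
#' @export
#' @examples
#' predict_alpha(36)
predict_alpha <- function(t, calib = milk_calibration("alpha_indoor")) {
  stopifnot(inherits(calib, "quartic_calibration"))
  if (calib$response != "alpha") {
    stop("`calib` must be an alpha calibration", call. = FALSE)
  }
  .check_day(t)
  .poly_eval(calib$coefficients, t)
}

#' Approximate prediction uncertainty of a seasonal alpha calibration
#'
#' For a sample from a herd not used to build the calibration, the
#' prediction uncertainty is approximated as
#' \deqn{u = \sqrt{s_{yx}^2 + s_{yx}^2 / n}}
#' (per mil). Bundled calibrations carry the published constants instead of
#' the recomputed value so that published decision thresholds are matched
#' exactly; set `recompute = TRUE` to apply the formula regardless.
#'
#' @param calib A `quartic_calibration`.
#' @param recompute Ignore any stored constant and apply the formula.
#' @return Uncertainty in per mil.
#' @export
alpha_prediction_uncertainty <- function(calib, recompute = FALSE) {
  stopifnot(inherits(calib, "quartic_calibration"))
  if (recompute || is.null(calib$u_pred)) {
    return(calib$s_yx * sqrt(1 + 1 / calib$n))
  }
  calib$u_pred
}

#' LOESS smoothing of a seasonal series
#'
#' Locally weighted linear regression (tricube kernel, degree 1, no
#' robustness iterations) of a response on the day number, evaluated on a
#' grid. Used as a model-free cross-check of the quartic calibrations: on
#' the herd data the two curves nearly coincide.
#'
#' @param t Day numbers.
#' @param y Response values.
#' @param span Smoothing parameter: fraction of the points in each local
#'   window (default 0.2).
#' @param grid Day numbers at which to evaluate the smoother (default: the
#'   sorted unique `t`).
#' @return Data frame with columns `t` and `fit`.
#' @export
loess_smooth <- function(t, y, span = 0.2, grid = sort(unique(t))) {
  if (length(t) != length(y)) {
    stop("`t` and `y` must have the same length", call. = FALSE)
  }
  if (length(t) < 10) {
    stop("need at least 10 points to smooth", call. = FALSE)
  }
  if (ceiling(span * length(t)) < 3) {
    stop("window too small: `span` gives fewer than 3 points per window",
         call. = FALSE)
  }
  fit <- stats::loess(y ~ t, span = span, degree = 1, family = "gaussian",
                      surface = "direct",
                      control = stats::loess.control(iterations = 1))
  data.frame(t = grid,
             fit = unname(stats::predict(fit, newdata = data.frame(t = grid))))
}
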