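#' Default measurement uncertainties
#'
#' Standard prediction uncertainties of the isotope measurements, in per mil
#' (vs VSMOW), as routinely achieved by CO2/H2 equilibration IRMS on water:
#' farm water is measured more precisely than milk water because the latter
#' must first be recovered by centrifugation and vacuum distillation.
#'
#' @return Named numeric vector with elements `farm_water_O`, `farm_water_H`,
#'   `milk_water_O`, `milk_water_H` (all in per mil).
#' @export
#' @examples
#' default_uncertainties()["milk_water_O"]
default_uncertainties <- function() {
  c(farm_water_O = 0.08, farm_water_H = 1.0,
    milk_water_O = 0.15, milk_water_H = 1.5)
}

# delta values live on the per-mil scale; a ratio stays positive only while
# delta > -1000
.check_delta <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) {
    stop("invalid measurement: `", name, "` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("invalid measurement: `", name, "` contains non-finite values",
         call. = FALSE)
  }
  if (any(x <= -1000)) {
    stop("invalid measurement: `", name,
         "` must exceed -1000 per mil (isotope ratio must stay positive)",
         call. = FALSE)
  }
  invisible(x)
}

#' Milk/farm-water isotope fractionation factor
#'
#' The fractionation factor between milk water (M) and the water the herd
#' drinks (W) at the same sampling time,
#' \deqn{\alpha = \frac{\delta_M/10^3 + 1}{\delta_W/10^3 + 1},}
#' with both delta values in per mil vs VSMOW. `alpha > 1` means the milk
#' water is enriched in the heavy isotope relative to the farm water, as is
#' normally the case for lactating cows.
#'
#' @param delta_M Milk-water delta value(s), per mil vs VSMOW.
#' @param delta_W Farm-water delta value(s), per mil vs VSMOW.
#' @return Numeric vector of dimensionless fractionation factors.
#'   Differences between fractionation factors are conventionally reported
#'   in per mil, i.e. `1000 * (a1 - a2)`.
#' @seealso [milk_delta_from_alpha()] for the algebraic inverse,
#'   [predict_alpha()] for the seasonal calibration value.
#' @export
#' @examples
#' compute_alpha(-8.16, -8.78) # 1.000625
compute_alpha <- function(delta_M, delta_W) {
  .check_delta(delta_M, "delta_M")
  .check_delta(delta_W, "delta_W")
  (delta_M / 1000 + 1) / (delta_W / 1000 + 1)
}

#' Milk-water delta implied by a fractionation factor
#'
#' Inverts [compute_alpha()]: given a fractionation factor and the
#' farm-water delta it was referenced to, returns the milk-water delta (per
#' mil). Used by the synthetic herd generator to build milk values from a
#' seasonal alpha model.
#'
#' @param alpha Dimensionless fractionation factor(s), `> 0`.
#' @param delta_W Farm-water delta value(s), per mil vs VSMOW.
#' @return Milk-water delta value(s) in per mil, such that
#'   `compute_alpha(result, delta_W) == alpha` to machine precision.
#' @export
#' @examples
#' milk_delta_from_alpha(1.000625, -8.78)
milk_delta_from_alpha <- function(alpha, delta_W) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be a finite positive number", call. = FALSE)
  }
  .check_delta(delta_W, "delta_W")
  (alpha * (delta_W / 1000 + 1) - 1) * 1000
}

#' Deuterium excess
#'
#' `d_ex = delta2H - 8 * delta18O` (per mil). Points on the global meteoric
#' water line have `d_ex` near +10 per mil; evaporation (and the
#' evaporation-like metabolic enrichment of milk water) moves points below
#' the line and lowers `d_ex`.
#'
#' @param delta2H Hydrogen delta value(s), per mil vs VSMOW.
#' @param delta18O Oxygen delta value(s), per mil vs VSMOW.
#' @return Deuterium excess in per mil.
#' @export
#' @examples
#' deuterium_excess(-70, -10) # 10
deuterium_excess <- function(delta2H, delta18O) {
  .check_delta(delta2H, "delta2H")
  .check_delta(delta18O, "delta18O")
  delta2H - 8 * delta18O
}

# cumulative days before each month in a non-leap year
.MONTH_OFFSET <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L,
                   304L, 334L)
.MONTH_LENGTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Day number on the non-leap calendar
#'
#' Ordinal day of the year with 1 January = 1, always computed on the
#' non-leap calendar so that a given calendar date maps to the same day
#' number in every year (the seasonal calibrations are parameterised on this
#' convention). 29 February is therefore rejected.
#'
#' @param date A `Date` vector, or a character vector in `DD/MM/YYYY`
#'   format (the year is accepted for record-keeping but does not affect the
#'   day number).
#' @return Integer day number(s) in 1..365.
#' @export
#' @examples
#' day_number("20/01/2019") # 20
#' day_number("01/07/2019") # 182
day_number <- function(date) {
  if (inherits(date, "Date")) {
    lt <- as.POSIXlt(date)
    day <- lt$mday
    month <- lt$mon + 1L
  } else if (is.character(date)) {
    parts <- strsplit(date, "/", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 3L
    if (any(bad)) {
      stop("invalid date: expected DD/MM/YYYY, got ",
           paste(date[bad], collapse = ", "), call. = FALSE)
    }
    day <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    month <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    if (any(is.na(day)) || any(is.na(month))) {
      stop("invalid date: unparseable day or month in DD/MM/YYYY",
           call. = FALSE)
    }
  } else {
    stop("`date` must be a Date or a DD/MM/YYYY character vector",
         call. = FALSE)
  }
  if (any(month < 1L | month > 12L)) {
    stop("invalid date: month out of range", call. = FALSE)
  }
  if (any(month == 2L & day == 29L)) {
    stop("invalid date: 29 February has no day number on the non-leap calendar",
         call. = FALSE)
  }
  if (any(day < 1L | day > .MONTH_LENGTH[month])) {
    stop("invalid date: day out of range for month", call. = FALSE)
  }
  .MONTH_OFFSET[month] + day
}

# month (1..12) a non-leap day number falls in
.month_of_day <- function(t) {
  findInterval(t - 1L, .MONTH_OFFSET)
}

.check_day <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0) || any(t > 365)) {
    stop("day number `t` must lie in 0..365", call. = FALSE)
  }
  invisible(t)
}
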