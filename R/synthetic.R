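#' Configuration for the synthetic dairy-herd generator
#'
#' Describes a year of monthly milk and farm-water sampling across a set of
#' sheds with the statistical structure the provenance analysis assumes:
#' near-constant per-shed farm waters lying on a local meteoric water line,
#' a seasonal temperature cycle, a fractionation factor rising linearly with
#' the two-week mean temperature (with steeper effective slopes for herds
#' grazing outdoors in the warm months), and measurement noise at the
#' routine analytical uncertainties.
#'
#' Defaults emulate the Parmigiano-Reggiano herd survey: nine sheds with
#' farm-water delta18O spread over the observed regional range, water-line
#' slope 8.33 and intercept 16.3 per mil, temperature-slope coefficients of
#' alpha within the observed per-shed range, two outdoor sheds, milk
#' measurement noise 0.15 per mil (O) and 1.5 per mil (H).
#'
#' @param n_sheds Number of sheds.
#' @param shed_ids Shed labels.
#' @param water_d18O_means Per-shed farm-water delta18O means (per mil).
#' @param water_line_slope,water_line_intercept,water_line_scatter Local
#'   meteoric water line generating the per-shed farm-water delta2H means
#'   (slope, intercept in per mil, vertical scatter sd in per mil).
#' @param water_sd_O,water_sd_H Month-to-month sd of the farm water
#'   (per mil), measurement-level by default.
#' @param temp_mean,temp_amplitude,temp_peak_day,temp_daily_sd Annual
#'   sinusoidal air-temperature cycle (degrees Celsius; peak day on the
#'   non-leap calendar) plus day-to-day Gaussian noise.
#' @param alpha_intercept_mean,alpha_intercept_sd Per-shed baseline of the
#'   alpha-temperature relation `alpha = A_i + B_i * T`.
#' @param alpha_temp_slope_range Range (per degree Celsius) from which the
#'   per-shed slopes `B_i` are drawn uniformly.
#' @param outdoor_sheds Shed labels whose animals graze outdoors in the warm
#'   months (May-October).
#' @param outdoor_b_factor Multiplier applied to `B_i` of outdoor sheds
#'   during the warm months.
#' @param alpha_calibration Optional `quartic_calibration` (response
#'   `"alpha"`); when supplied, the seasonal alpha is taken from this curve
#'   instead of the temperature-linear model (shed baselines are ignored).
#' @param milk_noise_O,milk_noise_H Milk measurement noise sd (per mil).
#' @param h_enrichment_slope Slope of the evaporation-like hydrogen
#'   enrichment of milk water relative to its source water (delta2H per
#'   delta18O).
#' @param dex_temp_slope Additional temperature-driven depression of the
#'   milk deuterium excess (per mil per degree Celsius above the annual
#'   mean).
#' @param months Months sampled (1..12).
#' @param sampling_day Day of month on which samples are taken.
#' @param seed Default random seed used by the simulators.
#' @return An object of class `herd_config` (a validated list).
#' @export
#' @examples
#' cfg <- herd_config(seed = 42)
#' head(simulate_herd_year(cfg))
herd_config <- function(n_sheds = 9,
                        shed_ids = sprintf("S%d", seq_len(n_sheds)),
                        water_d18O_means = seq(-11.3, -7.9,
                                               length.out = n_sheds),
                        water_line_slope = 8.33,
                        water_line_intercept = 16.3,
                        water_line_scatter = 1.6,
                        water_sd_O = 0.08,
                        water_sd_H = 1.0,
                        temp_mean = 13.5,
                        temp_amplitude = 11.5,
                        temp_peak_day = 205,
                        temp_daily_sd = 2,
                        alpha_intercept_mean = 1.0002,
                        alpha_intercept_sd = 2e-4,
                        alpha_temp_slope_range = c(5.7e-5, 9.0e-5),
                        outdoor_sheds = utils::tail(shed_ids, 2),
                        outdoor_b_factor = 1.7,
                        alpha_calibration = NULL,
                        milk_noise_O = 0.15,
                        milk_noise_H = 1.5,
                        h_enrichment_slope = 6.30,
                        dex_temp_slope = 0.35,
                        months = 1:12,
                        sampling_day = 15,
                        seed = NULL) {
  if (n_sheds < 1 || length(shed_ids) != n_sheds) {
    stop("invalid config: need at least one shed and matching `shed_ids`",
         call. = FALSE)
  }
  if (length(water_d18O_means) != n_sheds) {
    stop("invalid config: `water_d18O_means` must have one value per shed",
         call. = FALSE)
  }
  .check_delta(water_d18O_means, "water_d18O_means")
  if (!all(months %in% 1:12) || length(months) == 0) {
    stop("invalid config: `months` must be a subset of 1..12", call. = FALSE)
  }
  if (!all(outdoor_sheds %in% shed_ids)) {
    stop("invalid config: `outdoor_sheds` must be among `shed_ids`",
         call. = FALSE)
  }
  if (!is.null(alpha_calibration)) {
    stopifnot(inherits(alpha_calibration, "quartic_calibration"))
    if (alpha_calibration$response != "alpha") {
      stop("invalid config: `alpha_calibration` must have response 'alpha'",
           call. = FALSE)
    }
  }
  out <- as.list(environment())
  class(out) <- "herd_config"
  out
}

#' Deterministic seasonal temperature curve
#'
#' The noise-free annual air-temperature sinusoid of a [herd_config()],
#' `mean + amplitude * cos(2 * pi * (t - peak) / 365)` (degrees Celsius).
#'
#' @param t Day number(s).
#' @param config A [herd_config()].
#' @return Temperature(s) in degrees Celsius.
#' @export
seasonal_temperature <- function(t, config) {
  config$temp_mean + config$temp_amplitude *
    cos(2 * pi * (t - config$temp_peak_day) / 365)
}

# draw per-shed parameters and the noisy daily temperature series
.herd_state <- function(config) {
  n <- config$n_sheds
  list(
    d2H_W_mean = config$water_line_slope * config$water_d18O_means +
      config$water_line_intercept +
      stats::rnorm(n, 0, config$water_line_scatter),
    A = stats::rnorm(n, config$alpha_intercept_mean,
                     config$alpha_intercept_sd),
    B = stats::runif(n, config$alpha_temp_slope_range[1L],
                     config$alpha_temp_slope_range[2L]),
    temp_daily = seasonal_temperature(1:365, config) +
      stats::rnorm(365, 0, config$temp_daily_sd)
  )
}

# mean daily temperature over the 14 days preceding day t (wrapping the year)
.temp_2wk <- function(state, t) {
  vapply(t, function(ti) {
    days <- ((ti - 14):(ti - 1) - 1) %% 365 + 1
    mean(state$temp_daily[days])
  }, numeric(1))
}

# one record per (shed, sampling time); isotopes reflect t_actual, the
# declared metadata (date, t, temp_2wk) reflect t_declared
.generate_records <- function(config, state, shed, t_declared, t_actual) {
  k <- length(shed)
  temp_actual <- .temp_2wk(state, t_actual)
  temp_declared <- .temp_2wk(state, t_declared)
  outdoor <- config$shed_ids[shed] %in% config$outdoor_sheds
  warm <- .month_of_day(t_actual) %in% 5:10
  if (!is.null(config$alpha_calibration)) {
    alpha_true <- predict_alpha(t_actual, config$alpha_calibration)
  } else {
    b_eff <- state$B[shed] *
      ifelse(outdoor & warm, config$outdoor_b_factor, 1)
    alpha_true <- state$A[shed] + b_eff * temp_actual
  }
  d18O_W <- config$water_d18O_means[shed] +
    stats::rnorm(k, 0, config$water_sd_O)
  d2H_W <- state$d2H_W_mean[shed] + stats::rnorm(k, 0, config$water_sd_H)
  d18O_M_true <- milk_delta_from_alpha(alpha_true, d18O_W)
  d18O_M <- d18O_M_true + stats::rnorm(k, 0, config$milk_noise_O)
  d2H_M <- d2H_W + config$h_enrichment_slope * (d18O_M_true - d18O_W) -
    config$dex_temp_slope * (temp_actual - config$temp_mean) +
    stats::rnorm(k, 0, config$milk_noise_H)
  month_decl <- .month_of_day(t_declared)
  data.frame(
    shed_id = config$shed_ids[shed],
    date = sprintf("%02d/%02d/2018",
                   t_declared - .MONTH_OFFSET[month_decl], month_decl),
    t = as.integer(t_declared),
    month = as.integer(month_decl),
    d18O_W = d18O_W,
    d2H_W = d2H_W,
    d18O_M = d18O_M,
    d2H_M = d2H_M,
    temp_2wk = temp_declared,
    outdoor_summer = outdoor
  )
}

#' Simulate one year of monthly herd sampling
#'
#' Generates one sample record per shed and sampled month under a
#' [herd_config()]: farm water drawn around the shed mean, the fractionation
#' factor from the temperature-linear (or calibration-curve) seasonal model,
#' milk delta18O built by inverting the fractionation factor against the
#' farm water, and milk delta2H from the water value along an
#' evaporation-like enrichment slope with a temperature-driven
#' deuterium-excess depression. Identical config and seed give identical
#' output.
#'
#' @param config A [herd_config()].
#' @param seed Random seed (defaults to `config$seed`; `NULL` leaves the
#'   RNG state untouched).
#' @return Data frame of sample records (`shed_id`, `date`, `t`, `month`,
#'   `d18O_W`, `d2H_W`, `d18O_M`, `d2H_M`, `temp_2wk`, `outdoor_summer`)
#'   with the drawn per-shed parameters attached as attribute
#'   `shed_params`.
#' @export
simulate_herd_year <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "herd_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- .herd_state(config)
  t_samp <- vapply(config$months, function(m) {
    day_number(sprintf("%02d/%02d/2018", config$sampling_day, m))
  }, integer(1))
  grid <- expand.grid(shed = seq_len(config$n_sheds),
                      mi = seq_along(config$months))
  recs <- .generate_records(config, state,
                            shed = grid$shed,
                            t_declared = t_samp[grid$mi],
                            t_actual = t_samp[grid$mi])
  attr(recs, "shed_params") <- data.frame(
    shed_id = config$shed_ids,
    d18O_W_mean = config$water_d18O_means,
    d2H_W_mean = state$d2H_W_mean,
    A = state$A,
    B = state$B,
    outdoor = config$shed_ids %in% config$outdoor_sheds
  )
  recs
}

#' Simulate labelled authenticity scenarios
#'
#' Generates a herd-year of records under one of four scenarios and labels
#' them for false-accept / false-reject estimation of the two-step check:
#'
#' * `authentic` - records exactly as [simulate_herd_year()];
#' * `foreign_water` - the declared farm water is shifted by `water_shift`
#'   per mil (delta2H along the water line) while the milk is unchanged, as
#'   when milk is trucked in from a region with isotopically different
#'   groundwater;
#' * `foreign_milk` - the measured fractionation factor is offset by
#'   `alpha_offset` above the regional seasonal value;
#' * `season_mislabel` - the milk was produced `season_shift` days away from
#'   the declared sampling date.
#'
#' @param config A [herd_config()].
#' @param scenario Scenario name.
#' @param seed Random seed (defaults to `config$seed`).
#' @param water_shift Farm-water delta18O shift (per mil) for
#'   `foreign_water`.
#' @param alpha_offset Fractionation-factor offset (dimensionless, e.g.
#'   `1.5e-3` = 1.5 per mil) for `foreign_milk`.
#' @param season_shift Day shift for `season_mislabel`.
#' @return Data frame of records as in [simulate_herd_year()] plus columns
#'   `scenario` and `fraud` (logical truth label).
#' @export
simulate_fraud_scenarios <- function(config,
                                     scenario = c("authentic",
                                                  "foreign_water",
                                                  "foreign_milk",
                                                  "season_mislabel"),
                                     seed = config$seed,
                                     water_shift = 3,
                                     alpha_offset = 1.5e-3,
                                     season_shift = 180) {
  stopifnot(inherits(config, "herd_config"))
  scenario <- tryCatch(match.arg(scenario), error = function(e) {
    stop("invalid config: unknown scenario '", scenario[1L], "'",
         call. = FALSE)
  })
  if (!is.null(seed)) set.seed(seed)
  state <- .herd_state(config)
  t_samp <- vapply(config$months, function(m) {
    day_number(sprintf("%02d/%02d/2018", config$sampling_day, m))
  }, integer(1))
  grid <- expand.grid(shed = seq_len(config$n_sheds),
                      mi = seq_along(config$months))
  t_decl <- t_samp[grid$mi]
  t_act <- if (scenario == "season_mislabel") {
    as.integer((t_decl + season_shift - 1) %% 365 + 1)
  } else {
    t_decl
  }
  recs <- .generate_records(config, state, shed = grid$shed,
                            t_declared = t_decl, t_actual = t_act)
  if (scenario == "foreign_water") {
    recs$d18O_W <- recs$d18O_W + water_shift
    recs$d2H_W <- recs$d2H_W + config$water_line_slope * water_shift
  } else if (scenario == "foreign_milk") {
    alpha_m <- compute_alpha(recs$d18O_M, recs$d18O_W)
    recs$d18O_M <- milk_delta_from_alpha(alpha_m + alpha_offset, recs$d18O_W)
  }
  recs$scenario <- scenario
  recs$fraud <- scenario != "authentic"
  recs
}
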