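#' Default climate parameters for the simulated barn
#'
#' A single diurnal sinusoid plus white logger noise: summer in-barn
#' conditions with the daily temperature peak in the 16:00 hour.
#'
#' @param daily_mean_c daily mean dry-bulb temperature (degC).
#' @param amplitude_c half peak-to-trough amplitude of the diurnal cycle (degC).
#' @param phase_h clock time (decimal hours) at which the sinusoid peaks.
#' @param noise_sd_c logger white-noise SD (degC).
#' @param rh_mean_pct,rh_sd_pct mean and SD of relative humidity (%).
#' @return list of class \code{climate_params}.
#' @export
climate_params <- function(daily_mean_c = 28, amplitude_c = 4, phase_h = 16,
                           noise_sd_c = 0.5, rh_mean_pct = 70, rh_sd_pct = 8) {
  stopifnot(amplitude_c >= 0, noise_sd_c >= 0, rh_sd_pct >= 0,
            rh_mean_pct > 0, rh_mean_pct <= 100)
  structure(list(daily_mean_c = daily_mean_c, amplitude_c = amplitude_c,
                 phase_h = phase_h, noise_sd_c = noise_sd_c,
                 rh_mean_pct = rh_mean_pct, rh_sd_pct = rh_sd_pct),
            class = "climate_params")
}

#' Simulate 5-min in-barn climate logger records
#'
#' One record per logger per 5-min tick (288 ticks/day). Dry-bulb temperature
#' is \code{daily_mean + amplitude * sin(2*pi*(t - phase + 6)/24)} so the
#' sinusoid peaks at \code{phase_h}, plus iid logger noise. Relative humidity
#' is iid normal truncated to (0, 100].
#'
#' @param n_days number of days (>= 1).
#' @param n_loggers number of loggers (>= 1), assigned round-robin to rooms.
#' @param params [climate_params()].
#' @param seed integer seed.
#' @param n_rooms number of rooms the loggers are split over.
#' @param start date of the first record.
#' @return data frame of class \code{climate_series}: \code{logger_id},
#'   \code{room}, \code{timestamp} (POSIXct UTC), \code{dbt_c}, \code{rh_pct}.
#' @export
simulate_climate <- function(n_days, n_loggers, params = climate_params(),
                             seed = 1, n_rooms = 1,
                             start = as.Date("2021-06-09")) {
  stopifnot(n_days >= 1, n_loggers >= 1, n_rooms >= 1,
            inherits(params, "climate_params"))
  set.seed(seed)
  ticks <- seq(0, n_days * 24 * 3600 - 300, by = 300)  # 288 per day
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  n <- length(ticks) * n_loggers
  logger <- rep(seq_len(n_loggers), each = length(ticks))
  room <- ((logger - 1) %% n_rooms) + 1L
  tt <- rep(ticks, times = n_loggers)
  hour_of_day <- (tt / 3600) %% 24
  dbt <- params$daily_mean_c +
    params$amplitude_c * sin(2 * pi * (hour_of_day - params$phase_h + 6) / 24) +
    rnorm(n, 0, params$noise_sd_c)
  rh <- rnorm(n, params$rh_mean_pct, params$rh_sd_pct)
  rh <- pmin(pmax(rh, 1e-6), 100)
  out <- data.frame(logger_id = sprintf("L%02d", logger),
                    room = sprintf("R%02d", room),
                    timestamp = t0 + tt,
                    dbt_c = dbt, rh_pct = rh,
                    stringsAsFactors = FALSE)
  class(out) <- c("climate_series", "data.frame")
  out
}
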