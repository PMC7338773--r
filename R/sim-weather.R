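#' Simulate a daily weather series
#'
#' Sinusoidal seasonality plus Gaussian daily noise:
#' `t_mean = mean_temp + seasonal_amplitude * sin(2*pi*day/365.25) + noise`;
#' relative humidity follows the same form around `rh_mean` with a quarter-
#' cycle phase offset and is clipped to \[0, 100\]. Daily minimum and
#' maximum temperatures are the mean minus/plus a positive diurnal spread.
#'
#' @param n_days Number of days to simulate.
#' @param config A [sim_config()]; uses `weather_params` and `seed`.
#' @param start_date First date of the series.
#' @return A tibble `date`, `t_mean`, `t_min`, `t_max`, `rh`.
#' @export
simulate_weather <- function(n_days, config, start_date = as.Date("2010-01-01")) {
  if (n_days < 1) hn_abort("n_days must be >= 1.", "heatnorm_config_error")
  set.seed(config$seed + 2L)
  wp <- config$weather_params
  day <- seq_len(n_days)
  season <- sin(2 * pi * day / 365.25)
  t_mean <- wp$mean_temp + wp$seasonal_amplitude * season +
    rnorm(n_days, 0, wp$daily_noise_sd)
  rh <- wp$rh_mean + wp$rh_amplitude * sin(2 * pi * day / 365.25 + pi / 2) +
    rnorm(n_days, 0, wp$daily_noise_sd)
  rh <- pmin(pmax(rh, 0), 100)
  spread <- abs(wp$diurnal_spread)
  tibble::tibble(date = start_date + day - 1L,
                 t_mean = t_mean,
                 t_min = t_mean - spread,
                 t_max = t_mean + spread,
                 rh = rh)
}
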