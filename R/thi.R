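#' Temperature-humidity index
#'
#' Computes the NRC-1971 dry-bulb/relative-humidity temperature-humidity
#' index,
#' \deqn{THI = T_F - (0.55 - 0.0055\,RH)(1.8\,T_C - 26),}
#' where \eqn{T_C} is the dry-bulb temperature in Celsius,
#' \eqn{T_F = 1.8\,T_C + 32} and \eqn{RH} is relative humidity in percent.
#' At \eqn{RH = 100} the index equals \eqn{T_F}; the humidity correction
#' vanishes at \eqn{1.8\,T_C = 26}.
#'
#' @param t_mean Dry-bulb temperature in degrees Celsius (vectorized).
#' @param rh Relative humidity in percent, in \eqn{[0, 100]} (vectorized).
#' @return Numeric vector of THI values (dimensionless, Fahrenheit scale).
#' @examples
#' compute_thi(25, 50)   # 71.775
#' compute_thi(30, 100)  # equals 1.8 * 30 + 32
#' @export
compute_thi <- function(t_mean, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    hn_abort("relative humidity must lie in [0, 100].",
             "heatnorm_domain_error")
  }
  t_f <- 1.8 * t_mean + 32
  t_f - (0.55 - 0.0055 * rh) * (1.8 * t_mean - 26)
}
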