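#' Weekly interval layout of the reproductive cycle
#'
#' The sow reproductive cycle is tiled into 19 seven-day intervals relative
#' to the conception date, from three weeks before conception through
#' farrowing: interval 1 covers days \[−21, −14) and interval 19 covers days
#' \[105, 112). Intervals are half-open `[start_day, end_day)`.
#'
#' @return A tibble with columns `interval`, `start_day`, `end_day`.
#' @export
interval_spec <- function() {
  k <- 1:19
  tibble::tibble(interval = k,
                 start_day = 7L * (k - 1L) - 21L,
                 end_day   = 7L * k - 21L)
}

env_variables <- c("MeanT", "RH", "MaxT", "MinT", "THI")

#' Build the 95 litter-specific weekly environmental covariates
#'
#' For each reproductive record and each of the 19 weekly intervals of
#' [interval_spec()], averages five daily weather variables over the
#' interval's days (anchored at the record's conception date): mean, maximum
#' and minimum temperature, relative humidity, and the daily
#' temperature-humidity index of [compute_thi()]. This yields
#' 19 x 5 = 95 covariate columns named `<Variable>_<interval>` (e.g.
#' `RH_2` is average relative humidity 14 to 7 days before conception).
#'
#' @param weather A weather tibble with columns `date`, `t_mean`, `t_min`,
#'   `t_max`, `rh` (one row per day; must cover every record's window).
#' @param records A phenotype tibble with at least `sow`, `parity` and
#'   `conception_date` columns.
#' @param variables Subset of `c("MeanT","RH","MaxT","MinT","THI")` to
#'   compute; default all five.
#' @param intervals Integer subset of 1..19; default all 19.
#' @return A tibble keyed by (`sow`, `parity`) with one column per
#'   variable-interval combination.
#' @export
build_interval_covariates <- function(weather, records,
                                      variables = env_variables,
                                      intervals = 1:19) {
  stopifnot(all(variables %in% env_variables), all(intervals %in% 1:19))
  spec <- interval_spec()[intervals, , drop = FALSE]
  weather <- dplyr::arrange(weather, .data$date)
  wdate <- as.integer(weather$date)
  if (anyDuplicated(wdate)) {
    hn_abort("duplicate weather dates.", "heatnorm_weather_error")
  }
  if (length(wdate) > 1 && any(diff(wdate) != 1L)) {
    gaps <- setdiff(seq(wdate[1], wdate[length(wdate)]), wdate)
    hn_abort(paste0("weather series has ", length(gaps),
                    " missing day(s) inside its range."),
             "heatnorm_weather_error")
  }
  conc <- as.integer(records$conception_date)
  need <- range(outer(conc, range(c(spec$start_day, spec$end_day - 1L)), "+"))
  missing_days <- setdiff(seq(need[1], need[2]), wdate)
  if (length(missing_days) > 0) {
    hn_abort(paste0("weather series does not cover all record windows; ",
                    length(missing_days), " missing day(s), e.g. ",
                    paste(utils::head(as.Date(missing_days,
                                              origin = "1970-01-01"), 5),
                          collapse = ", ")),
             "heatnorm_weather_error")
  }
  # daily series indexed by day number for O(1) lookup
  daily <- list(MeanT = weather$t_mean, RH = weather$rh,
                MaxT = weather$t_max, MinT = weather$t_min,
                THI = compute_thi(weather$t_mean, weather$rh))
  # cumulative sums allow each 7-day mean to be two lookups
  day0 <- min(wdate)
  idx_of <- function(day) day - day0 + 1L
  out <- tibble::tibble(sow = records$sow, parity = records$parity)
  for (v in variables) {
    cs <- c(0, cumsum(daily[[v]]))
    for (r in seq_len(nrow(spec))) {
      lo <- idx_of(conc + spec$start_day[r])
      hi <- idx_of(conc + spec$end_day[r] - 1L)
      out[[paste0(v, "_", spec$interval[r])]] <- (cs[hi + 1L] - cs[lo]) / 7
    }
  }
  out
}

#' Standardize an environmental covariate to \[-1, 1\]
#'
#' Affine rescaling \eqn{x = 2 (v - \min)/(\max - \min) - 1}, so that the
#' column minimum maps to −1, the maximum to +1 and the midpoint
#' \eqn{(\min + \max)/2} to 0. The midpoint is the raw covariate value at
#' which a reaction norm's intercept term is evaluated.
#'
#' @param values Numeric covariate column.
#' @param min,max Optional user-supplied range (e.g. to reproduce a printed
#'   scale); defaults to the observed range.
#' @return A list with elements `x` (standardized values), `min`, `max`,
#'   `midpoint`.
#' @export
standardize_env <- function(values, min = NULL, max = NULL) {
  lo <- if (is.null(min)) base::min(values, na.rm = TRUE) else min
  hi <- if (is.null(max)) base::max(values, na.rm = TRUE) else max
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    hn_abort("degenerate covariate: max must exceed min.",
             "heatnorm_degenerate_covariate")
  }
  list(x = 2 * (values - lo) / (hi - lo) - 1,
       min = lo, max = hi, midpoint = (lo + hi) / 2)
}

#' Quintile boundaries of a covariate
#'
#' The first four quintiles (20/40/60/80th percentiles, linear-interpolation
#' rule) used as discriminants for the five residual-variance classes.
#'
#' @param x Numeric values (standardized covariate).
#' @return Numeric vector of four boundaries.
#' @export
residual_class_bounds <- function(x) {
  unname(quantile(x, probs = c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE))
}

#' Assign residual-variance classes from covariate quintiles
#'
#' Phenotypic records are allocated to one of five residual-variance classes
#' using the first four quintiles of the environmental covariate as
#' discriminants, giving balanced class sizes up to ties. Values equal to a
#' boundary go to the lower class.
#'
#' @param x Standardized covariate values, one per record.
#' @param bounds Optional pre-computed boundaries (e.g. from a training
#'   set); default [residual_class_bounds()] of `x`.
#' @return Integer vector of classes in 1..5.
#' @export
assign_residual_class <- function(x, bounds = NULL) {
  if (is.null(bounds)) {
    if (length(unique(x)) < 5) {
      hn_abort("need at least 5 distinct values to form quintile classes.",
               "heatnorm_class_error")
    }
    bounds <- residual_class_bounds(x)
  }
  findInterval(x, bounds, left.open = TRUE) + 1L
}

#' Edit phenotypes by the 3.5-SD rule
#'
#' Single-pass per-trait edit: a trait value deviating strictly more than
#' `k_sd` standard deviations from that trait's mean is masked to `NA`
#' (records carry all traits, and model fits are univariate, so masking is
#' equivalent to dropping the record from that trait's dataset). Values at
#' exactly `k_sd` SD are retained.
#'
#' @param records Phenotype tibble.
#' @param traits Character vector of trait columns to edit.
#' @param k_sd Deviation threshold in SD units (default 3.5).
#' @return A list with `records` (edited tibble) and `report` (tibble with
#'   per-trait counts of masked values).
#' @export
edit_phenotypes <- function(records, traits = c("tnb", "nba", "abw"),
                            k_sd = 3.5) {
  traits <- intersect(traits, names(records))
  report <- purrr::map_dfr(traits, function(tr) {
    y <- records[[tr]]
    ok <- !is.na(y)
    if (sum(ok) < 2) hn_abort("need at least 2 records per trait.",
                              "heatnorm_edit_error")
    m <- mean(y[ok]); s <- sd(y[ok])
    out <- ok & s > 0 & abs(y - m) > k_sd * s
    records[[tr]][out] <<- NA
    tibble::tibble(trait = tr, n = sum(ok), n_removed = sum(out),
                   mean = m, sd = s)
  })
  list(records = records, report = report)
}
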