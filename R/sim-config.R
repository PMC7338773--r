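#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate one
#' maternal-line nucleus population at the scale used for parameter-recovery
#' checks: 50 sires each with 10 recorded daughters (500 sows), repeated
#' farrowing records per sow, a mid-latitude seasonal climate, and genetic
#' (co)variances of the magnitude reported for sow litter traits.
#'
#' @param n_founders Number of founder animals (generation 1). The first
#'   `n_sires_per_gen` founders are male, the rest female.
#' @param n_generations Total number of generations including founders.
#' @param n_sires_per_gen Sires used in each generation.
#' @param n_daughters_per_sire Recorded daughters per sire per generation.
#' @param n_sons_per_gen Male offspring produced per generation (the next
#'   generation's sires).
#' @param n_parities_per_sow Farrowing records per sow.
#' @param n_snps Number of simulated SNPs.
#' @param n_chromosomes Chromosomes the SNPs are spread over.
#' @param maf_range Founder minor-allele-frequency range, within (0, 0.5].
#' @param weather_params List: `mean_temp` and `seasonal_amplitude` (deg C),
#'   `rh_mean` and `rh_amplitude` (percent), `daily_noise_sd`,
#'   `diurnal_spread` (deg C between daily min/max and mean).
#' @param true_varcomp List: `G` (2x2 genetic covariance of intercept and
#'   slope on the normalized Legendre scale), `sigma2_pe` (permanent
#'   environment), `sigma2_e` (length-5 residual variances, one per
#'   covariate-quintile class).
#' @param fixed_effects List: `intercept`, `beta` (fixed regression on
#'   phi1), `parity` (length-5 effects, first is the reference),
#'   `year` (named or unnamed vector of birth-year effects).
#' @param env_spec List: `variable` and `interval` naming the covariate that
#'   truly drives the genotype-by-environment interaction.
#' @param n_birth_years Number of sow birth-year cohorts (contemporary
#'   groups).
#' @param n_years Calendar span of the simulated weather series, years.
#' @param genotyped_sow_fraction Fraction of sows genotyped (sires are
#'   always genotyped).
#' @param traits Trait columns to emit; the reaction-norm signal is written
#'   on the first, the others are independent-noise companions.
#' @param seed Integer seed; fixes the whole dataset bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 550,
                       n_generations = 2,
                       n_sires_per_gen = 50,
                       n_daughters_per_sire = 10,
                       n_sons_per_gen = n_sires_per_gen,
                       n_parities_per_sow = 10,
                       n_snps = 2000,
                       n_chromosomes = 18,
                       maf_range = c(0.05, 0.5),
                       weather_params = list(mean_temp = 15,
                                             seasonal_amplitude = 10,
                                             rh_mean = 65,
                                             rh_amplitude = 15,
                                             daily_noise_sd = 3,
                                             diurnal_spread = 5),
                       true_varcomp = list(G = matrix(c(9, 0.6, 0.6, 6.5), 2),
                                           sigma2_pe = 15,
                                           sigma2_e = c(30, 32, 34, 36, 38)),
                       fixed_effects = list(intercept = 12,
                                            beta = -0.5,
                                            parity = c(0, 0.8, 1.0, 0.7, 0.2),
                                            year = c(0, 0.3, 0.6)),
                       env_spec = list(variable = "RH", interval = 2),
                       n_birth_years = 3,
                       n_years = 6,
                       genotyped_sow_fraction = 0.5,
                       traits = c("tnb", "nba", "abw"),
                       seed = 2026L) {
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              n_sires_per_gen = n_sires_per_gen,
              n_daughters_per_sire = n_daughters_per_sire,
              n_sons_per_gen = n_sons_per_gen,
              n_parities_per_sow = n_parities_per_sow,
              n_snps = n_snps, n_chromosomes = n_chromosomes,
              maf_range = maf_range, weather_params = weather_params,
              true_varcomp = true_varcomp, fixed_effects = fixed_effects,
              env_spec = env_spec, n_birth_years = n_birth_years,
              n_years = n_years,
              genotyped_sow_fraction = genotyped_sow_fraction,
              traits = traits, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_founders, cfg$n_generations, cfg$n_sires_per_gen,
              cfg$n_daughters_per_sire, cfg$n_parities_per_sow, cfg$n_snps,
              cfg$n_chromosomes)
  if (any(counts < 1) || any(counts != round(counts))) {
    hn_abort("all counts in sim_config must be positive integers.",
             "heatnorm_config_error")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2]) {
    hn_abort("maf_range must lie within (0, 0.5].", "heatnorm_config_error")
  }
  G <- cfg$true_varcomp$G
  if (!isTRUE(all.equal(G, t(G))) || any(eigen(G, symmetric = TRUE,
                                               only.values = TRUE)$values < 0)) {
    hn_abort("true G must be symmetric positive semidefinite.",
             "heatnorm_config_error")
  }
  if (cfg$true_varcomp$sigma2_pe < 0 || any(cfg$true_varcomp$sigma2_e < 0) ||
      length(cfg$true_varcomp$sigma2_e) != 5) {
    hn_abort("residual/permanent-environment variances must be >= 0 (5 residual classes).",
             "heatnorm_config_error")
  }
  if (cfg$n_founders < cfg$n_sires_per_gen + 1) {
    hn_abort("n_founders must exceed n_sires_per_gen (need founder dams).",
             "heatnorm_config_error")
  }
  invisible(cfg)
}
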