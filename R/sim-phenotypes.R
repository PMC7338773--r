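#' Simulate reproductive phenotypes under the reaction-norm model
#'
#' Draws intercept/slope breeding values \eqn{(a_0, a_1) \sim N(0, A \otimes G)}
#' by the pedigree-recursive rule (parent average plus a Mendelian-sampling
#' deviation with covariance \eqn{G (1 - (F_s + F_d)/2)/2}), a permanent
#' environmental effect per sow, and assembles each farrowing record as
#' \deqn{y = \alpha + \beta\,\phi_1(x) + CG + Par + a_0\,\phi_0 +
#'   a_1\,\phi_1(x) + p + e,}
#' where \eqn{x} is the record's standardized value of the designated
#' driving covariate (built from the weather series with
#' [build_interval_covariates()] and the same Legendre basis as the fitting
#' code) and the residual variance is the one of the record's covariate
#' quintile class. Conception dates are uniform over the calendar (so all
#' covariate classes are populated) and gestation is fixed at 114 days.
#'
#' The reaction-norm signal is written on the first trait in
#' `config$traits`; remaining traits are companions (number born alive is
#' total born minus a non-negative loss; average birth weight is
#' independent noise around 1.5 kg) so that record-table invariants hold.
#'
#' @param pedigree Pedigree tibble.
#' @param weather Daily weather tibble (see [simulate_weather()]).
#' @param env_spec List with `variable` and `interval`; default from
#'   `config`.
#' @param config A [sim_config()].
#' @return A list: `records` (phenotype tibble), `truth` (true breeding
#'   values, permanent-environment effects, per-record covariate values,
#'   classes and all generating parameters).
#' @export
simulate_phenotypes <- function(pedigree, weather, env_spec = NULL, config) {
  pedigree <- check_pedigree(pedigree)
  if (is.null(env_spec)) env_spec <- config$env_spec
  set.seed(config$seed + 3L)
  vc <- config$true_varcomp
  fe <- config$fixed_effects

  bv <- sample_breeding_values(pedigree, vc$G)

  sows <- pedigree$animal[pedigree$sex == "F" &
                            pedigree$generation == max(pedigree$generation)]
  n_sow <- length(sows)
  if (n_sow == 0) hn_abort("no sows in final generation.", "heatnorm_config_error")
  pe <- rnorm(n_sow, 0, sqrt(vc$sigma2_pe))
  names(pe) <- sows
  birth_year <- sample.int(config$n_birth_years, n_sow, replace = TRUE)
  names(birth_year) <- sows

  n_par <- config$n_parities_per_sow
  n_days <- nrow(weather)
  if (n_days < 22 + 114 + 1) {
    hn_abort("weather series too short for a full reproductive cycle.",
             "heatnorm_weather_error")
  }
  rec <- tidyr::expand_grid(sow = sows, parity = seq_len(n_par))
  conc_day <- sample(22:(n_days - 115), nrow(rec), replace = TRUE)
  rec$conception_date <- weather$date[1] + conc_day - 1L
  rec$farrowing_date <- rec$conception_date + 114L
  rec$birth_year <- birth_year[as.character(rec$sow)]

  env_col <- paste0(env_spec$variable, "_", env_spec$interval)
  env <- build_interval_covariates(weather, rec,
                                   variables = env_spec$variable,
                                   intervals = env_spec$interval)
  std <- standardize_env(env[[env_col]])
  x <- std$x
  bounds <- residual_class_bounds(x)
  cls <- assign_residual_class(x, bounds)
  phi <- legendre_basis(x)

  a0 <- bv[as.character(rec$sow), 1]
  a1 <- bv[as.character(rec$sow), 2]
  parity_class <- pmin(rec$parity, 5L)
  year_eff <- rep_len(fe$year, config$n_birth_years)[rec$birth_year]
  mu <- fe$intercept + fe$beta * phi[, "phi1"] + year_eff +
    fe$parity[parity_class] + a0 * phi[, "phi0"] + a1 * phi[, "phi1"] +
    pe[as.character(rec$sow)]
  e <- rnorm(nrow(rec), 0, sqrt(vc$sigma2_e[cls]))
  y <- mu + e

  records <- rec
  tr <- config$traits
  records[[tr[1]]] <- y
  if (length(tr) >= 2) records[[tr[2]]] <- y - abs(rnorm(nrow(rec), 0.8, 0.5))
  if (length(tr) >= 3) records[[tr[3]]] <- 1.5 + rnorm(nrow(rec), 0, 0.25)

  truth <- list(
    breeding_values = tibble::tibble(animal = pedigree$animal,
                                     a0 = bv[, 1], a1 = bv[, 2]),
    pe = tibble::tibble(sow = sows, pe = unname(pe)),
    record_env = tibble::tibble(sow = rec$sow, parity = rec$parity,
                                raw = env[[env_col]], x = x, class = cls),
    env_column = env_col, std = std[c("min", "max", "midpoint")],
    class_bounds = bounds, varcomp = vc, fixed_effects = fe,
    trait = tr[1]
  )
  list(records = records, truth = truth)
}

# Recursive sampling of (a0, a1) ~ N(0, A (x) G); linear cost, exact law.
sample_breeding_values <- function(pedigree, G) {
  # eigen square root tolerates semidefinite G (e.g. a zero matrix)
  eg <- eigen(G, symmetric = TRUE)
  L <- diag(sqrt(pmax(eg$values, 0)), 2) %*% t(eg$vectors)
  n <- nrow(pedigree)
  f <- pedigree_inbreeding(pedigree)
  sp <- match(pedigree$sire, pedigree$animal)
  dp <- match(pedigree$dam, pedigree$animal)
  bv <- matrix(0, n, 2, dimnames = list(pedigree$animal, c("a0", "a1")))
  z <- matrix(rnorm(2 * n), n, 2)
  for (i in seq_len(n)) {
    known <- c(!is.na(sp[i]), !is.na(dp[i]))
    pa <- rep(0, 2)
    f_par <- 0
    if (known[1]) { pa <- pa + 0.5 * bv[sp[i], ]; f_par <- f_par + f[sp[i]] }
    if (known[2]) { pa <- pa + 0.5 * bv[dp[i], ]; f_par <- f_par + f[dp[i]] }
    ms_var <- switch(sum(known) + 1L,
                     1,                        # both unknown: founder
                     0.75 - 0.25 * f_par,      # one parent known
                     0.5 * (1 - f_par / 2))    # both known
    bv[i, ] <- pa + sqrt(ms_var) * drop(z[i, ] %*% L)
  }
  bv
}

#' Simulate a complete synthetic herd dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()], [simulate_weather()] and
#' [simulate_phenotypes()], and building the full 95-column environmental
#' covariate table for the records. Genotyped animals are all sires plus a
#' `genotyped_sow_fraction` random subset of sows.
#'
#' @param config A [sim_config()].
#' @param env_table Logical; also build the 95-column covariate table.
#' @return A list `pedigree`, `genotypes`, `weather`, `records`, `env`
#'   (or `NULL`), `truth`, `genotyped_ids`, `config`.
#' @export
simulate_herd <- function(config = sim_config(), env_table = TRUE) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  weather <- simulate_weather(ceiling(365.25 * config$n_years), config)
  sim <- simulate_phenotypes(ped, weather, config$env_spec, config)
  env <- if (env_table) build_interval_covariates(weather, sim$records) else NULL
  set.seed(config$seed + 4L)
  sires <- unique(ped$sire[!is.na(ped$sire)])
  sows <- sim$truth$pe$sow
  geno_sows <- sort(sample(sows, round(config$genotyped_sow_fraction *
                                         length(sows))))
  list(pedigree = ped, genotypes = geno, weather = weather,
       records = sim$records, env = env, truth = sim$truth,
       genotyped_ids = c(sires, geno_sows), config = config)
}
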