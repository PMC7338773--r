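#' Build the reaction-norm model design
#'
#' Joins phenotype records to one environmental covariate column,
#' standardizes it to \[-1, 1\], assigns the five residual-variance classes
#' from its quintiles, and assembles the fixed-effect incidence (overall
#' intercept, fixed regression on \eqn{\phi_1}, contemporary group = sow
#' birth year, parity class 1..5+) together with the random-regression
#' covariables \eqn{(\phi_0, \phi_1(x))} and the permanent-environment
#' indexing. One row per record with a non-missing trait value.
#'
#' @param records Phenotype tibble with `sow`, `parity`, `birth_year` and
#'   the trait column.
#' @param env_table Covariate tibble keyed by (`sow`, `parity`), e.g. from
#'   [build_interval_covariates()].
#' @param trait Trait column name.
#' @param covariate Covariate column name in `env_table`.
#' @param env_min,env_max Optional fixed standardization range.
#' @return An `rn_design` list: `y`, `X` (fixed-effect matrix), `phi`
#'   (record-wise Legendre covariables), `sow`, `x`, `class`,
#'   `class_bounds`, `std`, `trait`, `covariate`.
#' @export
build_design <- function(records, env_table, trait, covariate,
                         env_min = NULL, env_max = NULL) {
  if (!trait %in% names(records)) {
    hn_abort(paste0("trait column `", trait, "` not found."),
             "heatnorm_design_error")
  }
  if (!covariate %in% names(env_table)) {
    hn_abort(paste0("covariate column `", covariate, "` not found."),
             "heatnorm_design_error")
  }
  dat <- dplyr::inner_join(records,
                           env_table[, c("sow", "parity", covariate)],
                           by = c("sow", "parity"))
  if (nrow(dat) < nrow(records)) {
    hn_abort("some records have no matching covariate row (sow/parity).",
             "heatnorm_design_error")
  }
  dat <- dat[!is.na(dat[[trait]]), , drop = FALSE]
  std <- standardize_env(dat[[covariate]], min = env_min, max = env_max)
  x <- pmin(pmax(std$x, -1), 1)
  bounds <- residual_class_bounds(x)
  cls <- assign_residual_class(x, bounds)
  phi <- legendre_basis(x)
  cg <- factor(dat$birth_year)
  par5 <- factor(pmin(dat$parity, 5L))
  mm <- model.matrix(~ cg + par5)
  X <- cbind(`(Intercept)` = mm[, 1], beta_phi1 = phi[, "phi1"],
             mm[, -1, drop = FALSE])
  structure(list(y = dat[[trait]], X = X, phi = phi,
                 sow = as.character(dat$sow), x = x,
                 class = cls, class_bounds = bounds,
                 std = std[c("min", "max", "midpoint")],
                 trait = trait, covariate = covariate,
                 n = nrow(dat)),
            class = "rn_design")
}

#' @export
print.rn_design <- function(x, ...) {
  cat("<rn_design> trait ", x$trait, " on ", x$covariate, ": ", x$n,
      " records, ", length(unique(x$sow)), " sows, ",
      ncol(x$X), " fixed-effect columns\n", sep = "")
  invisible(x)
}
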