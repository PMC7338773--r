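#' Screen environmental covariates for genotype-by-environment signal
#'
#' Step one of the two-step variance-component strategy: a reduced
#' reaction-norm fit is run for every candidate covariate column and the
#' covariates are ranked by the posterior mean of the slope genetic
#' variance \eqn{\sigma^2_1}, the working measure of GxE strength. To keep
#' the screen cheap, only sires' genotypes enter the single-step matrix by
#' default (`sires_only = TRUE`), mirroring the full analysis' first pass;
#' the top-ranked covariate is then refit with the full chain and all
#' genotypes.
#'
#' @param records Phenotype tibble.
#' @param env_table Covariate table; every non-key column is a candidate.
#' @param trait Trait column name.
#' @param pedigree Pedigree tibble.
#' @param genotypes Optional `geno_set` for the genomic block.
#' @param sires_only If `TRUE` (default) only animals appearing as sires
#'   contribute genotypes.
#' @param omega Blending weight for [blend_G()].
#' @param iterations,burn_in,thin,seed Reduced-chain settings (defaults
#'   follow a 30,000-iteration screening pass).
#' @param priors A [rn_priors()] list.
#' @return A tibble (`covariate`, `sigma2_0`, `sigma01`, `sigma2_1`,
#'   `sigma2_1_sd`) sorted by `sigma2_1` descending; the first row is the
#'   selected covariate. Degenerate (constant) covariates are skipped with
#'   a warning.
#' @export
screen_env <- function(records, env_table, trait, pedigree,
                       genotypes = NULL, sires_only = TRUE, omega = 0.95,
                       iterations = 30000, burn_in = 10000, thin = 10,
                       seed = 1L, priors = rn_priors()) {
  cand <- setdiff(names(env_table), c("sow", "parity"))
  if (length(cand) == 0) hn_abort("no candidate covariates.",
                                  "heatnorm_design_error")
  hinv <- screen_h_inverse(pedigree, genotypes, sires_only, omega)
  res <- purrr::map(cand, function(cv) {
    d <- tryCatch(build_design(records, env_table, trait, cv),
                  heatnorm_degenerate_covariate = function(e) NULL)
    if (is.null(d)) {
      warning("skipping degenerate covariate ", cv, call. = FALSE)
      return(NULL)
    }
    fit <- gibbs_sample(d, hinv, priors = priors, iterations = iterations,
                        burn_in = burn_in, thin = thin, seed = seed)
    tibble::tibble(covariate = cv,
                   sigma2_0 = mean(fit$chain$sigma2_0),
                   sigma01 = mean(fit$chain$sigma01),
                   sigma2_1 = mean(fit$chain$sigma2_1),
                   sigma2_1_sd = sd(fit$chain$sigma2_1))
  })
  dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(.data$sigma2_1))
}

screen_h_inverse <- function(pedigree, genotypes, sires_only, omega) {
  if (is.null(genotypes)) {
    return(build_H_inverse(pedigree))
  }
  gids <- rownames(genotypes$dosage)
  if (sires_only) {
    sires <- as.character(unique(pedigree$sire[!is.na(pedigree$sire)]))
    gids <- intersect(gids, sires)
  }
  if (length(gids) == 0) return(build_H_inverse(pedigree))
  geno <- subset_genotypes(genotypes, animals = gids)
  # SNPs monomorphic within the genotyped subset cannot enter G
  geno <- qc_genotypes(geno, hwe_p_min = 0)$genotypes
  G <- build_G_vanraden2(geno)
  A <- build_A(pedigree)
  Gs <- blend_G(G, A[gids, gids], omega = omega)
  build_H_inverse(pedigree, Gs, gids)
}

#' Fit the reaction-norm model for one covariate
#'
#' Convenience wrapper: builds the single-step inverse from pedigree and
#' genotypes (all genotyped animals, VanRaden method-2 G blended with
#' `omega`), the model design for the chosen trait/covariate, and runs the
#' full Gibbs chain.
#'
#' @inheritParams screen_env
#' @param covariate Covariate column to fit.
#' @param ... Passed to [gibbs_sample()] (chain lengths, seed, ...).
#' @return An `rn_fit`.
#' @export
fit_reaction_norm <- function(records, env_table, trait, covariate,
                              pedigree, genotypes = NULL, omega = 0.95,
                              priors = rn_priors(), ...) {
  hinv <- screen_h_inverse(pedigree, genotypes, sires_only = FALSE,
                           omega = omega)
  design <- build_design(records, env_table, trait, covariate)
  gibbs_sample(design, hinv, priors = priors, ...)
}
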