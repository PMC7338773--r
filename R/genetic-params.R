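#' Across-environment genetic (co)variance surface
#'
#' \eqn{\Gamma = \Phi' G \Phi}: the additive-genetic covariance between
#' performances at any two points of the standardized environmental
#' gradient, with \eqn{\Phi} holding the normalized first-order Legendre
#' basis \eqn{(\phi_0, \phi_1(x))} at each grid point. \eqn{\Gamma} has
#' rank at most 2 for a first-order norm; across-environment genetic
#' correlations below 1 signal genotype-by-environment interaction.
#'
#' @param G 2x2 genetic (co)variance matrix of the intercept and slope
#'   terms (e.g. [posterior_G()] of a fit).
#' @param grid Standardized covariate grid; default 201 equally spaced
#'   points on \eqn{[-1, 1]}.
#' @return A `gamma_matrix` list: `grid`, `phi`, `gamma` (grid x grid
#'   covariance matrix) and `G`.
#' @export
gamma_matrix <- function(G, grid = seq(-1, 1, length.out = 201)) {
  G <- as.matrix(G)
  if (!isTRUE(all.equal(G, t(G), check.attributes = FALSE))) {
    hn_abort("G must be symmetric 2x2.", "heatnorm_domain_error")
  }
  phi <- legendre_basis(grid)
  gam <- phi %*% G %*% t(phi)
  gam <- (gam + t(gam)) / 2
  structure(list(grid = grid, phi = phi, gamma = gam, G = unname(G)),
            class = "gamma_matrix")
}

#' @export
print.gamma_matrix <- function(x, ...) {
  s <- correlation_summary(x)
  cat("<gamma_matrix> ", length(x$grid), "-point grid; off-diagonal genetic",
      " correlations: min ", sprintf("%.1f%%", 100 * s$min), ", median ",
      sprintf("%.1f%%", 100 * s$median), "\n", sep = "")
  invisible(x)
}

#' Summarize across-environment genetic correlations
#'
#' Converts \eqn{\Gamma} to a correlation matrix and reports the minimum
#' and median over strictly off-diagonal pairs, plus the full long-format
#' table for heatmaps. The minimum for a first-order norm is attained at
#' the grid extremes and is grid-insensitive; the median depends on the
#' grid, which is therefore reported alongside.
#'
#' @param gamma A `gamma_matrix`.
#' @return A list: `min`, `median` (proportions, multiply by 100 for
#'   percent), `n_grid`, and `correlations` (tibble `x1`, `x2`, `r`).
#' @export
correlation_summary <- function(gamma) {
  stopifnot(inherits(gamma, "gamma_matrix"))
  d <- diag(gamma$gamma)
  if (any(d <= 0)) hn_abort("zero diagonal in Gamma; G is degenerate.",
                            "heatnorm_domain_error")
  R <- cov2cor(gamma$gamma)
  off <- R[upper.tri(R)]
  tbl <- tidyr::expand_grid(x1 = gamma$grid, x2 = gamma$grid)
  tbl$r <- as.vector(t(R))
  list(min = min(off), median = median(off), n_grid = length(gamma$grid),
       correlations = tbl)
}

#' Environment-specific heritability
#'
#' \eqn{h^2_k = \Gamma_{kk} / (\Gamma_{kk} + \sigma^2_{pe} +
#' \sigma^2_{e,t(k)})}, where the residual variance is the one of the
#' covariate class the grid point falls in — producing the broken-line
#' heritability profile across class boundaries. Given an `rn_fit`, the
#' curve is evaluated per posterior draw and summarized with equal-tail
#' 95% bands; given a plain G matrix, a point curve is returned.
#'
#' @param object An `rn_fit`, or a 2x2 G matrix.
#' @param grid Standardized covariate grid.
#' @param sigma2_pe,sigma2_e Needed in matrix mode: permanent-environment
#'   variance and length-5 residual-class variances.
#' @param class_bounds Quintile boundaries on the standardized scale
#'   mapping grid points to classes; in fit mode defaults to the fit's.
#' @param conf_level Band mass in fit mode (default 0.95).
#' @return A tibble `x`, `class`, `h2` (+ `conf.low`, `conf.high` in fit
#'   mode).
#' @export
heritability_curve <- function(object, grid = seq(-1, 1, length.out = 201),
                               sigma2_pe = NULL, sigma2_e = NULL,
                               class_bounds = NULL, conf_level = 0.95) {
  if (inherits(object, "rn_fit")) {
    if (is.null(class_bounds)) class_bounds <- object$design_info$class_bounds
    cls <- assign_residual_class(grid, class_bounds)
    ch <- object$chain
    nd <- nrow(ch)
    phi <- legendre_basis(grid)
    h2d <- matrix(NA_real_, nd, length(grid))
    se_mat <- as.matrix(ch[, paste0("sigma2_e", 1:5)])
    for (i in seq_len(nd)) {
      G <- matrix(c(ch$sigma2_0[i], ch$sigma01[i], ch$sigma01[i],
                    ch$sigma2_1[i]), 2)
      gkk <- rowSums((phi %*% G) * phi)
      h2d[i, ] <- gkk / (gkk + ch$sigma2_pe[i] + se_mat[i, cls])
    }
    a <- (1 - conf_level) / 2
    return(tibble::tibble(x = grid, class = cls,
                          h2 = colMeans(h2d),
                          conf.low = apply(h2d, 2, quantile, a),
                          conf.high = apply(h2d, 2, quantile, 1 - a)))
  }
  if (is.null(sigma2_pe) || is.null(sigma2_e) || is.null(class_bounds)) {
    hn_abort("matrix mode needs sigma2_pe, sigma2_e and class_bounds.",
             "heatnorm_domain_error")
  }
  cls <- assign_residual_class(grid, class_bounds)
  phi <- legendre_basis(grid)
  gkk <- rowSums((phi %*% as.matrix(object)) * phi)
  denom <- gkk + sigma2_pe + sigma2_e[cls]
  if (any(denom <= 0)) hn_abort("all-zero variance at some grid point.",
                                "heatnorm_domain_error")
  tibble::tibble(x = grid, class = cls, h2 = gkk / denom)
}

#' Reaction norms on the trait scale
#'
#' Population norm \eqn{r(x) = \alpha + \beta\,\phi_1(x)} and individual
#' norms \eqn{r_l(x) = \alpha + \phi_0\,\hat a_{0l} + (\beta + \hat
#' a_{1l})\,\phi_1(x)} from the posterior-mean solutions of a fit. `alpha`
#' is the fixed intercept (reference contemporary group and parity).
#'
#' @param fit An `rn_fit`.
#' @param grid Standardized covariate grid.
#' @param ids Animal ids for individual norms; `NULL` for the population
#'   norm only.
#' @return A tibble `level` ("population"/"individual"), `animal`, `x`,
#'   `value`, plus `raw` (the covariate on its original scale).
#' @export
reaction_norms <- function(fit, grid = seq(-1, 1, length.out = 41),
                           ids = NULL) {
  stopifnot(inherits(fit, "rn_fit"))
  phi <- legendre_basis(grid)
  alpha <- fit$location$fixed[["(Intercept)"]]
  beta <- fit$location$fixed[["beta_phi1"]]
  std <- fit$design_info$std
  raw <- std$midpoint + grid * (std$max - std$min) / 2
  pop <- tibble::tibble(level = "population", animal = NA_character_,
                        x = grid, raw = raw,
                        value = alpha + beta * phi[, "phi1"])
  if (is.null(ids)) return(pop)
  ids <- as.character(ids)
  miss <- setdiff(ids, names(fit$location$a0))
  if (length(miss) > 0) {
    hn_abort(paste0("unknown animal id(s): ",
                    paste(utils::head(miss, 5), collapse = ", ")),
             "heatnorm_id_error")
  }
  ind <- purrr::map_dfr(ids, function(id) {
    tibble::tibble(level = "individual", animal = id, x = grid, raw = raw,
                   value = alpha + fit$location$a0[[id]] * phi[, "phi0"] +
                     (beta + fit$location$a1[[id]]) * phi[, "phi1"])
  })
  dplyr::bind_rows(pop, ind)
}

#' Identify heat-tolerant and heat-susceptible sires
#'
#' Ranks sires by their estimated genetic slope \eqn{\beta + \hat a_{1l}}.
#' Eligible sires must have at least `min_daughters` daughters with
#' records, and those daughters' records must span the environmental
#' gradient: covering at least `min_range_cover` of the observed
#' standardized range and touching at least `min_classes` of the five
#' residual classes (so a sire judged only in comfortable conditions
#' cannot qualify). For a trait harmed by heat load, the `k` sires with
#' the highest slope are the most tolerant and the `k` lowest the most
#' susceptible.
#'
#' @param fit An `rn_fit`.
#' @param pedigree Pedigree tibble (to find each sow's sire).
#' @param records Phenotype tibble (sows with records).
#' @param fit_x Tibble `sow`, `parity`, `x`, `class` giving each record's
#'   standardized covariate and residual class (e.g. the generator truth,
#'   or rebuilt with [build_design()]).
#' @param min_daughters Minimum daughters with records (default 50).
#' @param k Number of sires per extreme (default 4).
#' @param min_range_cover Fraction of the observed x-range the daughters'
#'   records must span (default 0.6).
#' @param min_classes Minimum residual classes touched (default 4).
#' @return A list: `sires` (tibble of eligible sires with slopes, daughter
#'   counts and spread statistics), `tolerant`, `susceptible` (top/bottom
#'   `k`).
#' @export
select_extreme_sires <- function(fit, pedigree, records, fit_x,
                                 min_daughters = 50, k = 4,
                                 min_range_cover = 0.6, min_classes = 4) {
  stopifnot(inherits(fit, "rn_fit"))
  sire_of <- setNames(as.character(pedigree$sire), pedigree$animal)
  dat <- dplyr::inner_join(
    tibble::tibble(sow = as.character(fit_x$sow), parity = fit_x$parity,
                   x = fit_x$x, class = fit_x$class),
    tibble::tibble(sow = as.character(records$sow), parity = records$parity),
    by = c("sow", "parity"))
  dat$sire <- sire_of[dat$sow]
  dat <- dat[!is.na(dat$sire), , drop = FALSE]
  xr <- diff(range(dat$x))
  beta <- fit$location$fixed[["beta_phi1"]]
  stats <- dat %>%
    dplyr::group_by(sire = .data$sire) %>%
    dplyr::summarise(n_daughters = dplyr::n_distinct(.data$sow),
                     n_records = dplyr::n(),
                     range_cover = diff(range(.data$x)) / xr,
                     n_classes = dplyr::n_distinct(.data$class),
                     .groups = "drop") %>%
    dplyr::mutate(slope = beta + fit$location$a1[.data$sire],
                  eligible = .data$n_daughters >= min_daughters &
                    .data$range_cover >= min_range_cover &
                    .data$n_classes >= min_classes)
  elig <- dplyr::arrange(dplyr::filter(stats, .data$eligible),
                         dplyr::desc(.data$slope))
  if (nrow(elig) < 2 * k) {
    warning("only ", nrow(elig), " eligible sires for k = ", k,
            "; returning what exists.", call. = FALSE)
  }
  list(sires = stats,
       tolerant = utils::head(elig, min(k, nrow(elig))),
       susceptible = dplyr::arrange(utils::tail(elig, min(k, nrow(elig))),
                                    .data$slope))
}
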