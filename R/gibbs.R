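#' Priors for the reaction-norm Gibbs sampler
#'
#' Conjugate priors in the inverse-Wishart / scaled inverse-chi-square
#' family: the conditional for **G** is IW(`G_nu` + n_animals,
#' `G_scale` + S) and each scalar variance has a scaled inverse-chi-square
#' conditional. The defaults are *flat* (improper) priors — `G_nu = -3`
#' with a zero scale and `nu = -2`, `s2 = 0` for the scalars — whose
#' conditionals are proper whenever the effect counts exceed a handful.
#' Flat priors matter here: the genetic intercept variance is only weakly
#' separated from the permanent-environment variance (both are constant
#' within sow), and a seemingly mild proper prior such as IW(4, I) carries
#' several log-units of density against variances of magnitude 5-30 along
#' that flat likelihood direction, visibly biasing the posterior. Proper
#' weakly informative priors can still be supplied when regularization is
#' wanted (e.g. `rn_priors(G_nu = 4, G_scale = diag(2))`).
#'
#' @param G_nu,G_scale Inverse-Wishart degrees of freedom and scale matrix
#'   for **G** (flat: `-3` and a zero matrix).
#' @param nu_pe,s2_pe Permanent environment prior df and scale.
#' @param nu_e,s2_e Residual-class prior df and scale.
#' @return A list of prior settings.
#' @export
rn_priors <- function(G_nu = -3, G_scale = matrix(0, 2, 2), nu_pe = -2,
                      s2_pe = 0, nu_e = -2, s2_e = 0) {
  list(G_nu = G_nu, G_scale = G_scale, nu_pe = nu_pe, s2_pe = s2_pe,
       nu_e = nu_e, s2_e = s2_e)
}

#' Gibbs sampler for the single-step reaction-norm model
#'
#' Samples the mixed model \eqn{y = Xb + \phi_0 a_0 + \phi_1(x) a_1 + p + e}
#' with \eqn{(a_0, a_1) \sim N(0, H \otimes G)},
#' \eqn{p \sim N(0, I\sigma^2_{pe})} and five residual-variance classes.
#' Each iteration draws all location effects jointly from their conditional
#' normal via a sparse Cholesky factorization (distributionally equivalent
#' to single-site Gibbs, and far better mixing), then **G** from its
#' inverse-Wishart conditional and the scalar variances from scaled
#' inverse-chi-square conditionals (each residual class uses only its own
#' records). With `fix_variances = TRUE` the location draws are i.i.d.
#' samples from the exact location posterior at the given variances.
#'
#' @param design An `rn_design` from [build_design()].
#' @param h_inverse An `h_inverse` from [build_H_inverse()] spanning every
#'   sow with records.
#' @param priors A [rn_priors()] list.
#' @param iterations,burn_in,thin Chain length, burn-in, thinning interval.
#' @param seed Integer seed; the chain is bit-reproducible given it.
#' @param start Optional list with starting `G`, `sigma2_pe`, `sigma2_e`.
#' @param fix_variances If `TRUE`, variance components stay at `start`
#'   values and only locations are sampled.
#' @param store_location If `TRUE`, keep the thinned draws of all location
#'   effects (memory scales with equations x stored draws).
#' @param verbose Print progress every 10,000 iterations.
#' @return An `rn_fit` object; see [tidy.rn_fit()] and [glance.rn_fit()].
#' @export
gibbs_sample <- function(design, h_inverse, priors = rn_priors(),
                         iterations = 20000, burn_in = 4000, thin = 4,
                         seed = 1L, start = NULL, fix_variances = FALSE,
                         store_location = FALSE, verbose = FALSE) {
  stopifnot(inherits(design, "rn_design"), inherits(h_inverse, "h_inverse"))
  if (burn_in >= iterations) {
    hn_abort("burn_in must be smaller than iterations.", "heatnorm_chain_error")
  }
  set.seed(as.integer(seed))

  ids <- h_inverse$ids
  n_a <- length(ids)
  anim <- match(design$sow, ids)
  if (anyNA(anim)) {
    hn_abort("some sows with records are absent from the relationship matrix.",
             "heatnorm_id_error")
  }
  us <- unique(design$sow)
  pe_idx <- match(design$sow, us)
  n_pe <- length(us)
  n <- design$n
  X <- design$X
  p <- ncol(X)
  q <- p + 2L * n_a + n_pe
  y <- design$y

  W <- cbind(
    methods::as(X, "CsparseMatrix"),
    Matrix::sparseMatrix(i = seq_len(n), j = anim, x = design$phi[, "phi0"],
                         dims = c(n, n_a)),
    Matrix::sparseMatrix(i = seq_len(n), j = anim, x = design$phi[, "phi1"],
                         dims = c(n, n_a)),
    Matrix::sparseMatrix(i = seq_len(n), j = pe_idx, x = rep(1, n),
                         dims = c(n, n_pe)))
  cls <- design$class
  n_cls <- tabulate(cls, 5L)
  Mt <- lapply(1:5, function(t) {
    rows <- which(cls == t)
    Matrix::forceSymmetric(Matrix::crossprod(W[rows, , drop = FALSE]))
  })
  vt <- lapply(1:5, function(t) {
    rows <- which(cls == t)
    as.vector(Matrix::crossprod(W[rows, , drop = FALSE], y[rows]))
  })
  Hinv <- methods::as(h_inverse$mat, "generalMatrix")
  asm <- build_mme_assembler(Mt, h_inverse$mat, p, n_a, n_pe)

  # starting values
  v_y <- var(y)
  Gc <- if (!is.null(start$G)) start$G else diag(2) * v_y / 4
  s2pe <- if (!is.null(start$sigma2_pe)) start$sigma2_pe else v_y / 4
  s2e <- if (!is.null(start$sigma2_e)) start$sigma2_e else rep(v_y / 2, 5)
  if (fix_variances && is.null(start)) {
    hn_abort("fix_variances = TRUE requires `start` values.",
             "heatnorm_chain_error")
  }

  n_store <- length(seq.int(burn_in + thin, iterations, by = thin))
  draws <- matrix(NA_real_, n_store, 9,
                  dimnames = list(NULL, c("sigma2_0", "sigma01", "sigma2_1",
                                          "sigma2_pe", paste0("sigma2_e", 1:5))))
  iters <- integer(n_store)
  loc_sum <- numeric(q)
  loc_draws <- if (store_location) matrix(NA_real_, n_store, q) else NULL
  ch <- NULL
  stored <- 0L

  pe_cols <- p + 2L * n_a + seq_len(n_pe)

  for (it in seq_len(iterations)) {
    lam <- 1 / s2e
    Ginv <- chol2inv(chol(Gc))
    C <- asm$fill(lam, Ginv, 1 / s2pe)
    r <- lam[1] * vt[[1]]
    for (t in 2:5) if (n_cls[t] > 0) r <- r + lam[t] * vt[[t]]
    # reuse the symbolic analysis across iterations
    ch_try <- if (is.null(ch)) NULL else
      tryCatch(Matrix::update(ch, C), error = function(e) NULL)
    ch <- if (!is.null(ch_try)) ch_try else
      tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE, super = TRUE),
               error = function(e) hn_abort(
                 paste0("non-positive-definite conditional at iteration ",
                        it, "."), "heatnorm_numeric_error"))
    mu <- as.vector(Matrix::solve(ch, r, system = "A"))
    z <- rnorm(q)
    dev <- as.vector(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                   system = "Pt"))
    theta <- mu + dev

    if (!fix_variances) {
      a0 <- theta[p + seq_len(n_a)]
      a1 <- theta[p + n_a + seq_len(n_a)]
      Tm <- cbind(a0, a1)
      S <- crossprod(Tm, as.matrix(Hinv %*% Tm))
      S <- (S + t(S)) / 2
      scale <- priors$G_scale + S
      df <- priors$G_nu + n_a
      Wdraw <- rWishart(1, df, chol2inv(chol(scale)))[, , 1]
      Gc <- chol2inv(chol(Wdraw))
      Gc <- (Gc + t(Gc)) / 2
      pev <- theta[pe_cols]
      s2pe <- (priors$nu_pe * priors$s2_pe + sum(pev^2)) /
        rchisq(1, priors$nu_pe + n_pe)
      e <- y - as.vector(W %*% theta)
      for (t in 1:5) {
        sse <- sum(e[cls == t]^2)
        s2e[t] <- (priors$nu_e * priors$s2_e + sse) /
          rchisq(1, priors$nu_e + n_cls[t])
      }
    }

    if (it > burn_in && (it - burn_in) %% thin == 0) {
      stored <- stored + 1L
      draws[stored, ] <- c(Gc[1, 1], Gc[1, 2], Gc[2, 2], s2pe, s2e)
      iters[stored] <- it
      loc_sum <- loc_sum + theta
      if (store_location) loc_draws[stored, ] <- theta
    }
    if (verbose && it %% 10000 == 0) {
      message("iteration ", it, ": G = [",
              paste(signif(c(Gc[1, 1], Gc[1, 2], Gc[2, 2]), 4),
                    collapse = ", "), "]")
    }
  }

  loc_mean <- loc_sum / stored
  location <- list(
    fixed = setNames(loc_mean[seq_len(p)], colnames(X)),
    a0 = setNames(loc_mean[p + seq_len(n_a)], ids),
    a1 = setNames(loc_mean[p + n_a + seq_len(n_a)], ids),
    pe = setNames(loc_mean[pe_cols], us))
  if (store_location) {
    colnames(loc_draws) <- c(colnames(X), paste0("a0_", ids),
                             paste0("a1_", ids), paste0("pe_", us))
  }
  structure(list(
    chain = tibble::as_tibble(cbind(tibble::tibble(draw = seq_len(stored),
                                                   iteration = iters),
                                    tibble::as_tibble(draws))),
    location = location,
    location_draws = loc_draws,
    design_info = list(trait = design$trait, covariate = design$covariate,
                       std = design$std, class_bounds = design$class_bounds,
                       n_records = n, n_animals = n_a, n_sows = n_pe,
                       fixed_names = colnames(X)),
    h_ids = ids, genotyped_ids = h_inverse$genotyped_ids,
    chain_meta = list(iterations = iterations, burn_in = burn_in,
                      thin = thin, seed = as.integer(seed),
                      n_draws = stored, fix_variances = fix_variances),
    priors = priors), class = "rn_fit")
}

#' @export
print.rn_fit <- function(x, ...) {
  cm <- x$chain_meta
  cat("<rn_fit> ", x$design_info$trait, " on ", x$design_info$covariate,
      ": ", x$design_info$n_records, " records, ", cm$n_draws,
      " stored draws (", cm$iterations, " iterations, burn-in ",
      cm$burn_in, ", thin ", cm$thin, ")\n", sep = "")
  print(tidy(x), n = 9)
  invisible(x)
}

#' Posterior summaries of the variance components
#'
#' @param x An `rn_fit`.
#' @param conf_level Credible-interval mass (default 0.95, equal tails).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high`.
#' @method tidy rn_fit
#' @export
tidy.rn_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  ch <- dplyr::select(x$chain, -dplyr::all_of(c("draw", "iteration")))
  purrr::map_dfr(names(ch), function(nm) {
    v <- ch[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' One-row fit summary
#'
#' @param x An `rn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with problem sizes and chain settings.
#' @method glance rn_fit
#' @export
glance.rn_fit <- function(x, ...) {
  di <- x$design_info; cm <- x$chain_meta
  tibble::tibble(trait = di$trait, covariate = di$covariate,
                 n_records = di$n_records, n_animals = di$n_animals,
                 n_sows = di$n_sows, iterations = cm$iterations,
                 burn_in = cm$burn_in, thin = cm$thin, n_draws = cm$n_draws,
                 seed = cm$seed)
}

# Precomputed scatter maps for the mixed-model coefficient matrix
#'
#' The conditional precision of the location effects is
#' C = sum_t lambda_t W_t'W_t + blockdiag(0, Ginv (x) Hinv, I / s2pe).
#' Its sparsity pattern is fixed across iterations, so the symbolic work
#' (key matching into the upper-triangle template) is done once and each
#' iteration only rescales and scatters numeric values.
#' @noRd
build_mme_assembler <- function(Mt, Hsym, p, n_a, n_pe) {
  Hu <- methods::as(Matrix::forceSymmetric(Hsym, uplo = "U"), "CsparseMatrix")
  Hg <- methods::as(Hsym, "generalMatrix")
  q <- p + 2L * n_a + n_pe
  keys_of <- function(i, j) i + q * j  # 0-based row/col -> unique key
  dsc_keys <- function(M) {
    j <- rep.int(seq_len(ncol(M)) - 1L, diff(M@p))
    keys_of(M@i, j)
  }
  ucsparse <- function(M) methods::as(M, "CsparseMatrix")
  Mt_u <- lapply(Mt, ucsparse)
  # kron cross-block keys: H general entry (i,j) -> C entry (p+i, p+n_a+j)
  hg_j <- rep.int(seq_len(ncol(Hg)) - 1L, diff(Hg@p))
  k_h11 <- keys_of(Hu@i + p, rep.int(seq_len(n_a) - 1L, diff(Hu@p)) + p)
  k_h22 <- keys_of(Hu@i + p + n_a,
                   rep.int(seq_len(n_a) - 1L, diff(Hu@p)) + p + n_a)
  k_h12 <- keys_of(Hg@i + p, hg_j + p + n_a)
  k_pe <- keys_of(p + 2L * n_a + seq_len(n_pe) - 1L,
                  p + 2L * n_a + seq_len(n_pe) - 1L)
  k_fix <- keys_of(seq_len(p) - 1L, seq_len(p) - 1L)
  # union template with all-positive values (no cancellation drops)
  abs_x <- function(M) { M@x <- abs(M@x) + 1; M }
  Tpl <- Reduce(`+`, lapply(Mt_u, abs_x))
  Kp <- Matrix::sparseMatrix(
    i = c(Hu@i + p, Hu@i + p + n_a, Hg@i + p, rep(p + 2L * n_a, 0)) + 1L,
    j = c(rep.int(seq_len(n_a) - 1L, diff(Hu@p)) + p,
          rep.int(seq_len(n_a) - 1L, diff(Hu@p)) + p + n_a,
          hg_j + p + n_a) + 1L,
    x = 1, dims = c(q, q))
  Dg <- Matrix::sparseMatrix(i = c(seq_len(p), p + 2L * n_a + seq_len(n_pe)),
                             j = c(seq_len(p), p + 2L * n_a + seq_len(n_pe)),
                             x = 1, dims = c(q, q))
  Tpl <- Matrix::forceSymmetric(Tpl + Kp + Dg, uplo = "U")
  Tpl <- methods::as(Tpl, "CsparseMatrix")
  tkey <- dsc_keys(Tpl)
  pos <- list(M = lapply(Mt_u, function(M) match(dsc_keys(M), tkey)),
              h11 = match(k_h11, tkey), h22 = match(k_h22, tkey),
              h12 = match(k_h12, tkey), pe = match(k_pe, tkey),
              fix = match(k_fix, tkey))
  # one column per scalar coefficient; each iteration is a single gemv
  nnz <- length(tkey)
  B <- matrix(0, nnz, 9)
  for (t in 1:5) B[pos$M[[t]], t] <- Mt_u[[t]]@x
  B[pos$h11, 6] <- Hu@x
  B[pos$h22, 7] <- Hu@x
  B[pos$h12, 8] <- B[pos$h12, 8] + Hg@x
  B[pos$pe, 9] <- 1
  fill <- function(lam, Ginv, inv_s2pe) {
    Tpl@x <- drop(B %*% c(lam, Ginv[1, 1], Ginv[2, 2], Ginv[1, 2],
                          inv_s2pe))
    Tpl
  }
  list(fill = fill, template = Tpl)
}

#' Posterior mean G matrix of a fit
#'
#' @param fit An `rn_fit`.
#' @return The 2x2 posterior-mean genetic (co)variance matrix.
#' @export
posterior_G <- function(fit) {
  matrix(c(mean(fit$chain$sigma2_0), mean(fit$chain$sigma01),
           mean(fit$chain$sigma01), mean(fit$chain$sigma2_1)), 2,
         dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
}

#' Geweke convergence diagnostic
#'
#' Standard Geweke z-scores comparing the mean of the first `frac1` of each
#' stored chain against the last `frac2`, with spectral-density variance
#' estimates.
#'
#' @param chain An `rn_fit` or a tibble/matrix of chain draws.
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return A tibble with `term` and `z`.
#' @export
geweke_diagnostic <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  m <- if (inherits(chain, "rn_fit")) {
    as.matrix(dplyr::select(chain$chain,
                            -dplyr::all_of(c("draw", "iteration"))))
  } else {
    as.matrix(chain)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (nrow(m) < 100) {
    hn_abort("need at least 100 stored draws for the Geweke diagnostic.",
             "heatnorm_chain_error")
  }
  const <- apply(m, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    hn_abort(paste0("constant chain component(s): ",
                    paste(colnames(m)[const], collapse = ", "),
                    "; spectral variance undefined."),
             "heatnorm_chain_error")
  }
  z <- coda::geweke.diag(coda::mcmc(m), frac1 = frac1, frac2 = frac2)$z
  tibble::tibble(term = colnames(m), z = unname(z))
}
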