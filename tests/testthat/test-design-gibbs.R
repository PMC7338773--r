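toy_design_inputs <- function() {
  records <- tibble::tibble(
    sow = c(1L, 1L, 1L, 2L, 2L),
    parity = c(1L, 2L, 3L, 1L, 2L),
    birth_year = c(1L, 1L, 1L, 2L, 2L),
    tnb = c(11, 12, 13, 10, 9))
  env <- tibble::tibble(sow = records$sow, parity = records$parity,
                        RH_2 = c(20, 50, 80, 35, 65))
  list(records = records, env = env)
}

test_that("design rows share animal and pe levels within sow", {
  ti <- toy_design_inputs()
  d <- build_design(ti$records, ti$env, "tnb", "RH_2")
  expect_equal(d$n, 5)
  expect_equal(d$sow, as.character(c(1, 1, 1, 2, 2)))
  # hand-built oracle: standardized x and incidence
  x <- 2 * (ti$env$RH_2 - 20) / (80 - 20) - 1
  expect_equal(d$x, x)
  expect_equal(d$phi[, "phi1"], sqrt(1.5) * x)
  expect_equal(unname(d$X[, "(Intercept)"]), rep(1, 5))
  expect_equal(unname(d$X[, "beta_phi1"]), sqrt(1.5) * x)
  # record at the column midpoint has zero slope covariable
  expect_equal(d$phi[3, "phi1"], -d$phi[1, "phi1"] - 0)
  mid <- which(abs(ti$env$RH_2 - 50) < 1e-9)
  expect_equal(unname(d$phi[mid, "phi1"]), 0)
  # factor dummies: birth year 2 indicator on the last two records
  cg_col <- grep("^cg", colnames(d$X), value = TRUE)
  expect_equal(unname(d$X[, cg_col]), c(0, 0, 0, 1, 1))
})

test_that("records dropped for NA trait values and unmatched sows error", {
  ti <- toy_design_inputs()
  ti$records$tnb[2] <- NA
  d <- build_design(ti$records, ti$env, "tnb", "RH_2")
  expect_equal(d$n, 4)
  ti2 <- toy_design_inputs()
  ti2$env <- ti2$env[-1, ]
  expect_error(build_design(ti2$records, ti2$env, "tnb", "RH_2"),
               class = "heatnorm_design_error")
})

test_that("fixed-variance posterior means match the MME oracle", {
  fx <- small_fixture()
  d <- fx$design
  hinv <- fx$hinv
  start <- list(G = matrix(c(6, 1, 1, 4), 2), sigma2_pe = 10,
                sigma2_e = c(28, 30, 32, 34, 36))
  fit <- gibbs_sample(d, hinv, iterations = 600, burn_in = 100, thin = 1,
                      seed = 5, start = start, fix_variances = TRUE,
                      store_location = TRUE)
  # oracle: dense mixed-model equations built independently
  ids <- hinv$ids
  n_a <- length(ids)
  anim <- match(d$sow, ids)
  us <- unique(d$sow)
  pe_idx <- match(d$sow, us)
  W <- cbind(d$X,
             outer(seq_len(d$n), seq_len(n_a),
                   function(i, j) (anim[i] == j) * d$phi[i, "phi0"]),
             outer(seq_len(d$n), seq_len(n_a),
                   function(i, j) (anim[i] == j) * d$phi[i, "phi1"]),
             outer(seq_len(d$n), seq_along(us),
                   function(i, j) (pe_idx[i] == j) * 1))
  Rinv <- diag(1 / start$sigma2_e[d$class])
  Hi <- as.matrix(solve(as.matrix(build_A(fx$sim$pedigree))))
  # genomic correction
  A <- build_A(fx$sim$pedigree)
  gi <- match(fx$gids, ids)
  Hi[gi, gi] <- Hi[gi, gi] + solve(fx$Gs$mat) - solve(A[fx$gids, fx$gids])
  Ginv <- solve(start$G)
  p <- ncol(d$X)
  Prior <- matrix(0, ncol(W), ncol(W))
  ai <- p + seq_len(2 * n_a)
  Prior[ai, ai] <- kronecker(Ginv, Hi)
  pi <- p + 2 * n_a + seq_along(us)
  Prior[pi, pi] <- diag(1 / start$sigma2_pe, length(us))
  C <- crossprod(W, Rinv) %*% W + Prior
  sol <- solve(C, crossprod(W, Rinv %*% d$y))
  # with fixed variances the stored draws are i.i.d. from the exact
  # posterior, so the Monte Carlo standard error is sd/sqrt(ndraws)
  est <- colMeans(fit$location_draws)
  mcse <- apply(fit$location_draws, 2, sd) / sqrt(nrow(fit$location_draws))
  z <- abs(est - as.vector(sol)) / pmax(mcse, 1e-12)
  expect_lt(mean(z > 2), 0.1)   # ~5% expected by chance
  expect_lt(max(abs(est - as.vector(sol))), 0.5)
})

test_that("chains are bit-identical under the same seed", {
  fx <- small_fixture()
  f1 <- gibbs_sample(fx$design, fx$hinv, iterations = 150, burn_in = 50,
                     thin = 2, seed = 77)
  f2 <- gibbs_sample(fx$design, fx$hinv, iterations = 150, burn_in = 50,
                     thin = 2, seed = 77)
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$location, f2$location)
  expect_equal(nrow(f1$chain), (150 - 50) / 2)
})

test_that("posterior variance draws are scale-equivariant", {
  fx <- small_fixture()
  c_sc <- 3
  d2 <- fx$design
  d2$y <- d2$y * c_sc
  # under flat priors the posterior is exactly scale-equivariant, and with
  # a common seed the two chains are rescaled copies of each other
  f1 <- gibbs_sample(fx$design, fx$hinv, iterations = 120,
                     burn_in = 20, thin = 1, seed = 9)
  f2 <- gibbs_sample(d2, fx$hinv, iterations = 120,
                     burn_in = 20, thin = 1, seed = 9)
  expect_equal(f2$chain$sigma2_1, c_sc^2 * f1$chain$sigma2_1,
               tolerance = 1e-8)
  expect_equal(f2$chain$sigma2_e3, c_sc^2 * f1$chain$sigma2_e3,
               tolerance = 1e-8)
})

test_that("ssGBLUP reduces to pedigree BLUP when the genomic block is A22", {
  fx <- small_fixture()
  ped <- fx$sim$pedigree
  A <- fx$A
  gids <- fx$gids
  h_ped <- build_H_inverse(ped)
  h_a22 <- build_H_inverse(ped, A[gids, gids], gids)
  start <- list(G = matrix(c(6, 1, 1, 4), 2), sigma2_pe = 10,
                sigma2_e = rep(30, 5))
  f1 <- gibbs_sample(fx$design, h_ped, iterations = 800, burn_in = 100,
                     thin = 1, seed = 4, start = start,
                     fix_variances = TRUE, store_location = TRUE)
  f2 <- gibbs_sample(fx$design, h_a22, iterations = 800, burn_in = 100,
                     thin = 1, seed = 4, start = start,
                     fix_variances = TRUE, store_location = TRUE)
  # identical posteriors up to A22 inversion round-off; the residual
  # discrepancy between the two mean vectors is pure Monte Carlo noise
  mdiff <- colMeans(f1$location_draws) - colMeans(f2$location_draws)
  mcse <- sqrt(apply(f1$location_draws, 2, var) / nrow(f1$location_draws) +
                 apply(f2$location_draws, 2, var) / nrow(f2$location_draws))
  z <- abs(mdiff) / pmax(mcse, 1e-12)
  expect_lt(mean(z > 3), 0.02)
  expect_lt(max(abs(mdiff)), 1)
})

test_that("Geweke diagnostic separates stationary from trending chains", {
  set.seed(31)
  # null: fraction of |z| < 3 across many i.i.d. chains
  z <- replicate(300, geweke_diagnostic(matrix(rnorm(500)))$z)
  expect_gte(mean(abs(z) < 3), 0.98)
  # a strong linear trend is flagged
  trend <- matrix(seq(0, 10, length.out = 500) + rnorm(500, 0, 0.1))
  expect_gt(abs(geweke_diagnostic(trend)$z), 5)
  # constant chain: spectral variance undefined
  expect_error(geweke_diagnostic(matrix(rep(1, 500))),
               class = "heatnorm_chain_error")
  expect_error(geweke_diagnostic(matrix(rnorm(50))),
               class = "heatnorm_chain_error")
})

test_that("tidy and glance summarize a fit", {
  fx <- small_fixture()
  fit <- gibbs_sample(fx$design, fx$hinv, iterations = 150, burn_in = 50,
                      thin = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 50)
  expect_equal(gl$trait, "tnb")
})
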