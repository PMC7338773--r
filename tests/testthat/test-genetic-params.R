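test_that("gamma matrix equals brute-force per-pair evaluation", {
  G <- matrix(c(8.93, 0.61, 0.61, 6.57), 2)
  grid <- seq(-1, 1, length.out = 11)
  gm <- gamma_matrix(G, grid)
  phi <- function(x) c(sqrt(0.5), sqrt(1.5) * x)
  oracle <- outer(seq_along(grid), seq_along(grid),
                  Vectorize(function(i, j) {
                    drop(phi(grid[i]) %*% G %*% phi(grid[j]))
                  }))
  expect_equal(unname(gm$gamma), oracle, tolerance = 1e-12)
})

test_that("no slope variance means perfect correlations everywhere", {
  gm <- gamma_matrix(diag(c(4, 0)), seq(-1, 1, length.out = 21))
  expect_equal(unname(gm$gamma),
               matrix(2, 21, 21), tolerance = 1e-12)  # c/2 everywhere
  s <- correlation_summary(gm)
  expect_equal(s$min, 1)
  expect_equal(s$median, 1)
})

test_that("identity G gives the closed-form extreme correlation", {
  gm <- gamma_matrix(diag(2))
  s <- correlation_summary(gm)
  # corr(-1, +1) = (0.5 - 1.5) / (0.5 + 1.5)
  expect_equal(s$min, -0.5, tolerance = 1e-10)
})

test_that("correlations are invariant to rescaling G", {
  G <- matrix(c(10, -2, -2, 5), 2)
  s1 <- correlation_summary(gamma_matrix(G))
  s2 <- correlation_summary(gamma_matrix(G * 3.7))
  expect_equal(s1$min, s2$min, tolerance = 1e-12)
  expect_equal(s1$median, s2$median, tolerance = 1e-12)
})

test_that("the correlation minimum is attained at the grid extremes", {
  set.seed(2)
  for (i in 1:10) {
    L <- matrix(rnorm(4), 2)
    G <- crossprod(L) + diag(0.1, 2)
    gm <- gamma_matrix(G, seq(-1, 1, length.out = 101))
    R <- cov2cor(gm$gamma)
    expect_equal(min(R[upper.tri(R)]), R[1, 101], tolerance = 1e-10)
  }
})

test_that("heritability formula and class structure behave as expected", {
  bounds <- c(-0.6, -0.2, 0.2, 0.6)
  # flat genetic variance (no slope), increasing residual classes:
  # h2 is a non-increasing step function
  h2 <- heritability_curve(diag(c(2, 0)), sigma2_pe = 1,
                           sigma2_e = c(2, 3, 4, 5, 6),
                           class_bounds = bounds)
  expect_equal(h2$h2[1], 1 / (1 + 1 + 2))
  expect_true(all(diff(h2$h2) <= 1e-12))
  expect_equal(sort(unique(h2$class)), 1:5)
  # zero genetic variance: h2 = 0
  h0 <- heritability_curve(matrix(0, 2, 2), sigma2_pe = 1,
                           sigma2_e = rep(2, 5), class_bounds = bounds)
  expect_true(all(h0$h2 == 0))
  # in (0, 1] whenever Gamma_kk > 0
  hpos <- heritability_curve(matrix(c(5, 1, 1, 3), 2), sigma2_pe = 1,
                             sigma2_e = 1:5, class_bounds = bounds)
  expect_true(all(hpos$h2 > 0 & hpos$h2 <= 1))
})

test_that("heritability bands propagate posterior draws", {
  fx <- small_fixture()
  fit <- gibbs_sample(fx$design, fx$hinv, iterations = 200, burn_in = 50,
                      thin = 2, seed = 2)
  h2 <- heritability_curve(fit, grid = seq(-1, 1, length.out = 41))
  expect_true(all(h2$conf.low <= h2$h2 & h2$h2 <= h2$conf.high))
  expect_true(all(h2$h2 > 0 & h2$h2 < 1))
})

test_that("reaction norms evaluate linearly on the trait scale", {
  fx <- small_fixture()
  fit <- gibbs_sample(fx$design, fx$hinv, iterations = 150, burn_in = 50,
                      thin = 2, seed = 6)
  alpha <- fit$location$fixed[["(Intercept)"]]
  beta <- fit$location$fixed[["beta_phi1"]]
  grid <- c(-1, 0, 1)
  pop <- reaction_norms(fit, grid)
  expect_equal(pop$value, alpha + beta * sqrt(1.5) * grid)
  id <- names(fit$location$a0)[5]
  rn <- reaction_norms(fit, grid, ids = id)
  ind <- rn[rn$level == "individual", ]
  expect_equal(ind$value,
               alpha + fit$location$a0[[id]] * sqrt(0.5) +
                 (beta + fit$location$a1[[id]]) * sqrt(1.5) * grid)
  # zero genetic deviations: individual equals population
  fit0 <- fit
  fit0$location$a0[id] <- 0
  fit0$location$a1[id] <- 0
  rn0 <- reaction_norms(fit0, grid, ids = id)
  expect_equal(rn0$value[rn0$level == "individual"],
               rn0$value[rn0$level == "population"])
  expect_error(reaction_norms(fit, grid, ids = "no-such-animal"),
               class = "heatnorm_id_error")
})

test_that("sire selection enforces daughter counts and gradient spread", {
  fx <- small_fixture()
  fit <- gibbs_sample(fx$design, fx$hinv, iterations = 150, burn_in = 50,
                      thin = 2, seed = 8)
  fit_x <- fx$sim$truth$record_env
  # every sire has 5 daughters with 3 records each: none eligible at 50
  res50 <- suppressWarnings(
    select_extreme_sires(fit, fx$sim$pedigree, fx$sim$records, fit_x,
                         min_daughters = 50))
  expect_equal(nrow(res50$tolerant), 0)
  # with the threshold at 5 all sires are eligible; k = 2 returns 2 + 2
  res <- select_extreme_sires(fit, fx$sim$pedigree, fx$sim$records, fit_x,
                              min_daughters = 5, k = 2)
  expect_equal(nrow(res$tolerant), 2)
  expect_equal(nrow(res$susceptible), 2)
  expect_true(min(res$tolerant$slope) >= max(res$susceptible$slope))
  expect_true(all(res$sires$n_daughters == 5))
  # a sire whose daughters sit in one corner of the gradient is excluded
  fit_x2 <- fit_x
  one_sire <- res$sires$sire[1]
  sows1 <- fx$sim$pedigree$animal[!is.na(fx$sim$pedigree$sire) &
                                    fx$sim$pedigree$sire == one_sire]
  idx <- fit_x2$sow %in% sows1
  fit_x2$x[idx] <- -1
  fit_x2$class[idx] <- 1L
  res2 <- select_extreme_sires(fit, fx$sim$pedigree, fx$sim$records,
                               fit_x2, min_daughters = 5, k = 2)
  expect_false(res2$sires$eligible[res2$sires$sire == one_sire])
})
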