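test_that("tabular A reproduces classic hand-checked relationships", {
  A <- build_A(toy_pedigree())
  # parent-offspring
  expect_equal(A["1", "3"], 0.5)
  # full sibs
  expect_equal(A["3", "4"], 0.5)
  expect_equal(unname(diag(A)[1:4]), rep(1, 4))
  # offspring of full sibs: F = 0.25
  expect_equal(A["5", "5"], 1.25)
  f <- pedigree_inbreeding(toy_pedigree())
  expect_equal(unname(f["5"]), 0.25)
})

test_that("tabular A equals Wright's path counting on a 3-generation pedigree", {
  # half sibs through a common sire: a = sum over paths (1/2)^(n_links)
  ped <- tibble::tibble(animal = 1:5, sire = c(NA, NA, NA, 1L, 1L),
                        dam = c(NA, NA, NA, 2L, 3L),
                        sex = c("M", "F", "F", "F", "F"),
                        generation = c(1, 1, 1, 2, 2))
  A <- build_A(ped)
  expect_equal(A["4", "5"], 0.25)   # one path of two links
  expect_equal(A["1", "4"], 0.5)
  expect_equal(A["2", "5"], 0)      # unrelated
})

test_that("Henderson's sparse inverse matches the dense inverse", {
  for (ped in list(toy_pedigree(), small_fixture()$sim$pedigree)) {
    A <- build_A(ped)
    Ainv <- build_A_inverse(ped)
    expect_lt(max(abs(as.matrix(Ainv) - solve(A))), 1e-10)
  }
})

test_that("pedigree cycles are reported by name", {
  bad <- tibble::tibble(animal = 1:2, sire = c(2L, 1L), dam = c(NA, NA),
                        sex = c("M", "M"), generation = c(1L, 1L))
  expect_error(build_A(bad), class = "heatnorm_pedigree_error")
})

test_that("QC removes exactly the violating SNPs", {
  set.seed(5)
  n <- 400
  good <- replicate(5, rbinom(n, 2, 0.4))
  mono <- matrix(0L, n, 1)                         # MAF 0
  low_maf <- matrix(rbinom(n, 2, 0.02), n, 1)      # MAF ~0.02
  miss <- matrix(rbinom(n, 2, 0.4), n, 1)
  miss[sample(n, 50), 1] <- NA                     # call rate 0.875
  hwe_bad <- matrix(rep(1L, n), n, 1)              # all hets, p = 0.5
  M <- cbind(good, mono, low_maf, miss, hwe_bad)
  qc <- qc_genotypes(toy_geno(M))
  expect_equal(qc$report$n_removed[qc$report$filter == "total"], 4)
  expect_equal(ncol(qc$genotypes$dosage), 5)
  expect_equal(qc$report$n_removed[qc$report$filter == "call_rate"], 1)
  expect_gte(qc$report$n_removed[qc$report$filter == "maf"], 2)
  expect_gte(qc$report$n_removed[qc$report$filter == "hwe"], 1)
})

test_that("the HWE filter has near-zero false-positive rate at 1e-6", {
  set.seed(8)
  M <- replicate(1000, rbinom(500, 2, 0.3))
  qc <- qc_genotypes(toy_geno(M))
  expect_lte(qc$report$n_removed[qc$report$filter == "hwe"], 1)
})

test_that("VanRaden-2 G evaluates exactly on a single SNP", {
  M <- matrix(c(0L, 1L, 2L), 3, 1)
  G <- build_G_vanraden2(toy_geno(M))
  # p = 0.5: Z = (-1, 0, 1), D = 1/(1 * 0.5) = 2
  expect_equal(unname(diag(G$mat)), c(2, 0, 2))
  expect_equal(unname(G$d), 2)
})

test_that("G has unit mean diagonal under HWE and is order-invariant", {
  set.seed(3)
  n <- 500; m <- 2000
  p <- runif(m, 0.1, 0.5)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  g <- toy_geno(M)
  G <- build_G_vanraden2(g)
  expect_equal(mean(diag(G$mat)), 1, tolerance = 0.05)
  # permuting SNPs leaves G unchanged
  perm <- sample(m)
  G2 <- build_G_vanraden2(subset_genotypes(g, snps = perm))
  expect_equal(G$mat, G2$mat, tolerance = 1e-12)
  # duplicated animals give identical rows/columns
  M3 <- rbind(M, M[7, , drop = FALSE])
  rownames(M3) <- c(seq_len(n), "dup")
  G3 <- build_G_vanraden2(toy_geno(M3))
  expect_equal(unname(G3$mat["dup", seq_len(n)]),
               unname(G3$mat["7", seq_len(n)]))
})

test_that("blending interpolates between G and A22 and fixes rank", {
  fx <- small_fixture()
  A22 <- fx$A[fx$gids, fx$gids]
  g1 <- blend_G(fx$G, A22, omega = 1)
  expect_equal(g1$mat, fx$G$mat)
  g0 <- blend_G(fx$G, A22, omega = 0)
  expect_equal(unname(g0$mat), unname(A22))
  g95 <- blend_G(fx$G, A22, omega = 0.95)
  ev <- eigen(g95$mat, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0.05 * min(eigen(A22, symmetric = TRUE,
                                      only.values = TRUE)$values) - 1e-10)
})

test_that("H inverse reduces to A inverse without genomic information", {
  ped <- small_fixture()$sim$pedigree
  h <- build_H_inverse(ped)
  expect_identical(h$mat, build_A_inverse(ped))
  # genomic block equal to A22: correction vanishes
  A <- build_A(ped)
  gids <- as.character(sample(ped$animal, 20))
  h2 <- build_H_inverse(ped, A[gids, gids], gids)
  expect_lt(max(abs(h2$mat - build_A_inverse(ped))), 1e-8)
})

test_that("H inverse matches the brute-force joint-distribution oracle", {
  # 6-animal pedigree, animals 5 and 6 genotyped
  ped <- tibble::tibble(animal = 1:6, sire = c(NA, NA, 1L, 1L, 3L, 3L),
                        dam = c(NA, NA, 2L, 2L, 4L, 2L),
                        sex = c("M", "F", "M", "F", "F", "F"),
                        generation = c(1, 1, 2, 2, 3, 3))
  A <- build_A(ped)
  gids <- c("5", "6")
  Gstar <- A[gids, gids] * 1.08 + diag(0.02, 2)  # an arbitrary PD genomic block
  # oracle: H from the conditional-distribution identity, inverted densely
  nid <- setdiff(rownames(A), gids)
  A11 <- A[nid, nid]; A12 <- A[nid, gids]
  A22 <- A[gids, gids]; A22i <- solve(A22)
  H <- rbind(
    cbind(A11 + A12 %*% A22i %*% (Gstar - A22) %*% A22i %*% t(A12),
          A12 %*% A22i %*% Gstar),
    cbind(Gstar %*% A22i %*% t(A12), Gstar))
  ord <- c(nid, gids)
  Horacle <- solve(H)
  h <- build_H_inverse(ped, Gstar, gids)
  expect_lt(max(abs(as.matrix(h$mat)[ord, ord] - Horacle)), 1e-8)
})
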