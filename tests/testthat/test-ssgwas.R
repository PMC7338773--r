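hwe_geno <- function(n, m, seed = 1, n_chrom = 1) {
  set.seed(seed)
  p <- runif(m, 0.15, 0.5)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(M) <- as.character(seq_len(n))
  toy_geno(M, chrom = sort(rep_len(seq_len(n_chrom), m)),
           pos = as.integer(seq_len(m) * 1000))
}

test_that("back-solving is exact for a determined toy system", {
  # one SNP, breeding values generated directly from a known effect
  g <- toy_geno(matrix(c(0L, 2L), 2, 1))
  u_true <- 0.7
  Z <- sweep(g$dosage, 2, 2 * g$freq)
  a <- tibble::tibble(animal = rownames(g$dosage),
                      intercept = drop(Z * u_true))
  eff <- backsolve_snp_effects(a, g)
  expect_equal(eff$intercept, u_true, tolerance = 1e-10)
  # zero breeding values give zero effects
  a0 <- tibble::tibble(animal = rownames(g$dosage), intercept = c(0, 0))
  expect_equal(backsolve_snp_effects(a0, g)$intercept, 0)
})

test_that("back-solved effects reconstruct the gEBV when omega = 1", {
  g <- hwe_geno(40, 50, seed = 12)
  set.seed(13)
  u_true <- rnorm(50, 0, 0.3)
  Z <- sweep(g$dosage, 2, 2 * g$freq)
  a <- tibble::tibble(animal = rownames(g$dosage),
                      intercept = drop(Z %*% u_true),
                      slope = drop(Z %*% rev(u_true)))
  eff <- backsolve_snp_effects(a, g)
  recon <- Z %*% cbind(eff$intercept, eff$slope)
  expect_lt(norm(recon - cbind(a$intercept, a$slope), "F") /
              norm(cbind(a$intercept, a$slope), "F"), 1e-8)
  expect_gt(cor(recon[, 1], a$intercept), 0.99)
})

test_that("a 10-SNP genome forms one window carrying all the variance", {
  g <- hwe_geno(30, 10, seed = 3)
  set.seed(4)
  eff <- dplyr::bind_cols(g$map,
                          tibble::tibble(intercept = rnorm(10, 0, 0.5)))
  wv <- window_variance(eff, g)
  expect_equal(nrow(wv), 1)
  expect_equal(wv$pct_var, 100)
  expect_equal(wv$n_snps, 10)
})

test_that("window counts and effect localization follow the sliding rule", {
  g <- hwe_geno(60, 120, seed = 5, n_chrom = 2)
  u <- rep(0, 120)
  u[31:40] <- rnorm(10, 0, 1)   # all signal inside one window on chrom 1
  eff <- dplyr::bind_cols(g$map, tibble::tibble(intercept = u))
  wv <- window_variance(eff, g)
  # 60 SNPs per chromosome: 51 windows each
  expect_equal(as.integer(table(wv$chrom)), c(51L, 51L))
  hot <- wv[wv$chrom == 1 & wv$window == 31, ]
  expect_gt(hot$pct_var, 90)
  far <- wv[wv$chrom == 2, ]
  expect_lt(max(far$pct_var), 5)
  # windows never span chromosomes
  expect_true(all(wv$n_snps == 10))
})

test_that("top-window selection takes ceiling(q * W) per term with stable ties", {
  g <- hwe_geno(30, 109, seed = 6)   # 100 windows
  set.seed(7)
  eff <- dplyr::bind_cols(g$map,
                          tibble::tibble(intercept = rnorm(109),
                                         slope = rnorm(109)))
  wv <- window_variance(eff, g)
  sel <- select_top_windows(wv, quantile = 0.01)
  expect_equal(sum(sel$selected[sel$term == "intercept"]), 1)
  expect_equal(sum(sel$selected[sel$term == "slope"]), 1)
  # all-equal shares: deterministic tie-break keeps the first position
  wv2 <- wv
  wv2$pct_var <- 1
  sel2 <- select_top_windows(wv2, quantile = 0.01)
  picked <- sel2[sel2$selected & sel2$term == "intercept", ]
  expect_equal(picked$window, 1)
  expect_equal(attr(sel2, "n_union"), 1)
})

test_that("bootstrap test is seeded, reproducible and powerful", {
  g <- hwe_geno(40, 209, seed = 8)
  set.seed(9)
  u <- rnorm(209, 0, 0.05)
  u[100:109] <- rnorm(10, 0, 2)   # one window dominates
  eff <- dplyr::bind_cols(g$map, tibble::tibble(slope = u))
  wv <- select_top_windows(window_variance(eff, g), quantile = 0.01)
  expect_warning(bootstrap_test(wv, eff, g, B = 50, seed = 1), "unstable")
  b1 <- bootstrap_test(wv, eff, g, B = 200, seed = 21)
  b2 <- bootstrap_test(wv, eff, g, B = 200, seed = 21)
  expect_identical(b1$significant, b2$significant)
  hot <- b1[which.max(b1$pct_var), ]
  expect_true(hot$window >= 91 && hot$window <= 100)  # in the signal region
  expect_true(hot$selected && hot$significant)
  expect_true(all(is.na(b1$significant[!b1$selected])))
})

test_that("window-gene overlap matches hand enumeration and is half-open", {
  windows <- tibble::tibble(term = "slope", chrom = c(1L, 1L),
                            window = 1:2,
                            start_bp = c(1000L, 5000L),
                            end_bp = c(2001L, 6001L),
                            n_snps = 10L, pct_var = c(2, 3))
  genes <- tibble::tibble(chrom = 1L,
                          start = c(1500L, 2001L, 900L),
                          end = c(1600L, 2200L, 1000L),
                          gene = c("inside", "after_end", "ends_at_start"))
  ov <- annotate_windows(windows, genes)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$gene, "inside")
  expect_equal(ov$overlap_bp, 100)
  # chromosome mismatch errors with names
  genes_bad <- dplyr::mutate(genes, chrom = "chrX")
  expect_error(annotate_windows(windows, genes_bad),
               class = "heatnorm_id_error")
})

test_that("GFF3 gene annotations are read into half-open intervals", {
  skip_if_not_installed("rtracklayer")
  gff <- file.path(tempdir(), "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t1500\t1599\t.\t+\t.\tID=g1;Name=GENE1",
    "1\ttest\tmRNA\t1500\t1599\t.\t+\t.\tID=t1;Parent=g1",
    "2\ttest\tgene\t100\t200\t.\t-\t.\tID=g2;Name=GENE2"), gff)
  genes <- read_gene_annotation(gff)
  expect_equal(nrow(genes), 2)                 # mRNA dropped
  expect_equal(genes$gene, c("GENE1", "GENE2"))
  expect_equal(genes$start[1], 1500)
  expect_equal(genes$end[1], 1600)             # closed 1599 -> half-open 1600
})
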