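#' Pedigree relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix **A** by the
#' recursive tabular method, with inbreeding. Ancestors further back than
#' `max_generations` generations are treated as unknown founders.
#'
#' @param pedigree Pedigree tibble (`animal`, `sire`, `dam`).
#' @param max_generations Pedigree depth to retain (default 10).
#' @return A dense symmetric matrix with animal ids as dimnames; the
#'   diagonal is \eqn{1 + F}.
#' @export
build_A <- function(pedigree, max_generations = 10) {
  pedigree <- truncate_pedigree(check_pedigree(pedigree), max_generations)
  n <- nrow(pedigree)
  sp <- match(pedigree$sire, pedigree$animal)
  dp <- match(pedigree$dam, pedigree$animal)
  A <- matrix(0, n, n, dimnames = list(pedigree$animal, pedigree$animal))
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

# Generation-depth truncation: animals more than max_generations above the
# deepest descendant keep no parent links.
truncate_pedigree <- function(pedigree, max_generations) {
  n <- nrow(pedigree)
  sp <- match(pedigree$sire, pedigree$animal)
  dp <- match(pedigree$dam, pedigree$animal)
  gi <- integer(n)
  for (i in seq_len(n)) {
    gi[i] <- 1L + max(0L, if (!is.na(sp[i])) gi[sp[i]] else 0L,
                      if (!is.na(dp[i])) gi[dp[i]] else 0L)
  }
  cut <- max(gi) - max_generations
  if (cut > 0) {
    # ancestors above the retained depth become founders
    drop <- gi <= cut
    pedigree$sire[drop] <- NA_integer_
    pedigree$dam[drop] <- NA_integer_
  }
  pedigree
}

#' Inbreeding coefficients from a pedigree
#'
#' @param pedigree Pedigree tibble sorted or sortable parents-first.
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
pedigree_inbreeding <- function(pedigree) {
  A <- build_A(pedigree, max_generations = .Machine$integer.max)
  f <- diag(A) - 1
  names(f) <- rownames(A)
  f
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' \eqn{1/d_i} terms to its own, its parents' and the cross positions,
#' where \eqn{d_i} is the Mendelian-sampling variance given the parents'
#' inbreeding.
#'
#' @inheritParams build_A
#' @return A sparse symmetric `Matrix` (class `dsCMatrix`) with animal ids
#'   as dimnames; agrees with `solve(build_A(pedigree))` to numerical
#'   precision.
#' @export
build_A_inverse <- function(pedigree, max_generations = 10) {
  pedigree <- truncate_pedigree(check_pedigree(pedigree), max_generations)
  n <- nrow(pedigree)
  f <- pedigree_inbreeding(pedigree)
  sp <- match(pedigree$sire, pedigree$animal)
  dp <- match(pedigree$dam, pedigree$animal)
  fs <- ifelse(is.na(sp), 0, f[replace(sp, is.na(sp), 1L)])
  fd <- ifelse(is.na(dp), 0, f[replace(dp, is.na(dp), 1L)])
  d <- 1 - ifelse(is.na(sp), 0, 0.25 * (1 + fs)) -
    ifelse(is.na(dp), 0, 0.25 * (1 + fd))
  alpha <- 1 / d
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    lo <- pmin(i, j); hi <- pmax(i, j)
    ii[[k]] <<- hi; jj[[k]] <<- lo; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  ks <- !is.na(sp); kd <- !is.na(dp)
  add(idx[ks], sp[ks], -0.5 * alpha[ks])
  add(idx[kd], dp[kd], -0.5 * alpha[kd])
  add(sp[ks], sp[ks], 0.25 * alpha[ks])
  add(dp[kd], dp[kd], 0.25 * alpha[kd])
  both <- ks & kd
  add(sp[both], dp[both], 0.25 * alpha[both])
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               symmetric = TRUE,
                               dimnames = list(pedigree$animal,
                                               pedigree$animal))
  Ainv
}

#' Genotype quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min`, call rate
#' below `call_rate_min`, or a Hardy-Weinberg chi-square goodness-of-fit
#' p-value below `hwe_p_min`. Missing dosages (`NA`) are allowed and
#' excluded from the per-SNP statistics.
#'
#' @param genotypes A `geno_set`.
#' @param maf_min,call_rate_min,hwe_p_min Filter thresholds.
#' @return A list: `genotypes` (filtered `geno_set`) and `report` (tibble
#'   of per-filter failure counts; SNPs can fail several filters).
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.05, call_rate_min = 0.90,
                         hwe_p_min = 1e-6) {
  M <- genotypes$dosage
  n <- nrow(M)
  n_obs <- colSums(!is.na(M))
  call_rate <- n_obs / n
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  n2 <- colSums(M == 2L, na.rm = TRUE)
  n1 <- colSums(M == 1L, na.rm = TRUE)
  n0 <- n_obs - n1 - n2
  hwe_p <- hwe_pvalue(n0, n1, n2)
  fail_maf <- maf < maf_min | n_obs == 0
  fail_cr <- call_rate < call_rate_min
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_p_min
  fail <- fail_maf | fail_cr | fail_hwe
  if (all(fail)) hn_abort("all SNPs removed by QC.", "heatnorm_qc_error")
  report <- tibble::tibble(
    filter = c("maf", "call_rate", "hwe", "total"),
    n_removed = c(sum(fail_maf), sum(fail_cr), sum(fail_hwe), sum(fail)))
  list(genotypes = subset_genotypes(genotypes, snps = which(!fail)),
       report = report)
}

# chi-square (1 df) goodness-of-fit test for HWE on genotype counts
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chi <- rep(NA_real_, length(n))
  ok <- n > 0 & p > 0 & p < 1
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  ifelse(ok, pchisq(chi, df = 1, lower.tail = FALSE), NA_real_)
}

#' Genomic relationship matrix (VanRaden method 2)
#'
#' \eqn{G = Z D Z'} with \eqn{Z = M - 2p} (column-centered dosages, missing
#' values mean-imputed to \eqn{2p_i}) and
#' \eqn{D = \mathrm{diag}\{1 / [m \cdot 2 p_i (1 - p_i)]\}} where `m` is
#' the SNP count. Under Hardy-Weinberg equilibrium the mean diagonal is
#' close to 1. Allele frequencies are computed from the genotyped sample.
#'
#' @param genotypes A QC'd `geno_set`.
#' @return A `g_matrix` list: `mat` (dense symmetric matrix with animal-id
#'   dimnames), `d` (per-SNP weights), `p` (allele frequencies), `omega`
#'   (blending weight, 1 before blending).
#' @export
build_G_vanraden2 <- function(genotypes) {
  M <- genotypes$dosage
  p <- colMeans(M, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    hn_abort("fixed SNPs present; run qc_genotypes() first.",
             "heatnorm_qc_error")
  }
  m <- ncol(M)
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0
  d <- 1 / (m * 2 * p * (1 - p))
  Zs <- sweep(Z, 2, sqrt(d), "*")
  G <- tcrossprod(Zs)
  structure(list(mat = G, d = d, p = p, omega = 1), class = "g_matrix")
}

#' Blend the genomic matrix with its pedigree counterpart
#'
#' \eqn{G^* = \omega G + (1 - \omega) A_{22}}; guarantees invertibility of
#' the genomic block for the single-step inverse with negligible
#' distortion at the default \eqn{\omega = 0.95}.
#'
#' @param G A `g_matrix`.
#' @param A22 Pedigree relationship block of the genotyped animals (dense
#'   matrix with matching dimnames).
#' @param omega Genomic weight in \[0, 1\].
#' @return A blended `g_matrix`.
#' @export
blend_G <- function(G, A22, omega = 0.95) {
  ids <- rownames(G$mat)
  if (is.null(rownames(A22)) || !identical(ids, rownames(A22))) {
    if (!all(ids %in% rownames(A22))) {
      hn_abort("A22 ids do not cover the genotyped animals.",
               "heatnorm_id_error")
    }
    A22 <- A22[ids, ids]
  }
  G$mat <- omega * G$mat + (1 - omega) * A22
  G$omega <- omega
  G
}

#' Single-step relationship inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} -
#'   A_{22}^{-1}\end{bmatrix}}
#' in the ordering of the pedigree, with the correction placed on the
#' genotyped animals' block. With no genotyped animals this is exactly
#' \eqn{A^{-1}}; with \eqn{G^* = A_{22}} the correction vanishes.
#'
#' @param pedigree Pedigree tibble.
#' @param g_star Blended `g_matrix` (or plain matrix with id dimnames);
#'   `NULL` for a pedigree-only inverse.
#' @param genotyped_ids Animal ids of the genotyped block.
#' @param max_generations Pedigree depth for **A** (default 10).
#' @return An `h_inverse` list: `mat` (sparse symmetric Matrix), `ids`,
#'   `genotyped_ids`.
#' @export
build_H_inverse <- function(pedigree, g_star = NULL, genotyped_ids = NULL,
                            max_generations = 10) {
  pedigree <- check_pedigree(pedigree)
  Ainv <- build_A_inverse(pedigree, max_generations)
  ids <- rownames(Ainv)
  if (is.null(g_star) || is.null(genotyped_ids) || length(genotyped_ids) == 0) {
    return(structure(list(mat = Ainv, ids = ids, genotyped_ids = character()),
                     class = "h_inverse"))
  }
  Gm <- if (inherits(g_star, "g_matrix")) g_star$mat else g_star
  gids <- as.character(genotyped_ids)
  if (!all(gids %in% ids)) {
    hn_abort("genotyped ids missing from the pedigree.", "heatnorm_id_error")
  }
  if (!all(gids %in% rownames(Gm))) {
    hn_abort("genotyped ids missing from G*.", "heatnorm_id_error")
  }
  Gm <- Gm[gids, gids]
  A <- build_A(pedigree, max_generations)
  A22 <- A[gids, gids]
  Ginv <- tryCatch(solve(Gm),
                   error = function(e) hn_abort(
                     "G* is singular; blend it with A22 (see blend_G()).",
                     "heatnorm_singular_error"))
  corr <- Ginv - solve(A22)
  gi <- match(gids, ids)
  Corr <- Matrix::sparseMatrix(i = rep(gi, each = length(gi)),
                               j = rep(gi, times = length(gi)),
                               x = as.vector(t(corr)),
                               dims = dim(Ainv), dimnames = dimnames(Ainv))
  H <- Matrix::forceSymmetric((Ainv + Corr), uplo = "U")
  structure(list(mat = H, ids = ids, genotyped_ids = gids),
            class = "h_inverse")
}
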