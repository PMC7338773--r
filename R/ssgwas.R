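#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the genotyped animals' estimated breeding values into per-SNP
#' effects, \eqn{\hat u = D Z' G^{-1} \hat a} with \eqn{Z = M - 2p} and
#' \eqn{D} the VanRaden method-2 weights — the transformation under which
#' \eqn{Z\hat u} reproduces the breeding values exactly when the unblended
#' \eqn{G = Z D Z'} is used.
#'
#' @param gebv Tibble with `animal` plus one column per term (e.g.
#'   `intercept`, `slope`), or a matrix with animal-id rownames. Typically
#'   the posterior means `a0`/`a1` of an `rn_fit` restricted to genotyped
#'   animals.
#' @param genotypes The genotyped animals' `geno_set` (QC'd).
#' @param g_matrix Optional `g_matrix` whose `mat` was used in the
#'   evaluation (e.g. blended); defaults to the raw VanRaden-2 matrix.
#' @param ridge Small non-negative ridge added to the diagonal before
#'   inversion. With observed allele frequencies the raw `G` is singular
#'   (column-centering puts the ones vector in its null space), so the
#'   inverse is the Moore-Penrose pseudoinverse by default: breeding
#'   values in the column space of `G` — in particular any `Z u` — are
#'   reconstructed exactly.
#' @return A `snp_effects` tibble: `snp`, `chrom`, `pos`, one effect
#'   column per term, with the `d` weights and allele frequencies as
#'   attributes.
#' @export
backsolve_snp_effects <- function(gebv, genotypes, g_matrix = NULL,
                                  ridge = 0) {
  if (is.data.frame(gebv)) {
    a <- as.matrix(gebv[, setdiff(names(gebv), "animal"), drop = FALSE])
    rownames(a) <- as.character(gebv$animal)
  } else {
    a <- as.matrix(gebv)
  }
  ids <- rownames(genotypes$dosage)
  if (!all(ids %in% rownames(a))) {
    hn_abort("gebv missing for some genotyped animals.", "heatnorm_id_error")
  }
  a <- a[ids, , drop = FALSE]
  if (is.null(g_matrix)) g_matrix <- build_G_vanraden2(genotypes)
  Gm <- g_matrix$mat[ids, ids]
  if (ridge > 0) Gm <- Gm + diag(ridge, nrow(Gm))
  sol <- tryCatch(solve(Gm, a), error = function(e) NULL)
  if (is.null(sol)) {
    # symmetric pseudoinverse solve; exact on the column space of G
    eg <- eigen(Gm, symmetric = TRUE)
    tol <- max(eg$values) * nrow(Gm) * .Machine$double.eps
    pos <- eg$values > tol
    if (!any(pos)) hn_abort("G has no positive eigenvalues.",
                            "heatnorm_singular_error")
    V <- eg$vectors[, pos, drop = FALSE]
    sol <- V %*% ((crossprod(V, a)) / eg$values[pos])
  }
  p <- g_matrix$p
  Z <- sweep(genotypes$dosage, 2, 2 * p)
  Z[is.na(Z)] <- 0
  u <- (g_matrix$d) * crossprod(Z, sol)   # D Z' G^-1 a
  out <- dplyr::bind_cols(genotypes$map,
                          tibble::as_tibble(as.matrix(u),
                                            .name_repair = "minimal"))
  attr(out, "d") <- g_matrix$d
  attr(out, "p") <- p
  class(out) <- c("snp_effects", class(out))
  out
}

#' Variance shares of 10-SNP sliding windows
#'
#' For each term and each window of `window` consecutive SNPs (sliding by
#' `slide` within a chromosome; a chromosome with fewer SNPs than `window`
#' forms a single window), computes the direct genomic values
#' \eqn{DGV_w = Z_w \hat u_w} across genotyped animals and reports
#' \eqn{100 \cdot \mathrm{Var}(DGV_w) / \mathrm{Var}(Z\hat u)} — the
#' window's share of whole-genome direct-genomic-value variance.
#' Variances use the population divisor `n`.
#'
#' @param effects A `snp_effects` table from [backsolve_snp_effects()].
#' @param genotypes The matching `geno_set`.
#' @param terms Effect columns to scan; default all non-map columns.
#' @param window,slide Window size in SNPs and slide step (defaults 10, 1).
#' @return A tibble: `term`, `chrom`, `window`, `start_bp`, `end_bp`
#'   (half-open, last SNP position + 1), `n_snps`, `pct_var`.
#' @export
window_variance <- function(effects, genotypes, terms = NULL, window = 10,
                            slide = 1) {
  map <- genotypes$map
  if (!identical(map$snp, effects$snp)) {
    effects <- effects[match(map$snp, effects$snp), , drop = FALSE]
    if (anyNA(effects$snp)) hn_abort("effects/genotypes SNP mismatch.",
                                     "heatnorm_id_error")
  }
  if (is.null(terms)) terms <- setdiff(names(effects), c("snp", "chrom", "pos"))
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  p <- colMeans(genotypes$dosage, na.rm = TRUE) / 2
  Z <- sweep(genotypes$dosage, 2, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- Z[, ord, drop = FALSE]
  n <- nrow(Z)
  pvar <- function(m) colSums(sweep(m, 2, colMeans(m))^2) / n

  purrr::map_dfr(terms, function(term) {
    u <- effects[[term]][ord]
    E <- sweep(Z, 2, u, "*")
    total <- sum((rowSums(E) - mean(rowSums(E)))^2) / n
    if (total <= 0) hn_abort("zero total DGV variance.",
                             "heatnorm_domain_error")
    purrr::map_dfr(split(seq_along(u), map$chrom), function(idx) {
      s <- length(idx)
      if (s < window) {
        starts <- 1L; sizes <- s
      } else {
        starts <- seq.int(1L, s - window + 1L, by = slide)
        sizes <- rep(window, length(starts))
      }
      # cumulative sums over the chromosome make each window two lookups
      Cs <- cbind(0, t(apply(E[, idx, drop = FALSE], 1, cumsum)))
      D <- Cs[, starts + sizes, drop = FALSE] - Cs[, starts, drop = FALSE]
      tibble::tibble(term = term, chrom = map$chrom[idx[1]],
                     window = seq_along(starts),
                     start_bp = map$pos[idx[starts]],
                     end_bp = map$pos[idx[starts + sizes - 1L]] + 1L,
                     n_snps = sizes,
                     pct_var = unname(100 * pvar(D) / total))
    })
  })
}

#' Select top windows by variance share
#'
#' Flags, independently per term, the `ceiling(quantile * W)` windows with
#' the largest variance share (`W` = windows for that term). Ties are
#' broken deterministically by chromosome and position. The union of the
#' two terms' selections is reported as an attribute, since selections are
#' made per term but usually summarized jointly.
#'
#' @param windows Output of [window_variance()].
#' @param quantile Selection fraction (default 0.01, the top 1%).
#' @return `windows` with a logical `selected` column; attributes
#'   `n_selected` (per term) and `n_union` (distinct windows selected for
#'   at least one term).
#' @export
select_top_windows <- function(windows, quantile = 0.01) {
  # deterministic tie-break: order by pct desc then chrom/pos before ranking
  out <- windows %>%
    dplyr::arrange(.data$term, dplyr::desc(.data$pct_var), .data$chrom,
                   .data$start_bp) %>%
    dplyr::group_by(.data$term) %>%
    dplyr::mutate(selected = dplyr::row_number() <=
                    ceiling(quantile * dplyr::n())) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$term, .data$chrom, .data$window)
  sel <- dplyr::filter(out, .data$selected)
  attr(out, "n_selected") <- table(sel$term)
  attr(out, "n_union") <- nrow(dplyr::distinct(sel, .data$chrom,
                                               .data$window))
  out
}

#' Bootstrap significance test for selected windows
#'
#' Builds a null distribution of the maximum window variance share by `B`
#' rearrangements of the SNP-effect vector along the genome, breaking the
#' link between effect sizes and genomic position while preserving the
#' effect-size distribution. A selected window is significant when its
#' observed share exceeds the `1 - alpha` quantile of the null maxima for
#' its term. Under exchangeable (i.i.d.) effects both rearrangement
#' schemes give an exactly calibrated max-statistic test; the default full
#' permutation also disperses clustered signal effects and therefore has
#' power against localized QTL, whereas a circular shift keeps clustered
#' effects together (retained as an option for spatially structured
#' nulls). Seeded and reproducible.
#'
#' @param windows Output of [select_top_windows()] (rows with `selected`
#'   are tested; all rows if no `selected` column).
#' @param effects The `snp_effects` used for the scan.
#' @param genotypes The matching `geno_set`.
#' @param B Number of rearrangements (default 1000; a warning below 100).
#' @param alpha Significance level (default 0.05).
#' @param method `"permutation"` (default) or `"circular"`.
#' @param seed Integer seed.
#' @return `windows` with logical `significant` (NA for untested rows);
#'   attribute `null_quantile` per term.
#' @export
bootstrap_test <- function(windows, effects, genotypes, B = 1000,
                           alpha = 0.05,
                           method = c("permutation", "circular"),
                           seed = 1L) {
  method <- match.arg(method)
  if (B < 100) warning("B < 100 gives unstable null quantiles.",
                       call. = FALSE)
  set.seed(as.integer(seed))
  if (!"selected" %in% names(windows)) windows$selected <- TRUE
  terms <- unique(windows$term)
  window <- max(windows$n_snps)
  map <- genotypes$map
  ord <- order(map$chrom, map$pos)
  p_frq <- colMeans(genotypes$dosage, na.rm = TRUE) / 2
  Z <- sweep(genotypes$dosage, 2, 2 * p_frq)
  Z[is.na(Z)] <- 0
  Z <- Z[, ord, drop = FALSE]
  m <- ncol(Z)
  n <- nrow(Z)
  # sliding-window indicator (SNPs x windows), chromosome-respecting
  chrom_idx <- split(seq_len(m), map$chrom[ord])
  wlist <- unlist(lapply(chrom_idx, function(idx) {
    s <- length(idx)
    starts <- if (s < window) 1L else seq.int(1L, s - window + 1L)
    lapply(starts, function(st) idx[st:min(st + window - 1L, s)])
  }), recursive = FALSE)
  Sw <- matrix(0, m, length(wlist))
  for (w in seq_along(wlist)) Sw[wlist[[w]], w] <- 1
  max_pct <- function(u) {
    E <- sweep(Z, 2, u, "*")
    D <- E %*% Sw
    tot <- rowSums(E)
    vtot <- sum((tot - mean(tot))^2)
    100 * max(colSums(sweep(D, 2, colMeans(D))^2)) / vtot
  }
  eff_ord <- effects[match(map$snp[ord], effects$snp), , drop = FALSE]
  qs <- setNames(numeric(length(terms)), terms)
  for (term in terms) {
    u0 <- eff_ord[[term]]
    maxima <- numeric(B)
    for (b in seq_len(B)) {
      idx <- if (method == "circular") {
        shift <- sample.int(m - 1L, 1L)
        ((seq_len(m) - 1L + shift) %% m) + 1L
      } else {
        sample.int(m)
      }
      maxima[b] <- max_pct(u0[idx])
    }
    qs[term] <- quantile(maxima, 1 - alpha, names = FALSE)
  }
  windows$significant <- ifelse(windows$selected,
                                windows$pct_var > qs[windows$term], NA)
  attr(windows, "null_quantile") <- qs
  windows
}
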