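#' Simulate SNP genotypes by Mendelian gene dropping
#'
#' Founders receive Hardy-Weinberg genotypes at per-SNP allele frequencies
#' drawn uniformly from `maf_range`; descendants receive one allele from
#' each parent (a heterozygous parent transmits either allele with
#' probability 1/2). Loci segregate independently (no linkage). Allele
#' frequencies on the output are recomputed from the realized dosages.
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return A `geno_set` list: `map` (tibble `snp`, `chrom`, `pos`),
#'   `dosage` (animals x SNPs matrix of 0/1/2 with animal-id rownames) and
#'   `freq` (realized allele frequency of the counted allele per SNP).
#' @export
simulate_genotypes <- function(pedigree, config) {
  pedigree <- check_pedigree(pedigree)
  set.seed(config$seed + 1L)
  m <- config$n_snps
  n <- nrow(pedigree)
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
    sort(sample.int(1e8, length(i)))
  }), use.names = FALSE)
  map <- tibble::tibble(snp = paste0("snp", seq_len(m)), chrom = chrom,
                        pos = pos)
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  M <- matrix(0L, n, m, dimnames = list(pedigree$animal, map$snp))
  sp <- match(pedigree$sire, pedigree$animal)
  dp <- match(pedigree$dam, pedigree$animal)
  # transmit one gamete from a parent's dosage row
  gamete <- function(dos) {
    g <- as.integer(dos >= 2L)
    het <- dos == 1L
    g[het] <- rbinom(sum(het), 1L, 0.5)
    g
  }
  for (i in seq_len(n)) {
    if (is.na(sp[i]) && is.na(dp[i])) {
      M[i, ] <- rbinom(m, 2L, p)
    } else {
      gs <- if (is.na(sp[i])) rbinom(m, 1L, p) else gamete(M[sp[i], ])
      gd <- if (is.na(dp[i])) rbinom(m, 1L, p) else gamete(M[dp[i], ])
      M[i, ] <- gs + gd
    }
  }
  new_geno_set(map, M)
}

new_geno_set <- function(map, dosage) {
  structure(list(map = map, dosage = dosage,
                 freq = colMeans(dosage, na.rm = TRUE) / 2),
            class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("<geno_set> ", nrow(x$dosage), " animals x ", nrow(x$map), " SNPs on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Subset a genotype set by animal and/or SNP
#'
#' @param geno A `geno_set`.
#' @param animals Optional animal ids to keep.
#' @param snps Optional SNP ids (or logical/integer index) to keep.
#' @return A `geno_set` with recomputed allele frequencies.
#' @export
subset_genotypes <- function(geno, animals = NULL, snps = NULL) {
  M <- geno$dosage
  map <- geno$map
  if (!is.null(animals)) {
    idx <- match(as.character(animals), rownames(M))
    if (anyNA(idx)) hn_abort("unknown animal id(s) in subset.",
                             "heatnorm_id_error")
    M <- M[idx, , drop = FALSE]
  }
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, map$snp) else snps
    M <- M[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  new_geno_set(map, M)
}
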