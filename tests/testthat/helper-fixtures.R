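# Shared small-scale fixtures, built once per test run.

small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_founders = 60, n_sires_per_gen = 10, n_daughters_per_sire = 5,
         n_parities_per_sow = 3, n_snps = 300, n_years = 3, seed = seed),
    list(...))
  do.call(sim_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

# herd + relationship matrices + design at smoke-test scale, cached
small_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  sim <- simulate_herd(small_config())
  qc <- qc_genotypes(subset_genotypes(sim$genotypes,
                                      animals = sim$genotyped_ids))
  G <- build_G_vanraden2(qc$genotypes)
  A <- build_A(sim$pedigree)
  gids <- rownames(G$mat)
  Gs <- blend_G(G, A[gids, gids])
  hinv <- build_H_inverse(sim$pedigree, Gs, gids)
  design <- build_design(sim$records, sim$env, "tnb", sim$truth$env_column)
  .fixture_env$fx <- list(sim = sim, qc = qc, G = G, A = A, Gs = Gs,
                          hinv = hinv, design = design, gids = gids)
  .fixture_env$fx
}

# a tiny hand-checkable pedigree: two founders, two full sibs, one
# full-sib-mating offspring
toy_pedigree <- function() {
  tibble::tibble(animal = 1:5,
                 sire = c(NA, NA, 1L, 1L, 3L),
                 dam = c(NA, NA, 2L, 2L, 4L),
                 sex = c("M", "F", "M", "F", "F"),
                 generation = c(1L, 1L, 2L, 2L, 3L))
}

# deterministic geno_set from a dosage matrix
toy_geno <- function(M, chrom = NULL, pos = NULL) {
  m <- ncol(M)
  if (is.null(rownames(M))) rownames(M) <- as.character(seq_len(nrow(M)))
  colnames(M) <- paste0("snp", seq_len(m))
  map <- tibble::tibble(snp = colnames(M),
                        chrom = if (is.null(chrom)) rep(1L, m) else chrom,
                        pos = if (is.null(pos)) seq_len(m) * 1000L else pos)
  heatnorm:::new_geno_set(map, M)
}
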