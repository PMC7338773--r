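#' Write a simulated dataset to plain-text files
#'
#' Emits `pedigree.csv`, `phenotypes.csv`, `weather.csv`, `snp_map.csv`, a
#' PLINK-`.raw`-style genotype text file `genotypes.raw` (animal id
#' followed by one 0/1/2 column per SNP) and, when `jsonlite` is
#' available, `truth.json` with the generating parameters for recovery
#' tests.
#'
#' @param sim Output of [simulate_herd()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(sim$pedigree, "pedigree.csv")
  wcsv(sim$records, "phenotypes.csv")
  wcsv(sim$weather, "weather.csv")
  wcsv(sim$genotypes$map, "snp_map.csv")
  raw <- data.frame(IID = rownames(sim$genotypes$dosage),
                    sim$genotypes$dosage, check.names = FALSE)
  p <- file.path(dir, "genotypes.raw")
  utils::write.table(raw, p, row.names = FALSE, quote = FALSE, sep = " ")
  paths <- c(paths, p)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tp <- file.path(dir, "truth.json")
    truth <- sim$truth
    truth$varcomp$G <- as.vector(truth$varcomp$G)
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read a PLINK-raw-style genotype text file
#'
#' Expects a whitespace-separated table whose first column is the animal
#' id (`IID`) and remaining columns are 0/1/2 dosages named by SNP;
#' optionally joined with a SNP map (`snp`, `chrom`, `pos`).
#'
#' @param path Genotype file path.
#' @param map_path Optional `snp_map.csv` path; without it SNPs are placed
#'   on one pseudo-chromosome in column order.
#' @return A `geno_set`.
#' @export
read_genotypes_raw <- function(path, map_path = NULL) {
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
  id_col <- intersect(c("IID", "animal", "id"), names(raw))[1]
  if (is.na(id_col)) hn_abort("no animal id column (IID/animal/id).",
                              "heatnorm_io_error")
  M <- as.matrix(raw[, setdiff(names(raw), id_col), drop = FALSE])
  rownames(M) <- as.character(raw[[id_col]])
  storage.mode(M) <- "integer"
  map <- if (!is.null(map_path)) {
    tibble::as_tibble(utils::read.csv(map_path))
  } else {
    tibble::tibble(snp = colnames(M), chrom = 1L, pos = seq_len(ncol(M)))
  }
  map <- map[match(colnames(M), map$snp), ]
  new_geno_set(map, M)
}

#' Write an environmental covariate table with a standardization sidecar
#'
#' Writes the covariate table as CSV together with a JSON sidecar holding,
#' per covariate column, the observed min/max, the midpoint (the raw value
#' mapping to 0 on the standardized scale) and the four quintile class
#' boundaries.
#'
#' @param env_table Covariate tibble from [build_interval_covariates()].
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, the two paths.
#' @export
write_env_table <- function(env_table, path) {
  utils::write.csv(env_table, path, row.names = FALSE, quote = FALSE)
  cols <- setdiff(names(env_table), c("sow", "parity"))
  side <- lapply(cols, function(cl) {
    v <- env_table[[cl]]
    out <- list(min = min(v), max = max(v), midpoint = (min(v) + max(v)) / 2)
    if (length(unique(v)) >= 5) {
      s <- standardize_env(v)
      out$class_bounds <- residual_class_bounds(s$x)
    }
    out
  })
  names(side) <- cols
  jpath <- paste0(path, ".json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(side, jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(path, jpath))
}

#' Write a relationship matrix in MatrixMarket text format
#'
#' Sparse symmetric matrices (e.g. an `h_inverse`) are written with
#' `Matrix::writeMM`; dense matrices are coerced first. Animal ids go to
#' an `<path>.ids` sidecar, one id per line, in row order.
#'
#' @param mat An `h_inverse`, sparse `Matrix` or dense matrix with id
#'   dimnames.
#' @param path Output `.mtx` path.
#' @return Invisibly, the paths written.
#' @export
write_relationship <- function(mat, path) {
  if (inherits(mat, "h_inverse")) {
    ids <- mat$ids
    m <- mat$mat
  } else {
    ids <- rownames(mat)
    m <- mat
  }
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"),
                              "CsparseMatrix"), path)
  idp <- paste0(path, ".ids")
  writeLines(as.character(ids), idp)
  invisible(c(path, idp))
}
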