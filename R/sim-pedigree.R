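#' Simulate a sire-structured multi-generation pedigree
#'
#' Generation 1 holds `n_founders` unrelated founders (the first
#' `n_sires_per_gen` male, the rest female). In each later generation every
#' sire is mated to dams drawn with replacement from the previous
#' generation's females, producing exactly `n_daughters_per_sire` daughters;
#' `n_sons_per_gen` sons are produced round-robin across sires and become
#' the next generation's sires. Parents always precede offspring in the
#' returned table.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `animal`, `sire`, `dam` (integer ids, `NA`
#'   for unknown founder parents), `sex` ("M"/"F") and `generation`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_f <- config$n_founders
  sex <- c(rep("M", config$n_sires_per_gen),
           rep("F", n_f - config$n_sires_per_gen))
  ped <- tibble::tibble(animal = seq_len(n_f), sire = NA_integer_,
                        dam = NA_integer_, sex = sex, generation = 1L)
  next_id <- n_f + 1L
  for (g in seq_len(config$n_generations - 1L)) {
    prev <- dplyr::filter(ped, .data$generation == g)
    sires <- utils::head(prev$animal[prev$sex == "M"], config$n_sires_per_gen)
    dams_pool <- prev$animal[prev$sex == "F"]
    if (length(sires) == 0 || length(dams_pool) == 0) {
      hn_abort("pedigree generation ran out of sires or dams.",
               "heatnorm_config_error")
    }
    n_d <- config$n_daughters_per_sire
    n_s <- if (g < config$n_generations - 1L) config$n_sons_per_gen else 0L
    off_sire <- c(rep(sires, each = n_d),
                  rep_len(sires, n_s))
    off_dam <- sample(dams_pool, length(off_sire), replace = TRUE)
    off_sex <- c(rep("F", length(sires) * n_d), rep("M", n_s))
    ids <- seq.int(next_id, length.out = length(off_sire))
    ped <- dplyr::bind_rows(ped, tibble::tibble(animal = ids,
                                                sire = off_sire,
                                                dam = off_dam,
                                                sex = off_sex,
                                                generation = g + 1L))
    next_id <- next_id + length(off_sire)
  }
  ped
}

# Topologically sort a pedigree parents-first; errors naming a cycle.
check_pedigree <- function(pedigree) {
  a <- pedigree$animal
  if (anyDuplicated(a)) hn_abort("duplicate animal ids.", "heatnorm_pedigree_error")
  n <- length(a)
  sp <- match(pedigree$sire, a)
  dp <- match(pedigree$dam, a)
  placed <- logical(n)
  order_idx <- integer(n)
  filled <- 0L
  parent_placed <- function(p) {
    ok <- is.na(p)
    ok[!is.na(p)] <- placed[p[!is.na(p)]]
    ok
  }
  repeat {
    ready <- !placed & parent_placed(sp) & parent_placed(dp)
    if (!any(ready)) break
    idx <- which(ready)
    order_idx[filled + seq_along(idx)] <- idx
    filled <- filled + length(idx)
    placed[idx] <- TRUE
  }
  if (filled < n) {
    bad <- a[!placed]
    hn_abort(paste0("pedigree contains a cycle involving animal(s): ",
                    paste(utils::head(bad, 5), collapse = ", ")),
             "heatnorm_pedigree_error")
  }
  pedigree[order_idx, , drop = FALSE]
}
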