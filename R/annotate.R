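#' Overlap significant windows with gene annotations
#'
#' Half-open interval overlap between genomic windows (`[start_bp,
#' end_bp)`) and gene intervals (`[start, end)`): a gene ending exactly at
#' a window start does not overlap. Built on IRanges interval trees.
#'
#' @param windows Window tibble with `chrom`, `start_bp`, `end_bp` (e.g.
#'   significant rows of [bootstrap_test()] output).
#' @param genes Gene tibble with `chrom`, `start`, `end` (half-open) and
#'   `gene` (identifier), e.g. from [read_gene_annotation()].
#' @return A tibble: one row per window-gene overlap, with window columns,
#'   `gene` and `overlap_bp`.
#' @export
annotate_windows <- function(windows, genes) {
  for (pkg in c("IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      hn_abort(paste0(pkg, " is required for annotate_windows()."),
               "heatnorm_dependency_error")
    }
  }
  wch <- unique(as.character(windows$chrom))
  gch <- unique(as.character(genes$chrom))
  if (length(intersect(wch, gch)) == 0) {
    hn_abort(paste0("no shared chromosome names; windows have {",
                    paste(utils::head(wch, 5), collapse = ", "),
                    "} but annotation has {",
                    paste(utils::head(gch, 5), collapse = ", "), "}."),
             "heatnorm_id_error")
  }
  purrr::map_dfr(intersect(wch, gch), function(ch) {
    w <- windows[as.character(windows$chrom) == ch, , drop = FALSE]
    g <- genes[as.character(genes$chrom) == ch, , drop = FALSE]
    # half-open [a, b) as closed [a, b - 1]
    wr <- IRanges::IRanges(start = w$start_bp, end = w$end_bp - 1L)
    gr <- IRanges::IRanges(start = g$start, end = g$end - 1L)
    hits <- IRanges::findOverlaps(wr, gr)
    if (length(hits) == 0) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(wr[qi], gr[si])
    dplyr::bind_cols(w[qi, , drop = FALSE],
                     tibble::tibble(gene = g$gene[si],
                                    overlap_bp = IRanges::width(ov)))
  })
}

#' Read gene annotations from GFF3 or BED
#'
#' Imports gene intervals with `rtracklayer` and converts them to the
#' package's half-open convention (`[start, end)`, 1-based): a GFF record
#' `[s, e]` becomes `[s, e + 1)`; a BED record (0-based half-open) becomes
#' `[s0 + 1, e0 + 1)`.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param feature For GFF, feature types to keep (default `"gene"`; `NULL`
#'   keeps everything).
#' @return A tibble `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    hn_abort("rtracklayer is required for read_gene_annotation().",
             "heatnorm_dependency_error")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff && !is.null(feature) && "type" %in% names(md)) {
    keep <- md$type %in% feature
    gr <- gr[keep]
    md <- md[keep, , drop = FALSE]
  }
  name <- if ("Name" %in% names(md) && !all(is.na(md$Name))) {
    as.character(md$Name)
  } else if ("gene_id" %in% names(md)) {
    as.character(md$gene_id)
  } else if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else if ("name" %in% names(md)) {
    as.character(md$name)
  } else {
    paste0("feature", seq_along(gr))
  }
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr) + 1L,
                 gene = name)
}
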