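#' Heatmap of across-environment genetic correlations
#'
#' @param object A `gamma_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gamma_matrix
#' @export
autoplot.gamma_matrix <- function(object, ...) {
  tbl <- correlation_summary(object)$correlations
  ggplot2::ggplot(tbl, ggplot2::aes(.data$x1, .data$x2, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "navy", midpoint = 0,
                                  limits = c(-1, 1), name = "genetic\ncorrelation") +
    ggplot2::labs(x = "standardized covariate", y = "standardized covariate") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Heritability profile across the environmental gradient
#'
#' @param h2 Tibble from [heritability_curve()].
#' @return A ggplot; bands are drawn when present.
#' @export
plot_heritability <- function(h2) {
  p <- ggplot2::ggplot(h2, ggplot2::aes(.data$x, .data$h2,
                                        group = .data$class))
  if (all(c("conf.low", "conf.high") %in% names(h2))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                               ymax = .data$conf.high),
                                  fill = "grey80")
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "standardized covariate", y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' Reaction norms with extreme sires highlighted
#'
#' Population trend as a thick black line; tolerant sires in blue,
#' susceptible in red, remaining individuals in grey.
#'
#' @param norms Tibble from [reaction_norms()].
#' @param tolerant,susceptible Optional vectors of sire ids to color.
#' @param raw_scale Plot against the covariate's original units rather
#'   than \[-1, 1\].
#' @return A ggplot.
#' @export
plot_reaction_norms <- function(norms, tolerant = NULL, susceptible = NULL,
                                raw_scale = TRUE) {
  norms$group <- dplyr::case_when(
    norms$level == "population" ~ "population",
    norms$animal %in% as.character(tolerant) ~ "tolerant",
    norms$animal %in% as.character(susceptible) ~ "susceptible",
    TRUE ~ "other")
  xvar <- if (raw_scale) "raw" else "x"
  ggplot2::ggplot(norms,
                  ggplot2::aes(.data[[xvar]], .data$value,
                               group = interaction(.data$level, .data$animal),
                               colour = .data$group,
                               linewidth = .data$group == "population")) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(population = "black",
                                            tolerant = "blue",
                                            susceptible = "red",
                                            other = "grey70"),
                                 name = NULL) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1.4, `FALSE` = 0.5),
                                    guide = "none") +
    ggplot2::labs(x = if (raw_scale) "environmental covariate" else
      "standardized covariate", y = "expected performance") +
    ggplot2::theme_minimal()
}

#' Miami plot of window variance shares
#'
#' Intercept-term window shares above the axis, slope-term shares mirrored
#' below, colored by chromosome; significant windows highlighted.
#'
#' @param windows Window tibble with `term` values `"intercept"` and
#'   `"slope"` (or the first two terms present).
#' @return A ggplot.
#' @export
plot_miami <- function(windows) {
  terms <- unique(windows$term)
  up <- terms[1]; down <- if (length(terms) > 1) terms[2] else terms[1]
  w <- windows %>%
    dplyr::filter(.data$term %in% c(up, down)) %>%
    dplyr::mutate(y = ifelse(.data$term == up, .data$pct_var,
                             -.data$pct_var),
                  pos = .data$start_bp / 1e6)
  p <- ggplot2::ggplot(w, ggplot2::aes(.data$pos, .data$y,
                                       colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue")) +
    ggplot2::labs(x = "position (Mb) by chromosome",
                  y = paste0("% genomic variance (", up, " above, ", down,
                             " below)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
  if ("significant" %in% names(w)) {
    p <- p + ggplot2::geom_point(data = dplyr::filter(w,
                                                      !is.na(.data$significant) &
                                                        .data$significant),
                                 colour = "red", size = 1.2)
  }
  p
}
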