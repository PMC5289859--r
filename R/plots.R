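#' Forest plot of haplotype odds ratios
#'
#' Odds ratios with 95% confidence intervals for every non-reference
#' haplotype, colored by risk/protective/null class, on a log scale with
#' the reference line at OR = 1.
#'
#' @param object A `haplo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot haplo_fit
#' @export
autoplot.haplo_fit <- function(object, ...) {
  d <- object$table[object$table$class != "reference", , drop = FALSE]
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label, color = .data$class)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(
      risk = "#c0392b", protective = "#2471a3", null = "grey40"
    )) +
    ggplot2::labs(
      x = sprintf("odds ratio vs %s (95%% CI, log scale)", object$reference),
      y = NULL, color = "class",
      title = sprintf("Haplotype association (%s model)", object$model)
    ) +
    ggplot2::theme_minimal()
}

#' Haplotype allele mosaic
#'
#' Tile plot of the retained haplotypes (rows) by candidate variants
#' (columns), risk alleles in red and nonrisk alleles in blue — the
#' standard way to eyeball which recombinant carries which allele block.
#'
#' @param tbl Haplotype table with `label` and `alleles` columns.
#' @param vm Optional variant map for variant labels on the x axis.
#' @return A ggplot object.
#' @export
plot_haplotype_alleles <- function(tbl, vm = NULL) {
  m <- nchar(tbl$alleles[1])
  ids <- if (!is.null(vm)) vm$id else paste0("v", seq_len(m))
  d <- tidyr::expand_grid(label = tbl$label, variant = seq_len(m))
  d$allele <- purrr::map2_chr(d$label, d$variant, function(l, v) {
    a <- substr(tbl$alleles[tbl$label == l], v, v)
    if (a == "1") "risk" else "nonrisk"
  })
  d$variant <- factor(ids[d$variant], levels = ids)
  d$label <- factor(d$label, levels = rev(tbl$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant, y = .data$label, fill = .data$allele)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(risk = "#c0392b", nonrisk = "#2471a3")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "allele") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Posterior probability of association along the locus
#'
#' PPA per variant against genomic position, with credible-set members
#' highlighted when a credible set is supplied.
#'
#' @param assoc Association tibble with `pos` and `ppa` (from
#'   [compute_ppa()]).
#' @param credible Optional credible-set tibble (from [credible_set()]).
#' @return A ggplot object.
#' @export
plot_ppa <- function(assoc, credible = NULL) {
  assoc$in_set <- if (!is.null(credible)) assoc$id %in% credible$id else TRUE
  p <- ggplot2::ggplot(assoc, ggplot2::aes(x = .data$pos, y = .data$ppa)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0), color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = .data$in_set), size = 2) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey50"),
      labels = c(`TRUE` = "in credible set", `FALSE` = "outside"), name = NULL
    ) +
    ggplot2::labs(x = "position (bp)", y = "posterior probability of association") +
    ggplot2::theme_minimal()
  if (is.null(credible)) p <- p + ggplot2::guides(color = "none")
  p
}
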