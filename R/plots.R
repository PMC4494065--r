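# ggplot2 views of the pipeline's result types.

#' Plot expression indices for selected genes
#'
#' Index-scale expression by strain and temperature, one panel per gene.
#'
#' @param expr Tibble from [expression_index()].
#' @param design Design tibble.
#' @param genes Genes to show.
#' @return A ggplot.
#' @export
plot_expression <- function(expr, design, genes) {
  df <- expr |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::inner_join(dplyr::select(design, "library_id", "strain",
                                    "temperature"), by = "library_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$index,
                                   colour = factor(.data$temperature))) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1), size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "expression index (per-mille of compartment)",
                  colour = "temp (degC)")
}

#' @describeIn tidy.oxphos_de Fold-change vs significance plot of the
#'   within-strain contrasts.
#' @param object An `oxphos_de` object.
#' @method autoplot oxphos_de
#' @export
autoplot.oxphos_de <- function(object, ...) {
  df <- object$results[object$results$family == "within_strain", ]
  df$strain <- sub("_15v28$", "", df$contrast)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change,
                                   y = -log10(.data$q.value),
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::scale_colour_manual(values = c(up = "#1b9e77", down = "#d95f02",
                                            ns = "grey60")) +
    ggplot2::labs(x = "signed fold-change (index scale)",
                  y = expression(-log[10] ~ "BY q"))
}

#' @describeIn tidy.oxphos_variants Per-library CI-unit scores of the
#'   candidate sites, coloured by population.
#' @param object An `oxphos_variants` object.
#' @method autoplot oxphos_variants
#' @export
autoplot.oxphos_variants <- function(object, ...) {
  if (is.null(object$sites) || nrow(object$sites) == 0) {
    stop("no candidate sites to plot")
  }
  keys <- paste(object$sites$gene_id, object$sites$position, sep = ":")
  df <- object$scores
  df$site <- paste(df$gene_id, df$position, sep = ":")
  df <- df[df$site %in% keys, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$score,
                                   colour = .data$strain)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variant score (CI units)")
}

#' Plot a DE summary in the by-complex layout
#'
#' @param summary Tibble from [summarize_by_complex()].
#' @return A ggplot of DE counts per complex, compartment and strain.
#' @export
plot_de_summary <- function(summary) {
  df <- summary[summary$complex != "pct", ] |>
    tidyr::pivot_longer(dplyr::all_of(STRAINS), names_to = "strain",
                        values_to = "n_de")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$complex, y = .data$n_de,
                                   fill = .data$strain)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$genome)) +
    ggplot2::labs(x = "OXPHOS complex", y = "differentially expressed genes",
                  fill = NULL)
}
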