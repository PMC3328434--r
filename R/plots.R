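#' Quality-sensitivity screen overview plot
#'
#' Per-gene quality slope against significance, coloured by gene class:
#' the characteristic picture of FFPE degradation is a heavy cloud of
#' significant negative slopes (mRNA losing signal with quality) with a
#' small inverted population of small RNAs on the positive side.
#'
#' @param object A `gene_quality_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_quality_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slope,
                                   y = -log10(.data$p_value),
                                   colour = .data$gene_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha") %||% 0.05),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 expression change per Ct_diff cycle",
                  y = "-log10 p", colour = "class",
                  title = "Per-gene quality sensitivity") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential expression result
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object)
  df$log2_fc <- (df$mean_log2_tumour - df$mean_log2_control)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_adjusted),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumour - control)",
                  y = "-log10 adjusted p", colour = "significant",
                  title = "Differential expression") +
    ggplot2::theme_minimal()
}

#' Storage-time vs quality scatter with the fitted trend
#'
#' @param samples Sample tibble with `storage_months`, `ct_diff`, `group`.
#' @param tumours_only Fit the line on tumours only (default), matching
#'   the cohort regressions.
#' @return A ggplot object.
#' @export
plot_storage_quality <- function(samples, tumours_only = TRUE) {
  fit <- storage_quality_regression(samples, tumours_only = tumours_only)
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$storage_months,
                                        y = .data$ct_diff,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(
      x = "storage (months)", y = "Ct_diff (cycles)",
      title = sprintf("Quality vs storage time (r² = %.2f)",
                      fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Expression-vs-quality plot for selected genes
#'
#' The per-gene view of quality sensitivity: log2 expression against
#' Ct_diff with per-gene regression lines, for a handful of genes.
#'
#' @param dataset An `ffpe_dataset`.
#' @param gene_ids Genes (or probe ids) to show.
#' @param tumours_only Restrict to tumour samples. Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_quality_trend <- function(dataset, gene_ids, tumours_only = TRUE) {
  samples <- dataset$samples
  if (tumours_only) samples <- dplyr::filter(samples, .data$group == "tumour")
  rows <- dataset_gene_rows(gene_ids, rownames(dataset$expression))
  df <- purrr::map_dfr(seq_along(rows), function(i) {
    tibble(gene = gene_ids[i],
           ct_diff = samples$ct_diff,
           log2_expr = log2(dataset$expression[rows[i],
                                               samples$sample_id]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ct_diff, y = .data$log2_expr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "Ct_diff (cycles)", y = "log2 intensity") +
    ggplot2::theme_minimal()
}
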