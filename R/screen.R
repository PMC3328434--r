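#' Per-gene quality-sensitivity screen
#'
#' For every detected gene, regresses log2 expression on per-sample
#' quality (Ct_diff) across tumour samples and flags genes whose
#' expression is significantly influenced by quality -- the central
#' pitfall of FFPE expression data: most affected genes lose signal as
#' quality worsens, while small RNAs tend to gain apparent signal as the
#' larger transcripts degrade around them. The screening alpha is raw
#' (unadjusted) because the quantity of interest is the *fraction* of
#' genes whose expression tracks quality.
#'
#' @param dataset An `ffpe_dataset` (or any list with `expression`,
#'   `probes`, `samples`).
#' @param detection A `detection_calls` object with per-group calls; only
#'   detected genes are screened. Pass `NULL` to screen every gene.
#' @param alpha Significance level for the affected flag. Default 0.05.
#' @param tumours_only Use only tumour samples (default), avoiding the
#'   variance of genuine tumour/control differences.
#' @param samples Optional subset of sample records to use.
#' @return A tibble of class `gene_quality_screen`: per gene `slope`,
#'   `r_squared`, `p_value`, `affected`, `direction`
#'   (`decreasing`/`increasing`/`none`).
#' @export
screen_genes <- function(dataset, detection = NULL, alpha = 0.05,
                         tumours_only = TRUE, samples = NULL) {
  samples <- samples %||% dataset$samples
  if (tumours_only) samples <- dplyr::filter(samples, .data$group == "tumour")
  if (nrow(samples) < 3) stop("need at least 3 samples to screen", call. = FALSE)
  if (stats::var(samples$ct_diff) == 0) {
    stop("degenerate input: Ct_diff has zero variance", call. = FALSE)
  }
  expr <- dataset$expression[, samples$sample_id, drop = FALSE]
  genes <- rownames(expr)
  if (!is.null(detection)) {
    stopifnot(inherits(detection, "detection_calls"))
    det <- detection$per_group
    if (is.null(det)) stop("detection calls lack per-group results", call. = FALSE)
    # detection tables index genes by the expression row names (probe ids
    # in the one-probe-per-gene annotation)
    keep <- intersect(genes, det$gene_id[det$detected])
    expr <- expr[keep, , drop = FALSE]
    genes <- keep
  }
  fits <- ols_screen_rows(log2(pmax(expr, .Machine$double.xmin)),
                          samples$ct_diff)
  ann <- dataset$probes[match(genes, dataset$probes$probe_id), ]
  res <- dplyr::bind_cols(
    tibble(gene_id = ann$gene_id %||% genes,
           gene_class = ann$gene_class %||% NA_character_),
    fits
  )
  res$affected <- res$p_value < alpha
  res$direction <- dplyr::case_when(
    res$affected & res$slope < 0 ~ "decreasing",
    res$affected & res$slope > 0 ~ "increasing",
    TRUE ~ "none"
  )
  attr(res, "alpha") <- alpha
  class(res) <- c("gene_quality_screen", class(res))
  res
}

#' Summarize a quality screen
#'
#' Affected fractions and direction split, overall and by gene class.
#'
#' @param screen Output of [screen_genes()].
#' @return A tibble with one row per gene class plus an overall row.
#' @export
summarize_quality_screen <- function(screen) {
  one <- function(df, label) {
    aff <- df$affected
    tibble(
      gene_class = label,
      n_genes = nrow(df),
      n_affected = sum(aff),
      pct_affected = 100 * mean(aff),
      pct_affected_decreasing = if (any(aff))
        100 * mean(df$direction[aff] == "decreasing") else NA_real_,
      pct_affected_increasing = if (any(aff))
        100 * mean(df$direction[aff] == "increasing") else NA_real_
    )
  }
  by_class <- dplyr::group_modify(
    dplyr::group_by(as_tibble(screen), .data$gene_class),
    ~ one(.x, .y$gene_class)[-1]
  ) |> dplyr::ungroup()
  dplyr::bind_rows(one(screen, "all"), by_class)
}

#' Most and least quality-affected genes
#'
#' Returns the `k` genes influenced by quality with the highest
#' significance, and the `k` least affected genes. Candidates for the
#' least-affected list must additionally be expressed at least
#' `background_factor` times the per-sample background (mean
#' negative-control intensity) in *every* sample, so that genes sitting at
#' the detection limit are not mistaken for robust ones.
#'
#' @param screen Output of [screen_genes()].
#' @param expression Probes x samples intensity matrix (same scale as the
#'   screen input).
#' @param neg_controls Controls x samples matrix defining background.
#' @param k Number of genes per list. `k = 0` gives two empty lists.
#' @param background_factor Multiple of background required. Default 4.
#' @return A list with tibbles `most_affected` and `least_affected`.
#' @export
rank_extreme_genes <- function(screen, expression, neg_controls, k = 10,
                               background_factor = 4) {
  stopifnot(k >= 0)
  scr <- as_tibble(screen)
  scr <- scr[order(scr$p_value), ]
  if (k > nrow(scr)) {
    stop(sprintf("only %d screened genes available for k = %d lists",
                 nrow(scr), k), call. = FALSE)
  }
  background <- colMeans(neg_controls)
  ids <- dataset_gene_rows(scr$gene_id, rownames(expression))
  above <- expression[ids, colnames(neg_controls), drop = FALSE] >=
    matrix(background_factor * background, nrow = length(ids),
           ncol = length(background), byrow = TRUE)
  eligible <- rowSums(above) == ncol(above)
  least_pool <- scr[eligible, ]
  if (k > nrow(least_pool)) {
    stop(sprintf(paste0("only %d genes pass the %gx-background filter; ",
                        "%d more needed for k = %d"),
                 nrow(least_pool), background_factor,
                 k - nrow(least_pool), k), call. = FALSE)
  }
  list(
    most_affected = scr[seq_len(k), , drop = FALSE],
    least_affected = least_pool[rev(seq_len(nrow(least_pool)))[seq_len(k)], ,
                                drop = FALSE]
  )
}

# Map gene ids to expression row indices; probe ids equal row names in the
# one-probe-per-gene layout, but gene ids are accepted too.
dataset_gene_rows <- function(gene_ids, rownms) {
  idx <- match(gene_ids, rownms)
  if (anyNA(idx)) {
    idx2 <- match(sub("^G", "P", gene_ids), rownms)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx)) {
    stop("gene id(s) not found in expression matrix: ",
         paste(utils::head(gene_ids[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  idx
}
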