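#' Per-sample quality score from qPCR (Ct_diff)
#'
#' The per-sample quality statistic: the qPCR cycle threshold of a stable
#' reference gene in the FFPE sample minus the average Ct of the same gene
#' in two fresh-frozen reference samples. Larger values mean less
#' amplifiable template, i.e. worse RNA quality.
#'
#' @param ct_ffpe Numeric vector of FFPE Ct values (cycles).
#' @param ct_ff_refs The two fresh-frozen reference Cts: a length-2 vector
#'   (recycled across samples) or a matrix/data frame with 2 columns and
#'   one row per sample.
#' @return Numeric vector of Ct_diff values, cycles.
#' @examples
#' compute_ct_diff(28.4, c(24, 25)) # 3.9
#' @export
compute_ct_diff <- function(ct_ffpe, ct_ff_refs) {
  ct_ffpe <- as.numeric(ct_ffpe)
  if (is.data.frame(ct_ff_refs)) ct_ff_refs <- as.matrix(ct_ff_refs)
  if (is.matrix(ct_ff_refs)) {
    if (ncol(ct_ff_refs) != 2 || nrow(ct_ff_refs) != length(ct_ffpe)) {
      stop("`ct_ff_refs` matrix must be n x 2", call. = FALSE)
    }
    ref_mean <- rowMeans(ct_ff_refs)
    refs <- as.numeric(ct_ff_refs)
  } else {
    refs <- as.numeric(ct_ff_refs)
    if (length(refs) != 2) {
      stop("`ct_ff_refs` must supply exactly two reference Cts", call. = FALSE)
    }
    ref_mean <- mean(refs)
  }
  if (anyNA(ct_ffpe) || anyNA(refs) || any(c(ct_ffpe, refs) <= 0) ||
      any(!is.finite(c(ct_ffpe, refs)))) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  ct_ffpe - ref_mean
}

#' Default sample QC thresholds
#'
#' RNA yield of at least 400 ng for pre-qualification and array input; a
#' quality cutoff of 12 Ct_diff cycles (more than twelve cycles fails);
#' array mean signal strictly above 500 and 95th-percentile intensity
#' strictly above 2500.
#'
#' @return Named list of thresholds.
#' @export
default_qc_thresholds <- function() {
  list(min_rna_ng = 400, max_ct_diff = 12,
       min_mean_signal = 500, min_p95 = 2500)
}

#' Apply sample-level QC gates
#'
#' Evaluates the three gate stages in pipeline order -- RNA yield, qPCR
#' quality, array metrics -- and labels every sample pass/fail with the
#' exhaustive list of failed gates. Boundary conventions are strict: a
#' sample fails only when yield < 400 ng, Ct_diff > 12 cycles, mean signal
#' <= 500 or p95 <= 2500. A missing metric fails its gate with reason
#' `missing-<metric>`. The verdict is gate-order independent (all gates are
#' always evaluated); `qc_stage` records the first stage failed, for
#' flowchart-style accounting.
#'
#' @param samples Sample metadata tibble with columns `rna_yield_ng`,
#'   `ct_diff`, `mean_signal`, `p95` (missing columns are treated as
#'   missing metrics).
#' @param thresholds Named list as from [default_qc_thresholds()].
#' @return The input tibble with `qc_pass` (logical), `qc_reasons`
#'   (semicolon-separated, `""` when passing) and `qc_stage`
#'   (`"passed"`, `"yield"`, `"qpcr"` or `"array"`).
#' @export
apply_sample_gates <- function(samples, thresholds = default_qc_thresholds()) {
  samples <- as_tibble(samples)
  n <- nrow(samples)
  col <- function(name) {
    if (name %in% names(samples)) samples[[name]] else rep(NA_real_, n)
  }
  gate <- function(value, fail_when, reason, missing_reason) {
    dplyr::case_when(
      is.na(value) ~ missing_reason,
      fail_when(value) ~ reason,
      TRUE ~ NA_character_
    )
  }
  g_yield <- gate(col("rna_yield_ng"),
                  function(v) v < thresholds$min_rna_ng,
                  "insufficient-rna", "missing-rna-yield")
  g_ct <- gate(col("ct_diff"),
               function(v) v > thresholds$max_ct_diff,
               "quality-cutoff", "missing-ct-diff")
  g_ms <- gate(col("mean_signal"),
               function(v) v <= thresholds$min_mean_signal,
               "low-mean-signal", "missing-mean-signal")
  g_p95 <- gate(col("p95"),
                function(v) v <= thresholds$min_p95,
                "low-p95", "missing-p95")
  reasons <- purrr::pmap_chr(list(g_yield, g_ct, g_ms, g_p95), function(...) {
    r <- c(...)
    paste(r[!is.na(r)], collapse = ";")
  })
  samples$qc_pass <- !nzchar(reasons)
  samples$qc_reasons <- reasons
  samples$qc_stage <- dplyr::case_when(
    !is.na(g_yield) ~ "yield",
    !is.na(g_ct) ~ "qpcr",
    !is.na(g_ms) | !is.na(g_p95) ~ "array",
    TRUE ~ "passed"
  )
  samples
}

#' Flowchart-style QC accounting
#'
#' Counts samples entering the pipeline, failures at each gate stage, and
#' samples analysed, by group. The accounting identity
#' `in = failed (per stage) + analysed` holds on any input.
#'
#' @param samples Output of [apply_sample_gates()].
#' @return A tibble with one row per group plus a total row.
#' @export
qc_summary <- function(samples) {
  stopifnot(all(c("qc_stage", "group") %in% names(samples)))
  by_group <- samples |>
    dplyr::count(.data$group, .data$qc_stage) |>
    tidyr::pivot_wider(names_from = "qc_stage", values_from = "n",
                       values_fill = 0L)
  for (s in c("yield", "qpcr", "array", "passed")) {
    if (!s %in% names(by_group)) by_group[[s]] <- 0L
  }
  by_group$n_in <- by_group$yield + by_group$qpcr + by_group$array +
    by_group$passed
  total <- by_group |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum)) |>
    dplyr::mutate(group = "total")
  dplyr::bind_rows(by_group, total) |>
    dplyr::select("group", "n_in", failed_yield = "yield",
                  failed_qpcr = "qpcr", failed_array = "array",
                  analysed = "passed")
}

#' Detection p-values against negative control probes
#'
#' Empirical detection calls from the negative-control (background) probe
#' distribution. Per sample, a probe's detection p-value is the add-one
#' rank of its intensity among that sample's negative controls:
#' `p = (1 + #{controls >= intensity}) / (N + 1)`. Per group, the group
#' mean intensity of each gene is ranked against the pooled negative
#' controls of the group's samples; a gene is *detected* when its group
#' p-value is below `alpha` in either group. With `group_method =
#' "majority"`, a gene is instead detected in a group when more than half
#' of the group's samples have per-sample p below `alpha`.
#'
#' @param expression Probes x samples intensity matrix (linear scale).
#' @param neg_controls Controls x samples intensity matrix, same samples.
#' @param group Character vector of group labels, one per sample (optional;
#'   without it only per-sample p-values are computed).
#' @param alpha Detection significance level. Default 0.01.
#' @param group_method `"mean"` (default) or `"majority"`.
#' @return An object of class `detection_calls`: list with `per_sample`
#'   (p-value matrix), `per_group` (tibble gene_id, one p column per group,
#'   `detected`), `alpha`, `group_method`.
#' @export
detection_pvalues <- function(expression, neg_controls, group = NULL,
                              alpha = 0.01,
                              group_method = c("mean", "majority")) {
  group_method <- match.arg(group_method)
  expression <- as.matrix(expression)
  neg_controls <- as.matrix(neg_controls)
  if (ncol(expression) != ncol(neg_controls)) {
    stop("expression and negative controls must cover the same samples",
         call. = FALSE)
  }
  N <- nrow(neg_controls)
  if (N == 0) stop("no negative control probes", call. = FALSE)
  if (N < 50) {
    warning("fewer than 50 negative controls per sample; detection ",
            "p-values will be coarse", call. = FALSE)
  }
  p_rank <- function(x, controls) {
    sc <- sort(controls)
    n_lt <- findInterval(x, sc, left.open = TRUE)
    (1 + length(sc) - n_lt) / (length(sc) + 1)
  }
  per_sample <- matrix(
    vapply(seq_len(ncol(expression)), function(j) {
      p_rank(expression[, j], neg_controls[, j])
    }, numeric(nrow(expression))),
    nrow = nrow(expression), dimnames = dimnames(expression))
  per_group <- NULL
  if (!is.null(group)) {
    if (length(group) != ncol(expression)) {
      stop("`group` must have one label per sample", call. = FALSE)
    }
    groups <- unique(group)
    pg <- lapply(groups, function(g) {
      cols <- group == g
      if (group_method == "mean") {
        p_rank(rowMeans(expression[, cols, drop = FALSE]),
               as.numeric(neg_controls[, cols]))
      } else {
        rowMeans(per_sample[, cols, drop = FALSE] < alpha) > 0.5
      }
    })
    per_group <- tibble(gene_id = rownames(expression) %||%
                          as.character(seq_len(nrow(expression))))
    if (group_method == "mean") {
      for (i in seq_along(groups)) {
        per_group[[paste0("p_", groups[i])]] <- pg[[i]]
      }
      per_group$detected <- Reduce(`|`, lapply(pg, function(p) p < alpha))
    } else {
      for (i in seq_along(groups)) {
        per_group[[paste0("detected_", groups[i])]] <- pg[[i]]
      }
      per_group$detected <- Reduce(`|`, pg)
    }
  }
  structure(
    list(per_sample = per_sample, per_group = per_group, alpha = alpha,
         group_method = group_method),
    class = "detection_calls"
  )
}

#' @export
print.detection_calls <- function(x, ...) {
  cat("Detection calls:", nrow(x$per_sample), "probes x",
      ncol(x$per_sample), "samples, alpha =", x$alpha, "\n")
  if (!is.null(x$per_group)) {
    cat(sprintf("  %d genes detected (%.1f%%), group method '%s'\n",
                sum(x$per_group$detected),
                100 * mean(x$per_group$detected), x$group_method))
  }
  invisible(x)
}

#' Regression of sample quality on storage time
#'
#' How much of the variation in Ct_diff is explained by months in storage.
#' Tumour samples only by default, to avoid the variance contributed by
#' genuine tumour/control differences.
#'
#' @param samples Sample tibble with `storage_months`, `ct_diff`, `group`.
#' @param tumours_only Restrict to tumour samples. Default `TRUE`.
#' @return An [fit_ols()] object (Ct_diff on months).
#' @export
storage_quality_regression <- function(samples, tumours_only = TRUE) {
  s <- if (tumours_only) dplyr::filter(samples, .data$group == "tumour") else samples
  if (nrow(s) < 3) stop("need at least 3 samples", call. = FALSE)
  fit_ols(s$storage_months, s$ct_diff)
}

#' Regression of per-sample detected-gene count on quality
#'
#' Counts genes detected per sample (per-sample detection p below `alpha`)
#' and regresses the count on Ct_diff; the magnitude of the slope is the
#' genes-lost-per-cycle rate of the cohort.
#'
#' @param samples Sample tibble (`sample_id`, `ct_diff`, `group`).
#' @param detection A `detection_calls` object covering the samples.
#' @param alpha Per-sample detection level. Defaults to the level stored in
#'   `detection`.
#' @param tumours_only Restrict the fit to tumour samples. Default `TRUE`.
#' @return A list with `fit` (an `ols_fit`), `genes_lost_per_cycle`
#'   (|slope|) and `counts` (per-sample tibble).
#' @export
detection_count_regression <- function(samples, detection, alpha = NULL,
                                       tumours_only = TRUE) {
  stopifnot(inherits(detection, "detection_calls"))
  alpha <- alpha %||% detection$alpha
  ps <- detection$per_sample[, samples$sample_id, drop = FALSE]
  counts <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    ct_diff = samples$ct_diff,
    n_detected = colSums(ps < alpha)
  )
  use <- if (tumours_only) counts$group == "tumour" else rep(TRUE, nrow(counts))
  fit <- fit_ols(counts$ct_diff[use], counts$n_detected[use])
  list(fit = fit, genes_lost_per_cycle = abs(fit$slope), counts = counts)
}
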