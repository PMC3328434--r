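#' Select a quality-matched cohort
#'
#' Restricts both groups to a common quality range so that
#' quality-sensitive genes cannot masquerade as differentially expressed.
#' When no cutoff is supplied it is derived from the better-quality group
#' (controls) as the smallest integer Ct_diff retaining all but
#' `retain_all_but` of the controls -- the "all controls except one fell
#' below 5 cycles" rule.
#'
#' @param samples Sample tibble with `ct_diff` and `group`; rows failing
#'   QC (`qc_pass == FALSE`, if present) are dropped first.
#' @param cutoff Ct_diff cutoff in cycles (samples with `ct_diff < cutoff`
#'   are kept). `NULL` (default) derives it from the controls.
#' @param retain_all_but Number of controls the derived cutoff may lose.
#'   Default 1.
#' @return A list: `samples` (selected), `excluded` (with reasons),
#'   `cutoff`.
#' @export
select_quality_matched <- function(samples, cutoff = NULL,
                                   retain_all_but = 1) {
  s <- as_tibble(samples)
  if ("qc_pass" %in% names(s)) s <- dplyr::filter(s, .data$qc_pass)
  if (is.null(cutoff)) {
    ctl <- s$ct_diff[s$group == "control"]
    if (length(ctl) == 0) {
      stop("cannot derive a cutoff without control samples", call. = FALSE)
    }
    target <- max(length(ctl) - retain_all_but, 1)
    cutoff <- 1
    while (sum(ctl < cutoff) < target) cutoff <- cutoff + 1
  }
  keep <- s$ct_diff < cutoff
  excluded <- s[!keep, c("sample_id", "group", "ct_diff")]
  if (nrow(excluded)) excluded$reason <- "ct-diff-above-cutoff"
  selected <- s[keep, ]
  for (g in c("tumour", "control")) {
    if (g %in% s$group && !g %in% selected$group) {
      stop(sprintf("no %s samples remain below cutoff %g", g, cutoff),
           call. = FALSE)
    }
  }
  if (nrow(selected) == 0) {
    stop("both groups empty after quality matching", call. = FALSE)
  }
  list(samples = selected, excluded = excluded, cutoff = cutoff)
}

# Vectorized Welch two-sample t-test on rows of X (log2 scale).
welch_rows <- function(X, g1, g2) {
  x1 <- X[, g1, drop = FALSE]
  x2 <- X[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  zero <- se2 == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero variance in both groups",
            call. = FALSE)
    p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  }
  list(mean1 = m1, mean2 = m2, statistic = tstat, p = p)
}

#' Two-group differential expression with B-H correction
#'
#' Per-gene two-sided comparison of tumours against controls on log2
#' intensities (Welch t-test by default, Mann-Whitney by flag), with
#' Benjamini-Hochberg adjustment across the tested genes and a stringent
#' significance level of adjusted p < 0.01. Fold change is the ratio of
#' linear-scale group means, reported as a ratio >= 1 plus a direction
#' flag. When detection calls are supplied, only detected genes are
#' tested (filter first, then adjust).
#'
#' @param expression Probes x samples intensity matrix, linear scale.
#' @param samples Sample tibble (`sample_id`, `group`) defining the cohort.
#' @param detection Optional `detection_calls` to restrict to detected
#'   genes.
#' @param alpha Adjusted-p significance level. Default 0.01.
#' @param method `"welch"` (default) or `"mann-whitney"`.
#' @return A tibble of class `de_result`: per gene group means (log2),
#'   `fold_change`, `direction`, `p_raw`, `p_adjusted`, `significant`,
#'   `above_2fold`.
#' @export
differential_expression <- function(expression, samples, detection = NULL,
                                    alpha = 0.01,
                                    method = c("welch", "mann-whitney")) {
  method <- match.arg(method)
  expr <- as.matrix(expression)[, samples$sample_id, drop = FALSE]
  if (!is.null(detection)) {
    stopifnot(inherits(detection, "detection_calls"))
    det <- detection$per_group
    keep <- intersect(rownames(expr), det$gene_id[det$detected])
    expr <- expr[keep, , drop = FALSE]
  }
  g1 <- samples$group == "tumour"
  g2 <- samples$group == "control"
  if (sum(g1) < 2 || sum(g2) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  lx <- log2(pmax(expr, .Machine$double.xmin))
  if (method == "welch") {
    w <- welch_rows(lx, which(g1), which(g2))
    p_raw <- w$p
    statistic <- w$statistic
  } else {
    p_raw <- apply(lx, 1, function(v) {
      mann_whitney(v[g1], v[g2])$p_value
    })
    statistic <- NA_real_
  }
  mean_t <- rowMeans(lx[, g1, drop = FALSE])
  mean_c <- rowMeans(lx[, g2, drop = FALSE])
  ratio <- rowMeans(expr[, g1, drop = FALSE]) /
    rowMeans(expr[, g2, drop = FALSE])
  res <- tibble(
    gene_id = rownames(expr),
    mean_log2_tumour = mean_t,
    mean_log2_control = mean_c,
    fold_change = pmax(ratio, 1 / ratio),
    direction = ifelse(ratio >= 1, "up", "down"),
    statistic = statistic,
    p_raw = p_raw,
    p_adjusted = bh_adjust(p_raw)
  )
  res$significant <- res$p_adjusted < alpha
  res$above_2fold <- res$fold_change >= 2
  attr(res, "alpha") <- alpha
  attr(res, "method") <- method
  attr(res, "n_tumour") <- sum(g1)
  attr(res, "n_control") <- sum(g2)
  class(res) <- c("de_result", class(res))
  res
}

#' Compare confounded and quality-matched differential expression
#'
#' Runs the differential expression analysis twice -- once on all
#' QC-passing samples (where a quality imbalance between groups can
#' masquerade as biology) and once on the quality-matched cohort -- and
#' summarizes list sizes and overlap. With ground truth available
#' (synthetic data), false flags are attributed: a flagged ground-truth
#' null gene whose planted decay magnitude is above the cohort median is a
#' quality artefact.
#'
#' @param dataset An `ffpe_dataset` (samples should already carry QC flags
#'   via [apply_sample_gates()]; if absent, gates are applied).
#' @param cutoff,retain_all_but Passed to [select_quality_matched()].
#' @param alpha Significance level (B-H adjusted). Default 0.01.
#' @param detect_alpha Detection level used for the per-cohort detection
#'   filter. Default 0.01.
#' @return A list: `matched` and `unmatched` (`de_result`s), `summary`
#'   tibble, `cutoff`, `selection`.
#' @export
confounding_comparison <- function(dataset, cutoff = NULL,
                                   retain_all_but = 1, alpha = 0.01,
                                   detect_alpha = 0.01) {
  stopifnot(inherits(dataset, "ffpe_dataset"))
  samples <- dataset$samples
  if (!"qc_pass" %in% names(samples)) samples <- apply_sample_gates(samples)
  passing <- dplyr::filter(samples, .data$qc_pass)
  sel <- select_quality_matched(passing, cutoff = cutoff,
                                retain_all_but = retain_all_but)
  run_de <- function(cohort) {
    det <- detection_pvalues(
      dataset$expression[, cohort$sample_id, drop = FALSE],
      dataset$neg_controls[, cohort$sample_id, drop = FALSE],
      group = cohort$group, alpha = detect_alpha
    )
    differential_expression(dataset$expression, cohort, detection = det,
                            alpha = alpha)
  }
  matched <- run_de(sel$samples)
  unmatched <- run_de(passing)
  sig_m <- matched$gene_id[matched$significant]
  sig_u <- unmatched$gene_id[unmatched$significant]
  summary <- tibble(
    cohort = c("matched", "unmatched"),
    n_tumour = c(sum(sel$samples$group == "tumour"),
                 sum(passing$group == "tumour")),
    n_control = c(sum(sel$samples$group == "control"),
                  sum(passing$group == "control")),
    n_tested = c(nrow(matched), nrow(unmatched)),
    n_significant = c(length(sig_m), length(sig_u)),
    n_overlap = length(intersect(sig_m, sig_u))
  )
  out <- list(matched = matched, unmatched = unmatched, summary = summary,
              cutoff = sel$cutoff, selection = sel)
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    probe_of <- dataset$probes$probe_id[match(truth$gene_id,
                                              dataset$probes$gene_id)]
    null_probes <- probe_of[!truth$is_de]
    decay_abs <- abs(truth$decay)[match(probe_of, probe_of)]
    names(decay_abs) <- probe_of
    false_u <- intersect(sig_u, null_probes)
    false_m <- intersect(sig_m, null_probes)
    only_u <- setdiff(false_u, sig_m)
    med <- stats::median(abs(truth$decay))
    out$truth_attribution <- tibble(
      n_false_matched = length(false_m),
      n_false_unmatched = length(false_u),
      n_false_unmatched_only = length(only_u),
      frac_unmatched_false_quality_sensitive =
        if (length(false_u)) mean(decay_abs[false_u] > med) else NA_real_
    )
  }
  out
}
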