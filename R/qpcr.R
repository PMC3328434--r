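#' Delta-delta-Ct fold changes from paired qPCR measurements
#'
#' For each gene and tumour/control pair: `dCt = Ct_target - Ct_reference`
#' (normalization to a stable reference gene), `ddCt = dCt_tumour -
#' dCt_control`, per-pair fold `efficiency^-ddCt`. The gene-level summary
#' fold is the geometric mean across pairs (arithmetic means of ratios are
#' biased), reported as a ratio >= 1 with a direction flag. Incomplete
#' pairs are dropped with a warning.
#'
#' @param measurements Long-format tibble with columns `sample_id`,
#'   `pair_id`, `group` (`tumour`/`control`), `gene_id`, `ct_target`,
#'   `ct_reference`.
#' @param efficiency Amplification efficiency. Default 2 (perfect
#'   doubling per cycle).
#' @return A list: `per_pair` tibble (`gene_id`, `pair_id`, `dct_tumour`,
#'   `dct_control`, `ddct`, `fold`) and `summary` tibble (`gene_id`,
#'   `n_pairs`, `direction`, `fold`).
#' @export
ddct_fold_changes <- function(measurements, efficiency = 2) {
  m <- as_tibble(measurements)
  need <- c("pair_id", "group", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% names(m))) {
    stop("measurements need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cts <- c(m$ct_target, m$ct_reference)
  if (anyNA(cts) || any(!is.finite(cts)) || any(cts <= 0)) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  m$dct <- m$ct_target - m$ct_reference
  wide <- m |>
    dplyr::select("gene_id", "pair_id", "group", "dct") |>
    tidyr::pivot_wider(names_from = "group", values_from = "dct",
                       names_prefix = "dct_")
  if (!all(c("dct_tumour", "dct_control") %in% names(wide))) {
    stop("need both tumour and control measurements", call. = FALSE)
  }
  incomplete <- is.na(wide$dct_tumour) | is.na(wide$dct_control)
  if (any(incomplete)) {
    warning(sum(incomplete), " incomplete pair(s) excluded", call. = FALSE)
    wide <- wide[!incomplete, ]
  }
  if (nrow(wide) == 0) stop("no complete pairs", call. = FALSE)
  wide$ddct <- wide$dct_tumour - wide$dct_control
  wide$fold <- efficiency^(-wide$ddct)
  summary <- wide |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_ddct = mean(.data$ddct),
      direction = ifelse(mean(.data$ddct) < 0, "up", "down"),
      fold = efficiency^abs(mean(.data$ddct)),
      .groups = "drop"
    )
  list(per_pair = wide, summary = summary)
}

#' Paired test on delta-delta-Ct values
#'
#' Two-sided exact Wilcoxon signed-rank test on the per-pair ddCt values
#' of one gene. With `n` pairs the exact two-sided p-values lie on the
#' lattice `2k / 2^n`, so 10 pairs cannot go below ~0.002.
#'
#' @param ddct Numeric vector of per-pair delta-delta-Ct values.
#' @param exact_max_n Passed to [wilcoxon_signed_rank()].
#' @return A `rank_test` object.
#' @export
qpcr_paired_test <- function(ddct, exact_max_n = 15) {
  if (length(ddct) < 5) {
    warning("fewer than 5 pairs: the exact test is very coarse",
            call. = FALSE)
  }
  wilcoxon_signed_rank(ddct, exact_max_n = exact_max_n)
}

#' Validation table for a qPCR confirmation experiment
#'
#' Combines [ddct_fold_changes()] and [qpcr_paired_test()] into one
#' direction / fold / p-value row per gene.
#'
#' @inheritParams ddct_fold_changes
#' @return A tibble with `gene_id`, `n_pairs`, `direction`, `fold`,
#'   `p_value`.
#' @export
qpcr_validation_table <- function(measurements, efficiency = 2) {
  dd <- ddct_fold_changes(measurements, efficiency = efficiency)
  tests <- dd$per_pair |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(p_value = qpcr_paired_test(.data$ddct)$p_value,
                     .groups = "drop")
  dplyr::left_join(dd$summary, tests, by = "gene_id") |>
    dplyr::select("gene_id", "n_pairs", "direction", "fold", "p_value")
}

#' Simulate a paired fresh-frozen qPCR confirmation experiment
#'
#' Generates target and stable-reference Cts for selected genes across
#' paired tumour/control fresh-frozen samples, using the dataset's planted
#' baselines and differential expression: `Ct = offset - log2(expression)
#' + noise`, so planted up-regulation shows as a negative ddCt.
#'
#' @param dataset An `ffpe_dataset` with ground truth.
#' @param gene_ids Genes to assay.
#' @param n_pairs Number of tumour/control pairs. Default 10.
#' @param ct_noise_sd Ct measurement noise, cycles. Default 0.25.
#' @param ct_offset Cycles at unit expression. Default 30.
#' @return A long-format measurement tibble for [ddct_fold_changes()].
#' @export
simulate_qpcr <- function(dataset, gene_ids, n_pairs = 10,
                          ct_noise_sd = 0.25, ct_offset = 30) {
  stopifnot(inherits(dataset, "ffpe_dataset"))
  truth <- dataset$truth
  idx <- match(gene_ids, truth$gene_id)
  if (anyNA(idx)) stop("unknown gene id(s)", call. = FALSE)
  cfg <- dataset$config
  withr::with_seed((cfg$seed + 104729L) %% .Machine$integer.max,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection", {
    grid <- tidyr::expand_grid(gene = seq_along(idx),
                               pair = seq_len(n_pairs),
                               group = c("tumour", "control"))
    g <- idx[grid$gene]
    expr_log2 <- truth$baseline_log2[g] +
      ifelse(grid$group == "tumour",
             truth$de_direction[g] * cfg$de_log2_effect, 0) +
      stats::rnorm(nrow(grid), 0, cfg$noise_sd)
    tibble(
      sample_id = sprintf("FF_%s%02d", ifelse(grid$group == "tumour", "T", "C"),
                          grid$pair),
      pair_id = sprintf("pair%02d", grid$pair),
      group = grid$group,
      gene_id = truth$gene_id[g],
      ct_target = ct_offset - expr_log2 +
        stats::rnorm(nrow(grid), 0, ct_noise_sd),
      ct_reference = ct_offset - cfg$baseline_log2_mean +
        stats::rnorm(nrow(grid), 0, ct_noise_sd)
    )
  })
}
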