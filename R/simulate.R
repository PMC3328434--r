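#' Configuration for the synthetic FFPE degradation simulator
#'
#' Collects every knob of the generative model in one validated object.
#' The model (per probe i, sample j, on the log2 scale):
#'
#'   signal_ij = baseline_i + de_shift_i(group_j) - d_i * q_j + noise
#'
#' where `q_j` is the sample's true quality score (Ct_diff, cycles; larger
#' is worse), induced by storage time, and `d_i` is a per-probe decay
#' coefficient (log2 intensity lost per Ct_diff cycle). For mRNA probes
#' `d_i` has a lognormal backbone plus sequence-composition effects entering
#' through cohort z-scores of G count, G-run count and C count (C
#' protective); small-RNA probes draw predominantly *negative* decay --
#' their relative abundance rises as the larger RNAs degrade. Negative
#' control probes are background noise truncated at zero. Detection dropout
#' is emergent: probes whose decayed signal falls into the background
#' distribution stop being called detected.
#'
#' @param n_genes Number of genes (one probe per gene). Default 2000.
#' @param frac_small_rna Fraction of probes in the small-RNA class.
#' @param probe_length Probe length in nucleotides. Default 50.
#' @param n_tumours,n_controls Cohort sizes. Defaults 62 / 16, the size of
#'   a single-run archival cohort passing array QC.
#' @param frac_de Fraction of genes truly differentially expressed.
#' @param de_log2_effect Planted |log2 fold change| between groups.
#' @param storage_range_months Range of storage times, months.
#' @param storage_slope Ct_diff cycles gained per month of storage.
#' @param storage_noise_sd Cycles; residual spread of quality around the
#'   storage trend. Defaults give a storage-explains-quality r^2 near 1/3.
#' @param ct_diff_base Cycles; quality offset of a freshly archived block.
#' @param decay_meanlog,decay_sdlog Lognormal backbone of mRNA decay
#'   coefficients (log2 per cycle).
#' @param decay_per_G,decay_per_GGrun,decay_per_C Sequence effects on decay
#'   per cohort z-score of the composition feature; C is protective
#'   (entered with a minus sign).
#' @param decay_noise_sd Probe-level decay noise.
#' @param smallrna_decay_mean,smallrna_decay_sd Normal decay distribution
#'   for the small-RNA class; mean negative (apparent enrichment).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance.
#' @param noise_sd Residual log2 intensity noise.
#' @param background_mean,background_sd Negative-control intensity
#'   distribution (linear scale, truncated at 0).
#' @param n_neg_controls Number of negative control probes. Default 500.
#' @param rna_yield_meanlog_tumour,rna_yield_meanlog_control,rna_yield_sdlog
#'   Lognormal RNA yield (ng) parameters per group.
#' @param confounded_design If `TRUE`, controls are drawn from a shorter
#'   storage range (`confounded_control_months`) and are therefore
#'   systematically better quality than tumours -- the design in which
#'   quality masquerades as differential expression.
#' @param confounded_control_months Storage range for controls under the
#'   confounded design.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              frac_small_rna = 0.05,
                              probe_length = 50,
                              n_tumours = 62,
                              n_controls = 16,
                              frac_de = 0.10,
                              de_log2_effect = 1,
                              storage_range_months = c(6, 156),
                              storage_slope = 0.029,
                              storage_noise_sd = 1.8,
                              ct_diff_base = 1.5,
                              decay_meanlog = log(0.06),
                              decay_sdlog = 0.8,
                              decay_per_G = 0.03,
                              decay_per_GGrun = 0.02,
                              decay_per_C = 0.03,
                              decay_noise_sd = 0.02,
                              smallrna_decay_mean = -0.05,
                              smallrna_decay_sd = 0.03,
                              baseline_log2_mean = 7.8,
                              baseline_log2_sd = 2.8,
                              noise_sd = 0.4,
                              background_mean = 100,
                              background_sd = 30,
                              n_neg_controls = 500,
                              rna_yield_meanlog_tumour = log(3000),
                              rna_yield_meanlog_control = log(1500),
                              rna_yield_sdlog = 1.0,
                              confounded_design = FALSE,
                              confounded_control_months = c(6, 36),
                              seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(frac_small_rna = frac_small_rna, frac_de = frac_de)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(n_genes, probe_length, n_tumours, n_controls, n_neg_controls)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("FFPE simulation config:", x$n_genes, "genes,",
      x$n_tumours, "tumours /", x$n_controls, "controls,",
      if (x$confounded_design) "confounded design," else "matched design,",
      "seed", x$seed, "\n")
  invisible(x)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate probe annotations with planted decay coefficients
#'
#' Draws random probe sequences, assigns gene classes, and plants the
#' per-probe decay coefficient `d_i` used by [simulate_expression()].
#' Must be called inside the seeded stream of [simulate_ffpe_dataset()]
#' for reproducibility; callers using it directly should seed the RNG.
#'
#' @param config A [simulation_config()].
#' @return A tibble with probe/gene ids, class, sequence, composition
#'   counts and the planted `decay` coefficient.
#' @export
simulate_probes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  L <- config$probe_length
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  n_small <- round(config$frac_small_rna * n)
  cls <- rep("mRNA", n)
  if (n_small > 0) cls[sample.int(n, n_small)] <- "small_rna"
  probes <- tibble(
    probe_id = sprintf("P%05d", seq_len(n)),
    gene_id = sprintf("G%05d", seq_len(n)),
    gene_class = cls,
    sequence = seqs
  )
  probes <- probe_composition(probes)
  is_m <- probes$gene_class == "mRNA"
  d <- numeric(n)
  if (any(is_m)) {
    base <- stats::rlnorm(sum(is_m), config$decay_meanlog, config$decay_sdlog)
    d[is_m] <- pmax(
      0,
      base +
        config$decay_per_G * zscore(probes$n_G[is_m]) +
        config$decay_per_GGrun * zscore(probes$n_GG_runs[is_m]) -
        config$decay_per_C * zscore(probes$n_C[is_m]) +
        stats::rnorm(sum(is_m), 0, config$decay_noise_sd)
    )
  }
  if (any(!is_m)) {
    d[!is_m] <- stats::rnorm(sum(!is_m), config$smallrna_decay_mean,
                             config$smallrna_decay_sd)
  }
  probes$decay <- d
  probes
}

#' Generate the sample cohort with storage-driven quality
#'
#' Storage months are uniform over the configured range (controls use a
#' shorter range under the confounded design); true quality is
#' `q = ct_diff_base + storage_slope * months + noise`, clipped at 0.5
#' cycles. The qPCR bookkeeping (FFPE Ct against two fresh-frozen reference
#' Cts of a stable gene) is generated so that [compute_ct_diff()] recovers
#' `q` exactly.
#'
#' @param config A [simulation_config()].
#' @return A tibble of per-sample records including `storage_months`,
#'   `rna_yield_ng`, the raw Cts and `ct_diff`.
#' @export
simulate_samples <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nt <- config$n_tumours
  nc <- config$n_controls
  group <- c(rep("tumour", nt), rep("control", nc))
  rng_t <- config$storage_range_months
  rng_c <- if (config$confounded_design) config$confounded_control_months else rng_t
  months <- c(stats::runif(nt, rng_t[1], rng_t[2]),
              stats::runif(nc, rng_c[1], rng_c[2]))
  q <- config$ct_diff_base + config$storage_slope * months +
    stats::rnorm(nt + nc, 0, config$storage_noise_sd)
  q <- pmax(q, 0.5)
  yield <- stats::rlnorm(
    nt + nc,
    meanlog = ifelse(group == "tumour", config$rna_yield_meanlog_tumour,
                     config$rna_yield_meanlog_control),
    sdlog = config$rna_yield_sdlog
  )
  ref1 <- stats::rnorm(1, 25, 0.5)
  ref2 <- stats::rnorm(1, 25, 0.5)
  samples <- tibble(
    sample_id = sprintf("%s%02d", ifelse(group == "tumour", "T", "C"),
                        c(seq_len(nt), seq_len(nc))),
    group = group,
    storage_months = months,
    rna_yield_ng = yield,
    ct_ff_ref1 = ref1,
    ct_ff_ref2 = ref2,
    ct_ffpe = (ref1 + ref2) / 2 + q,
    true_ct_diff = q
  )
  samples$ct_diff <- compute_ct_diff(samples$ct_ffpe,
                                     cbind(samples$ct_ff_ref1,
                                           samples$ct_ff_ref2))
  samples
}

#' Generate expression and negative-control matrices
#'
#' Applies the generative model to planted probes and samples; also plants
#' truly differentially expressed genes (direction random, effect
#' `de_log2_effect` added to tumours) and appends per-sample array metrics
#' (`mean_signal`, `p95`) to the sample table.
#'
#' @param probes Output of [simulate_probes()].
#' @param samples Output of [simulate_samples()].
#' @param config The [simulation_config()].
#' @return A list: `expression` (linear-scale probes x samples matrix),
#'   `neg_controls` (controls x samples), updated `samples`, and `truth`
#'   (per-gene baseline, decay, DE status and direction).
#' @export
simulate_expression <- function(probes, samples, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- nrow(probes)
  m <- nrow(samples)
  if (n != config$n_genes) stop("probe table does not match config", call. = FALSE)
  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  n_de <- round(config$frac_de * n)
  is_de <- rep(FALSE, n)
  dir <- rep(0L, n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    is_de[idx] <- TRUE
    dir[idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  }
  tumour <- samples$group == "tumour"
  shift <- outer(dir * config$de_log2_effect, as.numeric(tumour))
  log2sig <- baseline + shift -
    outer(probes$decay, samples$true_ct_diff) +
    matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m)
  expr <- 2^log2sig
  dimnames(expr) <- list(probes$probe_id, samples$sample_id)
  neg <- matrix(stats::rnorm(config$n_neg_controls * m,
                             config$background_mean, config$background_sd),
                config$n_neg_controls, m)
  neg <- pmax(neg, 0)
  dimnames(neg) <- list(sprintf("NC%04d", seq_len(config$n_neg_controls)),
                        samples$sample_id)
  samples$mean_signal <- colMeans(expr)
  samples$p95 <- apply(expr, 2, stats::quantile, probs = 0.95, names = FALSE)
  truth <- tibble(
    gene_id = probes$gene_id,
    gene_class = probes$gene_class,
    baseline_log2 = baseline,
    decay = probes$decay,
    is_de = is_de,
    de_direction = dir
  )
  list(expression = expr, neg_controls = neg, samples = samples, truth = truth)
}

#' Simulate a complete synthetic FFPE expression dataset
#'
#' Runs [simulate_probes()], [simulate_samples()] and
#' [simulate_expression()] inside a single seeded RNG stream
#' (Mersenne-Twister with inversion normals, via [withr::with_seed()]), so
#' the same config reproduces the dataset bit-identically.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ffpe_dataset`: a list with `expression`,
#'   `neg_controls`, `probes`, `samples`, `truth` and `config`.
#' @examples
#' ds <- simulate_ffpe_dataset(simulation_config(n_genes = 100,
#'   n_tumours = 8, n_controls = 4, seed = 7))
#' dim(ds$expression)
#' @export
simulate_ffpe_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection", {
    probes <- simulate_probes(config)
    samples <- simulate_samples(config)
    em <- simulate_expression(probes, samples, config)
  })
  structure(
    list(expression = em$expression, neg_controls = em$neg_controls,
         probes = probes, samples = em$samples, truth = em$truth,
         config = config),
    class = "ffpe_dataset"
  )
}

#' @export
print.ffpe_dataset <- function(x, ...) {
  cat("Synthetic FFPE dataset:", nrow(x$expression), "probes x",
      ncol(x$expression), "samples (",
      sum(x$samples$group == "tumour"), "tumours /",
      sum(x$samples$group == "control"), "controls ),",
      nrow(x$neg_controls), "negative controls\n")
  invisible(x)
}

#' Ground-truth expected detection curve and dropout slope
#'
#' From the planted baselines and decay coefficients, computes the expected
#' number of per-sample detected genes as a function of quality, using the
#' detection rule's effective background threshold (the `1 - alpha`
#' quantile of the background distribution). The OLS slope of expected
#' counts on quality is the planted genes-lost-per-cycle rate that
#' [detection_count_regression()] should recover.
#'
#' @param dataset An `ffpe_dataset`.
#' @param alpha Detection significance level. Default 0.01.
#' @return A list with `curve` (tibble sample_id, ct_diff,
#'   expected_detected) and `slope` (genes lost per cycle, positive).
#' @export
expected_detection_slope <- function(dataset, alpha = 0.01) {
  stopifnot(inherits(dataset, "ffpe_dataset"))
  cfg <- dataset$config
  thr <- log2(stats::qnorm(1 - alpha, cfg$background_mean, cfg$background_sd))
  tumour <- dataset$samples$group == "tumour"
  shift <- outer(dataset$truth$de_direction * cfg$de_log2_effect,
                 as.numeric(tumour))
  mu <- dataset$truth$baseline_log2 + shift -
    outer(dataset$truth$decay, dataset$samples$true_ct_diff)
  p_det <- stats::pnorm((mu - thr) / cfg$noise_sd)
  curve <- tibble(
    sample_id = dataset$samples$sample_id,
    group = dataset$samples$group,
    ct_diff = dataset$samples$ct_diff,
    expected_detected = colSums(p_det)
  )
  fit <- fit_ols(curve$ct_diff[curve$group == "tumour"],
                 curve$expected_detected[curve$group == "tumour"])
  list(curve = curve, slope = abs(fit$slope))
}
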