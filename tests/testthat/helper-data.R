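# Small simulation configs reused across test files. Sizes are kept small;
# the acceptance tests use the full-scale configurations.

tiny_config <- function(seed = 42, ...) {
  simulation_config(n_genes = 120, n_tumours = 10, n_controls = 6,
                    n_neg_controls = 100, seed = seed, ...)
}

small_cohort <- function(seed = 42, ...) {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 400, n_tumours = 24, n_controls = 10,
                      seed = seed, ...))
  ds$samples <- apply_sample_gates(ds$samples)
  ds
}

passing_samples <- function(ds) dplyr::filter(ds$samples, qc_pass)

# Restrict a dataset's matrices and sample table to QC-passing samples.
subset_dataset <- function(ds, samples = passing_samples(ds)) {
  ds$expression <- ds$expression[, samples$sample_id, drop = FALSE]
  ds$neg_controls <- ds$neg_controls[, samples$sample_id, drop = FALSE]
  ds$samples <- samples
  ds
}

cohort_detection <- function(ds, samples = passing_samples(ds), ...) {
  detection_pvalues(ds$expression[, samples$sample_id, drop = FALSE],
                    ds$neg_controls[, samples$sample_id, drop = FALSE],
                    group = samples$group, ...)
}
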