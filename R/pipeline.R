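#' Run the full quality-aware analysis pipeline
#'
#' Executes the stages in flowchart order -- simulate (or load), sample QC
#' gates, detection calls, normalization, per-gene quality screen (raw and
#' normalized), probe composition comparison, quality-matched and
#' confounded differential expression, clustering, qPCR validation -- and
#' writes every stage's artifacts plus a reproducibility manifest
#' (config snapshot, seed, per-stage sample accounting, file inventory
#' with MD5 checksums). The manifest carries no timestamps: two runs with
#' the same config are byte-identical.
#'
#' @param config A [simulation_config()] describing the dataset to
#'   simulate, or an existing `ffpe_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run; any of `"qc"`,
#'   `"normalize"`, `"screen"`, `"seq"`, `"de"`, `"qpcr"`. Stages not run
#'   are listed as absent in the manifest.
#' @param n_knots Normalization knots. Default 12.
#' @param de_alpha Adjusted-p significance level for DE. Default 0.01.
#' @param screen_alpha Quality-screen level. Default 0.05.
#' @param qpcr_genes Number of top DE genes to carry into the simulated
#'   qPCR confirmation. Default 4.
#' @return Invisibly, the manifest (class `run_manifest`, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         stages = c("qc", "normalize", "screen", "seq",
                                    "de", "qpcr"),
                         n_knots = 12, de_alpha = 0.01,
                         screen_alpha = 0.05, qpcr_genes = 4) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_failed <- function(stage, e) {
    stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  dataset <- if (inherits(config, "ffpe_dataset")) config else
    simulate_ffpe_dataset(config)
  cfg <- dataset$config
  write_ffpe_dataset(dataset, file.path(out_dir, "dataset"))
  outputs <- character(0)
  emit <- function(obj, rel) {
    path <- file.path(out_dir, rel)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    if (is.data.frame(obj)) {
      readr::write_tsv(as_tibble(obj), path, na = ".")
    } else if (is.matrix(obj)) {
      write_matrix_tsv(obj, path, "probe_id")
    } else if (is.character(obj)) {
      writeLines(obj, path)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
    }
    outputs <<- c(outputs, rel)
    path
  }
  counts <- NULL
  detection <- NULL
  screen_raw <- NULL

  # -- qc ------------------------------------------------------------
  samples <- tryCatch({
    s <- apply_sample_gates(dataset$samples)
    counts <- qc_summary(s)
    emit(s, "qc/sample_qc.tsv")
    passing <- dplyr::filter(s, .data$qc_pass)
    detection <- detection_pvalues(
      dataset$expression[, passing$sample_id, drop = FALSE],
      dataset$neg_controls[, passing$sample_id, drop = FALSE],
      group = passing$group
    )
    storage_fit <- storage_quality_regression(passing)
    det_reg <- detection_count_regression(passing, detection)
    emit(det_reg$counts, "qc/detected_counts.tsv")
    emit(list(
      storage_quality = unclass(storage_fit)[c("slope", "intercept",
                                               "r_squared", "p_value", "n")],
      detection_count = unclass(det_reg$fit)[c("slope", "intercept",
                                               "r_squared", "p_value", "n")],
      genes_lost_per_cycle = det_reg$genes_lost_per_cycle,
      pct_genes_detected = 100 * mean(detection$per_group$detected)
    ), "qc/summary.json")
    s
  }, error = function(e) stage_failed("qc", e))
  dataset$samples <- samples
  passing <- dplyr::filter(samples, .data$qc_pass)

  # -- normalize -----------------------------------------------------
  norm_ds <- NULL
  if ("normalize" %in% stages) {
    norm_ds <- tryCatch({
      sub <- dataset
      sub$expression <- sub$expression[, passing$sample_id, drop = FALSE]
      sub$neg_controls <- sub$neg_controls[, passing$sample_id, drop = FALSE]
      sub$samples <- passing
      nd <- normalize_dataset(sub, n_knots = n_knots)
      emit(nd$expression, "normalized/expression_normalized.tsv")
      emit(list(n_knots = nd$normalization$n_knots,
                reference_log2 = nd$normalization$reference),
           "normalized/model.json")
      nd
    }, error = function(e) stage_failed("normalize", e))
  }

  # -- screen --------------------------------------------------------
  if ("screen" %in% stages) {
    tryCatch({
      sub <- dataset
      sub$samples <- passing
      screen_raw <- screen_genes(sub, detection, alpha = screen_alpha)
      emit(as_tibble(screen_raw), "screen/gene_quality_screen.tsv")
      sums <- list(raw = summarize_quality_screen(screen_raw))
      if (!is.null(norm_ds)) {
        screen_norm <- screen_genes(norm_ds, detection, alpha = screen_alpha)
        emit(as_tibble(screen_norm), "screen/gene_quality_screen_normalized.tsv")
        sums$normalized <- summarize_quality_screen(screen_norm)
      }
      emit(sums, "screen/summary.json")
    }, error = function(e) stage_failed("screen", e))
  }

  # -- seq -----------------------------------------------------------
  if ("seq" %in% stages && !is.null(screen_raw)) {
    tryCatch({
      scr <- dplyr::left_join(as_tibble(screen_raw),
                              dataset$probes[c("gene_id", "sequence")],
                              by = "gene_id")
      aff <- dplyr::filter(scr, .data$gene_class == "mRNA", .data$affected)
      un <- dplyr::filter(scr, .data$gene_class == "mRNA", !.data$affected)
      if (nrow(aff) > 0 && nrow(un) > 0) {
        cmp <- compare_composition(aff, un,
                                   labels = c("affected", "unaffected"))
        emit(cmp, "seq/composition_comparison.tsv")
      }
    }, error = function(e) stage_failed("seq", e))
  }

  # -- de ------------------------------------------------------------
  de_res <- NULL
  if ("de" %in% stages) {
    de_res <- tryCatch({
      cc <- confounding_comparison(dataset, alpha = de_alpha)
      emit(as_tibble(cc$matched), "de/de_matched.tsv")
      emit(as_tibble(cc$unmatched), "de/de_unmatched.tsv")
      emit(cc$summary, "de/summary.tsv")
      det_sel <- detection_pvalues(
        dataset$expression[, cc$selection$samples$sample_id, drop = FALSE],
        dataset$neg_controls[, cc$selection$samples$sample_id, drop = FALSE],
        group = cc$selection$samples$group
      )
      cl <- cluster_samples(dataset$expression, cc$selection$samples,
                            genes = det_sel$per_group$gene_id[
                              det_sel$per_group$detected])
      emit(cl$newick, "de/clustering.nwk")
      emit(cl$labels, "de/cluster_labels.tsv")
      emit(list(cutoff = cc$cutoff, rand_index = cl$rand_index,
                n_significant_matched = sum(cc$matched$significant),
                n_significant_unmatched = sum(cc$unmatched$significant)),
           "de/run.json")
      cc
    }, error = function(e) stage_failed("de", e))
  }

  # -- qpcr ----------------------------------------------------------
  if ("qpcr" %in% stages && !is.null(de_res)) {
    tryCatch({
      top <- as_tibble(de_res$matched) |>
        dplyr::filter(.data$significant) |>
        dplyr::arrange(.data$p_adjusted) |>
        utils::head(qpcr_genes)
      if (nrow(top) > 0) {
        gene_ids <- dataset$probes$gene_id[match(top$gene_id,
                                                 dataset$probes$probe_id)]
        meas <- simulate_qpcr(dataset, gene_ids)
        emit(meas, "qpcr/measurements.tsv")
        emit(qpcr_validation_table(meas), "qpcr/validation.tsv")
      }
    }, error = function(e) stage_failed("qpcr", e))
  }

  all_stage_outputs <- sort(outputs)
  inventory <- tibble(
    file = all_stage_outputs,
    md5 = unname(tools::md5sum(file.path(out_dir, all_stage_outputs)))
  )
  dataset_files <- list.files(file.path(out_dir, "dataset"), full.names = FALSE)
  inventory <- dplyr::bind_rows(
    tibble(file = file.path("dataset", sort(dataset_files)),
           md5 = unname(tools::md5sum(file.path(out_dir, "dataset",
                                                sort(dataset_files))))),
    inventory
  )
  manifest <- structure(list(
    config = unclass(cfg),
    seed = cfg$seed,
    stages_run = stages,
    stages_absent = setdiff(c("qc", "normalize", "screen", "seq", "de",
                              "qpcr"), stages),
    sample_accounting = counts,
    outputs = inventory
  ), class = "run_manifest")
  jsonlite::write_json(
    list(config = manifest$config, seed = manifest$seed,
         stages_run = manifest$stages_run,
         stages_absent = manifest$stages_absent,
         sample_accounting = counts, outputs = inventory),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = I(17), pretty = TRUE, dataframe = "rows"
  )
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  cat("  stages:", paste(x$stages_run, collapse = ", "), "\n")
  cat("  outputs:", nrow(x$outputs), "files\n")
  print(x$sample_accounting)
  invisible(x)
}

#' Verify a manifest against the files on disk
#'
#' Recomputes the MD5 checksum of every file in the manifest inventory and
#' fails loudly on any mismatch, the tamper check of the reproducibility
#' contract.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return `TRUE` invisibly on success.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  root <- dirname(manifest_path)
  actual <- unname(tools::md5sum(file.path(root, man$outputs$file)))
  bad <- which(is.na(actual) | actual != man$outputs$md5)
  if (length(bad)) {
    stop("manifest verification failed for: ",
         paste(man$outputs$file[bad], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
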