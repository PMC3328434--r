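test_that("quality-matched selection applies and derives the cutoff", {
  s <- tibble::tibble(
    sample_id = paste0("s", 1:7),
    group = c("tumour", "tumour", "tumour", "control", "control", "control",
              "control"),
    ct_diff = c(3, 4, 6, 2, 3, 4, 9)
  )
  sel <- select_quality_matched(s, cutoff = 5)
  expect_equal(sum(sel$samples$group == "tumour"), 2)
  expect_equal(sel$excluded$sample_id, c("s3", "s7"))
  expect_equal(sel$excluded$reason, rep("ct-diff-above-cutoff", 2))

  # derived: smallest integer keeping all but one control
  auto <- select_quality_matched(s)
  expect_equal(auto$cutoff, 5)

  expect_error(select_quality_matched(s, cutoff = 0.4), "below cutoff")
})

test_that("differential expression recovers planted effects", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 600, n_tumours = 28, n_controls = 15,
                      seed = 23))
  ds$samples <- apply_sample_gates(ds$samples)
  pas <- passing_samples(ds)
  det <- cohort_detection(ds, pas)
  de <- differential_expression(ds$expression, pas, detection = det)
  expect_s3_class(de, "de_result")
  expect_true(all(de$fold_change >= 1))
  expect_true(all(de$significant == (de$p_adjusted < 0.01)))
  expect_true(all(de$above_2fold == (de$fold_change >= 2)))
  # detection filter reduces (or preserves) the tested set
  de_all <- differential_expression(ds$expression, pas)
  expect_lte(nrow(de), nrow(de_all))

  probe_de <- ds$probes$probe_id[match(ds$truth$gene_id[ds$truth$is_de],
                                       ds$probes$gene_id)]
  tested_true <- intersect(de$gene_id, probe_de)
  sig <- de$gene_id[de$significant]
  expect_gt(length(intersect(sig, tested_true)) / length(tested_true), 0.8)
  if (length(sig) > 0) expect_lte(mean(!sig %in% probe_de), 0.05)
})

test_that("null genes stay quiet under B-H at 0.01", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 1000, n_tumours = 20, n_controls = 15,
                      frac_de = 0, seed = 29))
  ds$samples <- apply_sample_gates(ds$samples)
  pas <- passing_samples(ds)
  de <- differential_expression(ds$expression, pas)
  expect_lte(sum(de$significant), 2)
})

test_that("B-H adjusted values are invariant to gene order", {
  ds <- simulate_ffpe_dataset(tiny_config())
  pas <- ds$samples
  de1 <- differential_expression(ds$expression, pas)
  perm <- sample(nrow(ds$expression))
  de2 <- differential_expression(ds$expression[perm, ], pas)
  m <- match(de1$gene_id, de2$gene_id)
  expect_equal(de1$p_adjusted, de2$p_adjusted[m])
})

test_that("fold change is exact at a planted log2 difference", {
  expr <- 2^rbind(g1 = c(rep(3, 4), rep(2, 4)),
                  g2 = rep(5, 8))
  colnames(expr) <- paste0("s", 1:8)
  samples <- tibble::tibble(sample_id = colnames(expr),
                            group = rep(c("tumour", "control"), each = 4))
  expect_warning(de <- differential_expression(expr, samples),
                 "zero variance")
  g1 <- de[de$gene_id == "g1", ]
  expect_equal(unname(g1$fold_change), 2)
  expect_equal(unname(g1$direction), "up")
  expect_true(g1$above_2fold)
  expect_equal(unname(de$p_raw[de$gene_id == "g2"]), 1)
})

test_that("mann-whitney engine is available by flag", {
  ds <- simulate_ffpe_dataset(tiny_config())
  de <- differential_expression(ds$expression[1:30, ], ds$samples,
                                method = "mann-whitney")
  expect_true(all(de$p_raw > 0 & de$p_raw <= 1))
})

test_that("confounded design inflates unmatched DE and matching calms it", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 500, frac_de = 0, confounded_design = TRUE,
                      seed = 31))
  ds$samples <- apply_sample_gates(ds$samples)
  cc <- confounding_comparison(ds)
  expect_gt(mean(cc$unmatched$p_raw < 0.01),
            mean(cc$matched$p_raw < 0.01))
  expect_equal(cc$cutoff, 5)
  expect_true(all(cc$selection$samples$ct_diff < cc$cutoff))
})

test_that("ground-truth attribution labels unmatched false flags", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 2000, confounded_design = TRUE, seed = 33))
  ds$samples <- apply_sample_gates(ds$samples)
  cc <- confounding_comparison(ds)
  expect_true(!is.null(cc$truth_attribution))
  expect_gte(cc$truth_attribution$n_false_unmatched,
             cc$truth_attribution$n_false_matched)
  if (cc$truth_attribution$n_false_unmatched >= 5) {
    expect_gt(cc$truth_attribution$frac_unmatched_false_quality_sensitive,
              0.7)
  }
})

test_that("clustering separates groups at large planted effect", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 500, n_tumours = 20, n_controls = 10,
                      de_log2_effect = 2, seed = 37))
  ds$samples <- apply_sample_gates(ds$samples)
  pas <- passing_samples(ds)
  det <- cohort_detection(ds, pas)
  cl <- cluster_samples(ds$expression, pas,
                        genes = det$per_group$gene_id[det$per_group$detected])
  expect_equal(cl$rand_index, 1)
  expect_equal(sort(unique(cl$labels$cluster)), 1:2)
})

test_that("no planted effect leaves clustering at chance", {
  ri <- vapply(1:5, function(i) {
    ds <- simulate_ffpe_dataset(
      simulation_config(n_genes = 300, n_tumours = 12, n_controls = 12,
                        frac_de = 0, seed = 40 + i))
    cluster_samples(ds$expression, ds$samples)$rand_index
  }, numeric(1))
  expect_lt(mean(ri), 0.9)
})

test_that("duplicated samples merge first and newick round-trips", {
  ds <- simulate_ffpe_dataset(tiny_config())
  expr <- ds$expression
  expr <- cbind(expr, dup = expr[, 1] * (1 + 1e-9))
  samples <- dplyr::bind_rows(ds$samples,
                              tibble::tibble(sample_id = "dup",
                                             group = ds$samples$group[1]))
  cl <- cluster_samples(expr, samples)
  first_merge <- cl$hclust$labels[-cl$hclust$merge[1, ]]
  expect_setequal(first_merge, c(ds$samples$sample_id[1], "dup"))
  # newick parses back with identical topology
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, samples$sample_id)
  ref <- ape::as.phylo(cl$hclust)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ref))[1], 0)
})

test_that("rand index is exact on known partitions", {
  expect_equal(rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c("a", "b", "a", "b")), 1 / 3)
})
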