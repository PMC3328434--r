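test_that("config validation catches bad inputs", {
  expect_error(simulation_config(frac_de = 1.5), "fractions")
  expect_error(simulation_config(n_genes = 0), "positive integers")
  expect_error(simulation_config(seed = NA), "seed")
})

test_that("same seed gives bit-identical datasets", {
  a <- simulate_ffpe_dataset(tiny_config())
  b <- simulate_ffpe_dataset(tiny_config())
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(a$probes, b$probes)
  c <- simulate_ffpe_dataset(tiny_config(seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("probe sequences are uniform and decay tracks planted sequence effects", {
  cfg <- simulation_config(n_genes = 2000, seed = 1)
  withr::with_seed(1, probes <- simulate_probes(cfg))
  # per-base counts near length/4 under uniform draws
  expect_equal(mean(probes$n_A), cfg$probe_length / 4, tolerance = 0.02)
  expect_equal(mean(probes$n_G), cfg$probe_length / 4, tolerance = 0.02)
  expect_equal(probes$n_A + probes$n_C + probes$n_G + probes$n_T,
               rep(cfg$probe_length, nrow(probes)))
  m <- probes[probes$gene_class == "mRNA", ]
  expect_gt(cor(m$n_G, m$decay, method = "spearman"), 0.1)
  expect_lt(cor(m$n_C, m$decay, method = "spearman"), -0.1)
  # small RNAs predominantly negative decay
  s <- probes[probes$gene_class == "small_rna", ]
  expect_gt(mean(s$decay < 0), 0.8)
})

test_that("decay is sequence-independent when sequence effects are off", {
  cfg <- simulation_config(n_genes = 1500, decay_per_G = 0,
                           decay_per_GGrun = 0, decay_per_C = 0, seed = 5)
  withr::with_seed(5, probes <- simulate_probes(cfg))
  m <- probes[probes$gene_class == "mRNA", ]
  ct <- cor.test(m$n_G, m$decay)
  expect_true(ct$conf.int[1] < 0 && ct$conf.int[2] > 0)
})

test_that("sample quality is driven by storage with the planted r2", {
  cfg <- simulation_config(n_tumours = 60, n_controls = 10, seed = 2)
  withr::with_seed(2, samples <- simulate_samples(cfg))
  fit <- fit_ols(samples$storage_months[samples$group == "tumour"],
                 samples$ct_diff[samples$group == "tumour"])
  expect_gt(fit$r_squared, 0.2)
  expect_lt(fit$r_squared, 0.45)
  expect_true(all(samples$ct_diff >= 0.5))

  noiseless <- simulation_config(storage_noise_sd = 0, ct_diff_base = 3, seed = 2)
  withr::with_seed(2, s0 <- simulate_samples(noiseless))
  f0 <- fit_ols(s0$storage_months[s0$group == "tumour"],
                s0$ct_diff[s0$group == "tumour"])
  expect_equal(f0$r_squared, 1, tolerance = 1e-9)
})

test_that("confounded design makes controls systematically better quality", {
  ds <- simulate_ffpe_dataset(
    simulation_config(n_genes = 50, confounded_design = TRUE, seed = 9))
  q <- ds$samples
  expect_gt(mean(q$ct_diff[q$group == "tumour"]),
            mean(q$ct_diff[q$group == "control"]) + 0.5)
})

test_that("expression follows the planted decay model", {
  # no decay anywhere -> per-gene slope p-values uniform
  ds0 <- simulate_ffpe_dataset(
    simulation_config(n_genes = 300, n_tumours = 30, n_controls = 5,
                      frac_de = 0, decay_meanlog = log(1e-9),
                      decay_sdlog = 1e-6, decay_per_G = 0, decay_per_GGrun = 0,
                      decay_per_C = 0, decay_noise_sd = 0,
                      smallrna_decay_mean = 0, smallrna_decay_sd = 0,
                      seed = 12))
  tum <- ds0$samples[ds0$samples$group == "tumour", ]
  fits <- ffpeqc:::ols_screen_rows(log2(ds0$expression[, tum$sample_id]),
                                   tum$ct_diff)
  expect_lt(abs(mean(fits$p_value < 0.05) - 0.05),
            2.5 * sqrt(0.05 * 0.95 / nrow(fits)))

  # strong planted decay -> monotone expected decrease in quality
  ds1 <- simulate_ffpe_dataset(tiny_config())
  hi <- which.max(ds1$probes$decay)
  tum1 <- ds1$samples[ds1$samples$group == "tumour", ]
  fit <- fit_ols(tum1$ct_diff, log2(ds1$expression[hi, tum1$sample_id]))
  expect_lt(fit$slope, 0)
})

test_that("dataset round-trips through disk bit-identically", {
  ds <- simulate_ffpe_dataset(tiny_config())
  dir <- withr::local_tempdir()
  write_ffpe_dataset(ds, dir)
  back <- read_ffpe_dataset(dir)
  expect_equal(back$expression, ds$expression)
  expect_equal(back$neg_controls, ds$neg_controls)
  expect_equal(as.data.frame(back$truth), as.data.frame(ds$truth))
  expect_equal(nrow(back$truth), ds$config$n_genes)
  # config file alone reproduces the dataset
  again <- simulate_ffpe_dataset(back$config)
  expect_identical(again$expression, ds$expression)
})

test_that("malformed matrix files are rejected with location info", {
  ds <- simulate_ffpe_dataset(tiny_config())
  dir <- withr::local_tempdir()
  write_ffpe_dataset(ds, dir)
  path <- file.path(dir, "expression.tsv")
  lines <- readLines(path)
  fields <- strsplit(lines[3], "\t")[[1]]
  fields[2] <- "."
  lines[3] <- paste(fields, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_ffpe_dataset(dir), "missing cell")
})
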