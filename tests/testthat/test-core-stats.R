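test_that("fit_ols reproduces closed-form examples", {
  perfect <- fit_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$r_squared, 1)

  hand <- fit_ols(c(0, 1, 2), c(0, 2, 2))
  expect_equal(hand$slope, 1)
  expect_equal(hand$intercept, 1 / 3)
  expect_equal(hand$r_squared, 0.75)

  expect_warning(flat <- fit_ols(c(0, 1, 2), c(5, 5, 5)), "constant response")
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("fit_ols matches lm on random inputs", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(3:30, 1)
      x <- rnorm(n)
      y <- 0.5 * x + rnorm(n)
      fit <- fit_ols(x, y)
      ref <- summary(lm(y ~ x))
      expect_equal(fit$slope, unname(coef(ref)["x", "Estimate"]),
                   tolerance = 1e-10)
      expect_equal(fit$intercept, unname(coef(ref)["(Intercept)", "Estimate"]),
                   tolerance = 1e-10)
      expect_equal(fit$r_squared, ref$r.squared, tolerance = 1e-10)
      expect_equal(fit$p_value, unname(coef(ref)["x", "Pr(>|t|)"]),
                   tolerance = 1e-10)
    }
  })
})

test_that("fit_ols rejects degenerate inputs", {
  expect_error(fit_ols(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_ols(c(1, 2), c(1, 2)), "at least 3")
})

test_that("row-wise screen fits agree with per-gene fit_ols", {
  withr::with_seed(21, {
    Y <- matrix(rnorm(20 * 8), 20, 8)
    x <- rnorm(8)
    rows <- ffpeqc:::ols_screen_rows(Y, x)
    for (i in c(1, 7, 20)) {
      fit <- fit_ols(x, Y[i, ])
      expect_equal(rows$slope[i], fit$slope, tolerance = 1e-12)
      expect_equal(rows$p_value[i], fit$p_value, tolerance = 1e-12)
      expect_equal(rows$r_squared[i], fit$r_squared, tolerance = 1e-12)
    }
  })
})

test_that("under a true null the slope test is calibrated", {
  withr::with_seed(31, {
    p <- replicate(1000, fit_ols(rnorm(10), rnorm(10))$p_value)
  })
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("exact Mann-Whitney matches the enumeration oracle", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$method, "mann-whitney-exact")

  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  withr::with_seed(41, {
    for (i in 1:60) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      vals <- sample(1:5, n1 + n2, replace = TRUE) # forces ties
      a <- vals[seq_len(n1)]
      b <- vals[-seq_len(n1)]
      if (length(unique(vals)) == 1) next
      expect_equal(mann_whitney(a, b)$p_value, oracle_mann_whitney(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact Mann-Whitney agrees with wilcox.test when tie-free", {
  withr::with_seed(43, {
    for (i in 1:20) {
      a <- rnorm(4)
      b <- rnorm(4)
      expect_equal(mann_whitney(a, b)$p_value,
                   wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("large-sample Mann-Whitney approximation is sensible", {
  withr::with_seed(44, {
    a <- rnorm(40)
    b <- rnorm(40) + 2
  })
  res <- mann_whitney(a, b)
  expect_equal(res$method, "mann-whitney-approx")
  expect_lt(res$p_value, 1e-6)
  expect_warning(tied <- mann_whitney(rep(1, 10), rep(1, 12)), "tied")
  expect_equal(tied$p_value, 1)
})

test_that("Mann-Whitney null rejection rate is nominal", {
  withr::with_seed(45, {
    p <- replicate(1000, mann_whitney(rnorm(10), rnorm(10))$p_value)
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("exact Wilcoxon signed-rank matches enumeration", {
  res <- wilcoxon_signed_rank(1:5)
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 2 / 32)
  expect_equal(res$method, "wilcoxon-exact")

  expect_equal(wilcoxon_signed_rank(c(1, -1))$p_value, 1)
  expect_equal(wilcoxon_signed_rank(rep(1, 10))$p_value, 2 / 1024)

  withr::with_seed(51, {
    for (i in 1:40) {
      n <- sample(2:9, 1)
      d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
      expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_wilcoxon(d),
                   tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon conventions: zeros dropped, all-zero warns", {
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$p_value,
               wilcoxon_signed_rank(c(1, 2, 3))$p_value)
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_equal(res$p_value, 1)
})

test_that("bh_adjust equals the naive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(61, {
    for (i in 1:200) {
      p <- runif(sample(1:50, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_equal(order(adj[order(p)]), seq_along(p)) # monotone in p
    }
  })
})

test_that("pearson_distance_matrix matches the direct formula", {
  withr::with_seed(71, {
    m <- matrix(rnorm(40), 10, 4)
  })
  colnames(m) <- paste0("s", 1:4)
  d <- pearson_distance_matrix(m)
  expect_equal(d, oracle_pearson_distance(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diag(d), setNames(rep(0, 4), colnames(m)))

  dup <- cbind(m, s5 = m[, 1], s6 = -m[, 1])
  d2 <- pearson_distance_matrix(dup)
  expect_equal(d2["s1", "s5"], 0, tolerance = 1e-12)
  expect_equal(d2["s1", "s6"], 2, tolerance = 1e-12)

  bad <- m
  bad[, 2] <- 7
  expect_error(pearson_distance_matrix(bad), "s2")
})

test_that("tidy and glance methods expose fit results", {
  fit <- fit_ols(1:10, (1:10) * 2 + rnorm(10, sd = 1e-3))
  expect_named(glance(fit), c("r.squared", "sigma", "p.value", "nobs"))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "x"], fit$slope)
  rt <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(tidy(rt)$p.value, 1 / 3)
})
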