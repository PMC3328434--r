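#' Simple linear regression by ordinary least squares
#'
#' Closed-form least-squares fit of `y` on `x`, the regression primitive
#' used by every cohort- and gene-level screen in the package. The two-sided
#' p-value for the slope comes from the t distribution with `n - 2` degrees
#' of freedom.
#'
#' @param x Numeric predictor; must not be constant.
#' @param y Numeric response, same length as `x`.
#'
#' @return An object of class `ols_fit` with elements `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n` and `sigma` (residual standard deviation).
#'   When the response is constant (`SS_tot = 0`), `r_squared` is defined as
#'   0 with a warning: a flat response carries no signal.
#'
#' @examples
#' fit <- fit_ols(c(0, 1, 2), c(0, 2, 2))
#' fit$slope      # 1
#' fit$r_squared  # 0.75
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("degenerate input: need at least 3 complete observations", call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    stop("degenerate input: predictor `x` has zero variance", call. = FALSE)
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- ss_tot - slope^2 * sxx
  ss_res <- max(ss_res, 0) # guard tiny negative from cancellation
  if (ss_tot == 0) {
    warning("constant response: r_squared defined as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  sigma2 <- ss_res / (n - 2)
  if (sigma2 == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    tstat <- slope / sqrt(sigma2 / sxx)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         p_value = p, n = n, sigma = sqrt(sigma2)),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (n =", x$n, ")\n")
  cat(sprintf("  slope %.4g, intercept %.4g\n", x$slope, x$intercept))
  cat(sprintf("  r^2 = %.3f, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

# Row-wise simple regression of every row of Y on x; vectorized closed form.
# Returns a tibble with one row per row of Y. Rows with zero response
# variance get slope 0, r2 0, p 1 (no signal).
ols_screen_rows <- function(Y, x) {
  stopifnot(ncol(Y) == length(x))
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for the per-gene screen", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate input: predictor has zero variance", call. = FALSE)
  ym <- rowMeans(Y)
  slope <- as.numeric(Y %*% xc) / sxx
  ss_tot <- rowSums((Y - ym)^2)
  ss_res <- pmax(ss_tot - slope^2 * sxx, 0)
  sigma2 <- ss_res / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(-abs(tstat), df = n - 2))
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  tibble(
    slope = slope,
    intercept = ym - slope * mean(x),
    r_squared = r2,
    p_value = p,
    n = n
  )
}

rank_test_result <- function(statistic, p_value, method, n) {
  structure(
    list(statistic = statistic, p_value = min(max(p_value, 0), 1),
         method = method, n = n),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "+")))
  invisible(x)
}

two_sided_enum_p <- function(null_stats, observed) {
  eps <- 1e-9
  lo <- mean(null_stats <= observed + eps)
  hi <- mean(null_stats >= observed - eps)
  min(1, 2 * min(lo, hi))
}

#' Mann-Whitney U test for two unpaired groups
#'
#' Two-sided rank-sum test. When the pooled sample size is at most
#' `exact_max_n` the p-value is computed by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings (valid under ties, which get
#' average ranks); above that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_max_n Largest pooled size for which the exact null
#'   distribution is enumerated. Default 12 (enumeration cost grows as
#'   `choose(n, n_a)`).
#'
#' @return A `rank_test` object with the U statistic of group `a`, the
#'   two-sided p-value and the method used.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p_value # 1/3, by enumeration
#' @export
mann_whitney <- function(a, b, exact_max_n = 12) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; p = 1", call. = FALSE)
    return(rank_test_result(U, 1, "mann-whitney-approx", c(n1, n2)))
  }
  if (n1 + n2 <= exact_max_n) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- two_sided_enum_p(Us, U)
    return(rank_test_result(U, p, "mann-whitney-exact", c(n1, n2)))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (U - mu)
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2) # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  rank_test_result(U, p, "mann-whitney-approx", c(n1, n2))
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided one-sample signed-rank test on a vector of paired differences.
#' Zero differences are dropped before ranking (standard convention). When
#' the number of non-zero differences is at most `exact_max_n`, the p-value
#' is computed by enumerating all `2^n` sign assignments (valid under tied
#' absolute ranks); otherwise a normal approximation with tie and continuity
#' corrections is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max_n Largest `n` for which the `2^n` sign vectors are
#'   enumerated. Default 15.
#'
#' @return A `rank_test` object; the statistic is `W+`, the sum of ranks of
#'   positive differences.
#' @examples
#' wilcoxon_signed_rank(1:5)$p_value # 2/32, by enumeration
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max_n = 15) {
  d <- as.numeric(diffs)
  if (anyNA(d)) stop("missing values not allowed", call. = FALSE)
  if (length(d) == 0) stop("need at least one difference", call. = FALSE)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(rank_test_result(0, 1, "wilcoxon-approx", 0L))
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max_n) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% r)
    p <- two_sided_enum_p(Ws, W)
    return(rank_test_result(W, p, "wilcoxon-exact", n))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- W - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  rank_test_result(W, p, "wilcoxon-approx", n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (running-minimum monotonized,
#' capped at 1, input order preserved). Validates the input and delegates
#' the arithmetic to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson-correlation distance between sample columns
#'
#' Distance `1 - r` where `r` is the Pearson correlation between sample
#' columns of a genes-by-samples matrix; the similarity measure used for
#' unsupervised clustering of arrays.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns; at least
#'   2 of each, no constant column.
#' @return A symmetric samples-by-samples matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(mat)[sds == 0] %||% which(sds == 0)
    stop("constant sample column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- 1 - stats::cor(mat)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}
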