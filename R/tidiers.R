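#' @export
tidy.ols_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$sigma, p.value = x$p_value,
         nobs = x$n)
}

#' @export
tidy.rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}

#' @export
tidy.sample_clustering <- function(x, ...) {
  x$labels
}

#' @export
glance.sample_clustering <- function(x, ...) {
  tibble(k = x$k, linkage = x$linkage, rand.index = x$rand_index,
         nobs = nrow(x$labels))
}

#' @export
tidy.detection_calls <- function(x, ...) {
  if (is.null(x$per_group)) {
    stop("no per-group detection results to tidy", call. = FALSE)
  }
  x$per_group
}
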