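#' Fit a spline quantile normalization model
#'
#' Quantile-anchored monotone cubic spline normalization, fitted on log2
#' intensities and *without* background subtraction (negative-control
#' signal is never removed). The reference curve is the across-sample mean
#' of per-sample quantile curves evaluated at `n_knots` evenly spaced
#' quantile levels; each sample gets a monotone cubic spline (Hyman
#' filtered) mapping its own quantiles onto the reference. With
#' `n_knots = 2` the mapping degenerates to a linear rescaling between the
#' per-sample extremes.
#'
#' @param expression Probes x samples matrix of positive intensities.
#' @param n_knots Number of quantile anchor points. Default 12. Reduced
#'   with a warning when a sample has fewer unique values.
#' @return An object of class `spline_norm_model`.
#' @export
fit_spline_normalization <- function(expression, n_knots = 12) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(expression <= 0)) {
    stop("intensities must be positive (log2 is applied internally)",
         call. = FALSE)
  }
  if (n_knots < 2) stop("need at least 2 knots", call. = FALSE)
  lx <- log2(expression)
  min_unique <- min(apply(lx, 2, function(v) length(unique(v))))
  if (min_unique < n_knots) {
    warning(sprintf("reducing knots from %d to %d (fewer unique values)",
                    n_knots, min_unique), call. = FALSE)
    n_knots <- max(2, min_unique)
  }
  levels <- seq(0, 1, length.out = n_knots)
  qmat <- apply(lx, 2, stats::quantile, probs = levels, names = FALSE)
  ref <- rowMeans(qmat)
  structure(
    list(levels = levels, reference = ref, sample_quantiles = qmat,
         sample_ids = colnames(expression), n_knots = n_knots),
    class = "spline_norm_model"
  )
}

#' @export
print.spline_norm_model <- function(x, ...) {
  cat("Spline normalization model:", length(x$sample_ids), "samples,",
      x$n_knots, "quantile knots (log2 scale)\n")
  invisible(x)
}

# Monotone spline through (x, y) anchors with linear extrapolation beyond
# the anchor range (keeps the mapping monotone everywhere).
monotone_map <- function(x, y) {
  keep <- !duplicated(x)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) {
    off <- y[1] - x[1]
    return(function(v) v + off)
  }
  f <- stats::splinefun(x, y, method = "hyman")
  x1 <- x[1]; xk <- x[length(x)]
  s1 <- (y[2] - y[1]) / (x[2] - x[1])
  sk <- (y[length(y)] - y[length(y) - 1]) / (xk - x[length(x) - 1])
  function(v) {
    out <- numeric(length(v))
    lo <- v < x1
    hi <- v > xk
    mid <- !lo & !hi
    out[mid] <- f(v[mid])
    out[lo] <- y[1] + s1 * (v[lo] - x1)
    out[hi] <- y[length(y)] + sk * (v[hi] - xk)
    out
  }
}

#' Apply a fitted normalization model
#'
#' Maps each sample's intensities through its monotone spline onto the
#' reference quantile curve. Negative controls, when supplied, are mapped
#' with the *same* per-sample spline, so background is transformed
#' consistently with signal rather than subtracted.
#'
#' @param model A `spline_norm_model`.
#' @param expression Probes x samples matrix; sample names must be present
#'   in the model.
#' @param neg_controls Optional controls x samples matrix.
#' @return A list with normalized `expression` (and `neg_controls` if
#'   given), on the original linear scale.
#' @export
apply_normalization <- function(model, expression, neg_controls = NULL) {
  stopifnot(inherits(model, "spline_norm_model"))
  expression <- as.matrix(expression)
  ids <- colnames(expression)
  missing <- setdiff(ids, model$sample_ids)
  if (length(missing)) {
    stop("sample(s) absent from normalization model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map_sample <- function(values, id) {
    j <- match(id, model$sample_ids)
    f <- monotone_map(model$sample_quantiles[, j], model$reference)
    lv <- log2(pmax(values, .Machine$double.xmin))
    mapped <- f(lv)
    out <- 2^mapped
    out[values <= 0] <- 0
    out
  }
  norm_expr <- expression
  for (id in ids) norm_expr[, id] <- map_sample(expression[, id], id)
  out <- list(expression = norm_expr)
  if (!is.null(neg_controls)) {
    neg_controls <- as.matrix(neg_controls)
    nc <- neg_controls
    for (id in colnames(neg_controls)) {
      nc[, id] <- map_sample(neg_controls[, id], id)
    }
    out$neg_controls <- nc
  }
  out
}

#' Normalize an FFPE dataset in place
#'
#' Convenience wrapper: fits the spline quantile model on the dataset's
#' expression matrix and returns a copy of the dataset with normalized
#' expression and negative controls, the model attached as
#' `$normalization`.
#'
#' @param dataset An `ffpe_dataset`.
#' @param n_knots Passed to [fit_spline_normalization()].
#' @return The normalized `ffpe_dataset`.
#' @export
normalize_dataset <- function(dataset, n_knots = 12) {
  stopifnot(inherits(dataset, "ffpe_dataset"))
  model <- fit_spline_normalization(dataset$expression, n_knots = n_knots)
  mapped <- apply_normalization(model, dataset$expression,
                                dataset$neg_controls)
  dataset$expression <- mapped$expression
  dataset$neg_controls <- mapped$neg_controls
  dataset$normalization <- model
  dataset
}
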