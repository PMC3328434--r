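#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of sample columns on `1 - Pearson r`
#' distances (average linkage by default), cut into `k` flat clusters and
#' compared against the known group labels with the Rand index. The
#' dendrogram is serialized to Newick.
#'
#' @param expression Probes x samples intensity matrix (clustered on log2
#'   scale).
#' @param samples Sample tibble with `sample_id` and `group`.
#' @param genes Optional character vector restricting to (detected) genes.
#' @param k Number of flat clusters. Default 2.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `sample_clustering`: `hclust`, `labels`
#'   tibble, `newick` string, `rand_index`, `k`.
#' @export
cluster_samples <- function(expression, samples, genes = NULL, k = 2,
                            linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  expr <- as.matrix(expression)[, samples$sample_id, drop = FALSE]
  if (!is.null(genes)) {
    expr <- expr[intersect(rownames(expr), genes), , drop = FALSE]
  }
  if (ncol(expr) < 3) stop("need at least 3 samples to cluster", call. = FALSE)
  lx <- log2(pmax(expr, .Machine$double.xmin))
  d <- pearson_distance_matrix(lx)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  cl <- stats::cutree(hc, k = k)
  labels <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    cluster = unname(cl[samples$sample_id])
  )
  structure(
    list(
      hclust = hc,
      labels = labels,
      newick = ape::write.tree(ape::as.phylo(hc)),
      rand_index = rand_index(labels$cluster, labels$group),
      k = k,
      linkage = linkage
    ),
    class = "sample_clustering"
  )
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (both together
#' or both apart); 1 means identical partitions up to label names.
#'
#' @param a,b Two label vectors of equal length.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least 2 elements", call. = FALSE)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf(
    "Sample clustering: %d samples, %s linkage, k = %d, Rand index vs groups = %.3f\n",
    nrow(x$labels), x$linkage, x$k, x$rand_index))
  print(table(cluster = x$labels$cluster, group = x$labels$group))
  invisible(x)
}

#' @export
plot.sample_clustering <- function(x, ...) {
  plot(stats::as.dendrogram(x$hclust), ...)
  invisible(x)
}
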