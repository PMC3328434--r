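#' Base composition and G-run content of probe sequences
#'
#' Counts A/C/G/T and the number of maximal runs of at least `min_run`
#' consecutive guanines in each probe sequence. Degradation and chemical
#' modification of FFPE RNA are sequence dependent, and G content / G runs
#' in the ~50-nt probe are the composition features that separate
#' quality-sensitive from robust probes, so these five numbers are the
#' feature set for all composition comparisons in the package.
#'
#' A run is *maximal*: `"GGGG"` contains one run, `"AGGTGGGA"` two.
#'
#' @param sequences Character vector of probe sequences over `{A,C,G,T}`,
#'   or a data frame with a `sequence` column (e.g. a probe annotation
#'   table), in which case the counts are appended as columns.
#' @param min_run Minimum run length counted as a G run. Default 2
#'   ("two or more consecutive Gs"); set 3 for the stricter
#'   "more than two" convention.
#'
#' @return A tibble with columns `n_A`, `n_C`, `n_G`, `n_T`, `n_GG_runs`
#'   (plus the input columns when a data frame was supplied).
#' @examples
#' probe_composition("AGGTGGGA") # 2 A, 5 G, 2 G-runs
#' @export
probe_composition <- function(sequences, min_run = 2) {
  df <- NULL
  if (is.data.frame(sequences)) {
    if (!"sequence" %in% names(sequences)) {
      stop("data frame input must have a `sequence` column", call. = FALSE)
    }
    df <- as_tibble(sequences)
    seqs <- df$sequence
  } else {
    seqs <- as.character(sequences)
  }
  if (length(seqs) == 0 || any(!nzchar(seqs))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!chars[[i]] %in% c("A", "C", "G", "T"))
    if (length(bad)) {
      stop(sprintf("invalid character '%s' at position %d of sequence %d",
                   chars[[i]][bad[1]], bad[1], i), call. = FALSE)
    }
  }
  count_base <- function(ch, base) sum(ch == base)
  comp <- tibble(
    n_A = vapply(chars, count_base, integer(1) + 0, base = "A"),
    n_C = vapply(chars, count_base, integer(1) + 0, base = "C"),
    n_G = vapply(chars, count_base, integer(1) + 0, base = "G"),
    n_T = vapply(chars, count_base, integer(1) + 0, base = "T"),
    n_GG_runs = vapply(chars, function(ch) {
      r <- rle(ch == "G")
      sum(r$values & r$lengths >= min_run)
    }, integer(1) + 0)
  )
  if (!is.null(df)) dplyr::bind_cols(df, comp) else comp
}

#' Compare probe composition between two probe groups
#'
#' Mann-Whitney comparison of each composition feature (A, C, G, T counts
#' and G runs) between two groups of probes, typically quality-affected vs
#' unaffected probes. Operates at probe level.
#'
#' @param group_a,group_b Character vectors of sequences or data frames
#'   with a `sequence` column. Both non-empty.
#' @param min_run Passed to [probe_composition()].
#' @param exact_max_n Passed to [mann_whitney()].
#' @param labels Length-2 character, names for the two groups in the
#'   output column headers.
#'
#' @return A tibble with one row per feature: group means, U statistic and
#'   two-sided p-value.
#' @export
compare_composition <- function(group_a, group_b, min_run = 2,
                                exact_max_n = 12,
                                labels = c("group_a", "group_b")) {
  ca <- probe_composition(group_a, min_run = min_run)
  cb <- probe_composition(group_b, min_run = min_run)
  features <- c("n_A", "n_C", "n_G", "n_T", "n_GG_runs")
  out <- purrr::map_dfr(features, function(f) {
    test <- mann_whitney(ca[[f]], cb[[f]], exact_max_n = exact_max_n)
    tibble(
      feature = sub("^n_", "", f),
      mean_a = mean(ca[[f]]),
      mean_b = mean(cb[[f]]),
      statistic = test$statistic,
      p_value = test$p_value,
      method = test$method
    )
  })
  names(out)[names(out) == "mean_a"] <- paste0("mean_", labels[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", labels[2])
  out
}
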