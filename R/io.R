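# Tab-separated artifact I/O. All matrices carry explicit row identifiers
# in the first column; headers are mandatory; missing values are written
# as ".".

write_matrix_tsv <- function(mat, path, id_col) {
  df <- as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

read_matrix_tsv <- function(path, id_col) {
  df <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                        progress = FALSE)
  if (names(df)[1] != id_col) {
    stop(sprintf("%s: expected first column '%s', found '%s'",
                 path, id_col, names(df)[1]), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop(sprintf("%s: missing cell(s) at data line %d (column %s)",
                 path, bad[1],
                 names(df)[which(is.na(df[bad[1], ]))[1]]), call. = FALSE)
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' Write a synthetic dataset to disk
#'
#' Emits the expression matrix, negative-control matrix, probe annotation,
#' sample metadata and ground-truth tables as TSV, and the simulation
#' config as JSON, into `dir`. [read_ffpe_dataset()] round-trips the
#' result bit-identically.
#'
#' @param dataset An `ffpe_dataset`.
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_ffpe_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ffpe_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    neg_controls = file.path(dir, "neg_controls.tsv"),
    probes = file.path(dir, "probes.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  tryCatch({
    write_matrix_tsv(dataset$expression, paths["expression"], "probe_id")
    write_matrix_tsv(dataset$neg_controls, paths["neg_controls"], "control_id")
    readr::write_tsv(dataset$probes, paths["probes"], na = ".")
    readr::write_tsv(dataset$samples, paths["samples"], na = ".")
    readr::write_tsv(dataset$truth, paths["truth"], na = ".")
    cfg <- unclass(dataset$config)
    # digits = I(17): doubles must survive the JSON round-trip exactly so
    # that a re-run from the config file reproduces the dataset bit for bit
    jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE,
                         digits = I(17))
  }, error = function(e) {
    stop(sprintf("failed writing dataset under '%s': %s", dir,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(paths)
}

#' Read a dataset written by [write_ffpe_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return An `ffpe_dataset`.
#' @export
read_ffpe_dataset <- function(dir) {
  need <- c("expression.tsv", "neg_controls.tsv", "probes.tsv",
            "samples.tsv", "truth.tsv", "config.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing dataset file(s) in '", dir, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(simulation_config, cfg[names(cfg) %in%
                                            names(formals(simulation_config))])
  structure(
    list(
      expression = read_matrix_tsv(file.path(dir, "expression.tsv"), "probe_id"),
      neg_controls = read_matrix_tsv(file.path(dir, "neg_controls.tsv"),
                                     "control_id"),
      probes = readr::read_tsv(file.path(dir, "probes.tsv"), na = ".",
                               show_col_types = FALSE, progress = FALSE),
      samples = readr::read_tsv(file.path(dir, "samples.tsv"), na = ".",
                                show_col_types = FALSE, progress = FALSE),
      truth = readr::read_tsv(file.path(dir, "truth.tsv"), na = ".",
                              show_col_types = FALSE, progress = FALSE),
      config = config
    ),
    class = "ffpe_dataset"
  )
}
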