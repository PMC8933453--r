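# Plain-CSV interchange with a one-line schema header.  Every table the
# pipeline emits starts with a comment line `# tissueorigin <schema> v1`
# so files are self-describing and readers can refuse the wrong table.

.schema_version <- "v1"

schema_header <- function(schema) {
  sprintf("# tissueorigin %s %s", schema, .schema_version)
}

#' Read and write the pipeline's CSV tables
#'
#' All tables travel as plain CSV with a single comment header line
#' identifying the schema (`curves`, `truth`, `methylation`, `panels`,
#' `calls`) and its version, e.g. `# tissueorigin curves v1`.
#' `write_origin_table()`/`read_origin_table()` are the generic pair;
#' [write_cohort()] writes the three tables of a simulated cohort into a
#' directory in one call.
#'
#' @param data A data frame to write.
#' @param path File path.
#' @param schema Schema identifier string.
#' @return `read_origin_table()` returns a tibble;
#'   `write_origin_table()` invisibly returns `path`.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_origin_table(data.frame(a = 1:2), tmp, "demo")
#' read_origin_table(tmp, "demo")
#' @export
write_origin_table <- function(data, path, schema) {
  writeLines(schema_header(schema), path)
  readr::write_csv(as_tibble(data), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_origin_table
#' @export
read_origin_table <- function(path, schema = NULL) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# tissueorigin ")) {
    stop_input(sprintf("'%s' is not a tissueorigin table (missing schema header)",
                       path))
  }
  found <- strsplit(trimws(sub("^# tissueorigin", "", first)), "[ ]+")[[1]][1]
  if (!is.null(schema) && !identical(found, schema)) {
    stop_input(sprintf("'%s' holds schema '%s', expected '%s'",
                       path, found, schema))
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a simulated cohort to a directory
#'
#' Emits `curves.csv` (long raw-signal table), `truth.csv` (per-sample
#' ground truth) and `methylation.csv` under `dir`, each with its schema
#' header, plus `config.csv` recording every generator setting so the run
#' is reproducible from its outputs alone.
#'
#' @param cohort An `"origin_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "origin_cohort")) {
    stop_input("`cohort` must come from simulate_cohort()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    curves = file.path(dir, "curves.csv"),
    truth = file.path(dir, "truth.csv"),
    methylation = file.path(dir, "methylation.csv"),
    config = file.path(dir, "config.csv")
  )
  write_origin_table(cohort$curves, paths[["curves"]], "curves")
  write_origin_table(cohort$truth, paths[["truth"]], "truth")
  write_origin_table(cohort$methylation, paths[["methylation"]], "methylation")
  cfg <- cohort$config
  cfg_tbl <- tibble(
    setting = names(cfg),
    value = vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ";"),
                   character(1))
  )
  write_origin_table(cfg_tbl, paths[["config"]], "config")
  invisible(paths)
}
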