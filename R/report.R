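#' Write a pipeline report bundle
#'
#' Writes every supplied table as a TSV, a versioned summary JSON (class
#' medians, correlations, test results -- whatever the caller assembled), a
#' filter log recording gene counts at each filtering step, and a manifest
#' listing every file with its row count. All writers are deterministic:
#' rerunning the same pipeline with the same seed reproduces the report
#' byte-for-byte.
#'
#' @param dir Output directory. Must not exist unless `force = TRUE`.
#' @param tables Named list of data.frames; each becomes `<name>.tsv`.
#' @param summary Named list serialized to `summary.json`.
#' @param filter_log Optional data.frame (`step`, `n_genes`) describing the
#'   gene-count funnel of the run.
#' @param force Overwrite an existing directory (default `FALSE`).
#' @return Path of the manifest file, invisibly.
#' @export
write_report <- function(dir, tables = list(), summary = list(),
                         filter_log = NULL, force = FALSE) {
  if (dir.exists(dir)) {
    if (!force)
      stop("output directory exists: ", dir, " (use force = TRUE)")
  } else {
    dir.create(dir, recursive = TRUE)
  }
  manifest <- list()
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    tab <- as.data.frame(tables[[nm]])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[nm]] <- data.frame(name = nm, file = basename(path),
                                 rows = nrow(tab), cols = ncol(tab),
                                 stringsAsFactors = FALSE)
  }
  if (!is.null(filter_log)) {
    path <- file.path(dir, "filter_log.tsv")
    utils::write.table(filter_log, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[["filter_log"]] <- data.frame(
      name = "filter_log", file = "filter_log.tsv", rows = nrow(filter_log),
      cols = ncol(filter_log), stringsAsFactors = FALSE)
  }
  summary <- c(list(schema_version = "1.0"), summary)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest[["summary"]] <- data.frame(name = "summary",
                                      file = "summary.json", rows = NA,
                                      cols = NA, stringsAsFactors = FALSE)
  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
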