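#' Write sample results as CSV and JSON
#'
#' One record per sample lane, mirroring the layout of a screening report:
#' retention factor (2 decimals), AUC, concentration, mg per tablet and
#' verdict flags.
#'
#' @param result a `plate_result` (or list of `sample_result`s).
#' @param dir output directory (created if needed).
#' @param stem file stem, default "results".
#' @return Invisibly, the two paths written.
#' @export
write_results <- function(result, dir, stem = "results") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- if (inherits(result, "plate_result")) as.data.frame(result)
       else do.call(rbind, lapply(result, as.data.frame))
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  write.csv(d, csv, row.names = FALSE)
  jsonlite::write_json(d, json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, json))
}

#' Aggregate per-run result files into one report table
#'
#' Merges every `*.csv` result file under `dir` into a single table with
#' one row per sample and a `flagged` column marking samples whose verdict
#' is not "pass" (the report-table analogue of printing out-of-range cells
#' in italics).
#'
#' @param dir directory of result CSVs written by [write_results()].
#' @param out optional path for the merged CSV.
#' @return The merged data frame (invisibly when `out` is given).
#' @export
aggregate_report <- function(dir, out = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!is.null(out)) files <- setdiff(files, normalizePath(out, mustWork = FALSE))
  if (length(files) == 0L) {
    tlc_warn(sprintf("no result files under %s", dir),
             "tlc_empty_report_warning")
    return(invisible(data.frame()))
  }
  tabs <- lapply(files, function(f) {
    d <- read.csv(f)
    d$source <- basename(f)
    d
  })
  merged <- do.call(rbind, tabs)
  merged$flagged <- merged$verdict != "pass"
  merged <- merged[order(merged$source, merged$sample_id), , drop = FALSE]
  rownames(merged) <- NULL
  if (!is.null(out)) {
    write.csv(merged, out, row.names = FALSE)
    return(invisible(merged))
  }
  merged
}

#' Read/write a run configuration
#'
#' A run configuration merges the pixel-pipeline and quantitation
#' parameters with a standards registry path; it round-trips losslessly
#' through YAML.
#'
#' @param path YAML file.
#' @return `read_run_config`: a validated list with elements `pipeline`
#'   (a [pipeline_config]) and `quant` (a [quant_config]) plus any
#'   `standards` path.
#' @name run-config
NULL

#' @rdname run-config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    tlc_abort(sprintf("config file not found: %s", path),
              "tlc_config_error")
  raw <- yaml::read_yaml(path)
  pcfg <- do.call(pipeline_config, raw$pipeline %||% list())
  qcfg <- do.call(quant_config, raw$quant %||% list())
  if (!is.null(raw$standards) && !file.exists(raw$standards))
    tlc_abort(sprintf("standards registry not found: %s", raw$standards),
              "tlc_config_error")
  list(pipeline = pcfg, quant = qcfg, standards = raw$standards)
}

#' @rdname run-config
#' @param config list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    pipeline = unclass(config$pipeline),
    quant = unclass(config$quant),
    standards = config$standards), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny FNV-1a checksum of a deparsed object, for the per-stage log lines.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (bitwXor(h, b) * 16777619) %% 2^31
  sprintf("%08x", h)
}
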