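#' Write simulation outputs to a directory
#'
#' Writes the spike raster (`raster.csv`), the sampled continuous traces
#' (`traces.csv`), the outcome summary (`summary.json`) and a run manifest
#' (`manifest.json`: resolved configuration, seed, package version and
#' per-file checksums) sufficient to reproduce the run bit-exactly.
#'
#' @param result a [run_simulation()] result.
#' @param outdir output directory (created if missing).
#' @param write_counts also write the per-ms spike counts (`counts.csv`).
#' @return invisibly, the vector of written file paths.
#' @export
write_outputs <- function(result, outdir, write_counts = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ras <- result$raster
  if (is.null(ras))
    ras <- data.frame(neuron = integer(0), time_ms = integer(0),
                      cell_class = character(0))
  f <- file.path(outdir, "raster.csv")
  write.csv(ras, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "traces.csv")
  write.csv(result$traces, f, row.names = FALSE)
  files <- c(files, f)
  if (write_counts) {
    f <- file.path(outdir, "counts.csv")
    write.csv(as.data.frame(result$counts), f, row.names = FALSE)
    files <- c(files, f)
  }
  outcome <- tryCatch(simulation_outcome(result),
                      error = function(e) list(generated = NA,
                                               note = conditionMessage(e)))
  f <- file.path(outdir, "summary.json")
  jsonlite::write_json(outcome, f, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files <- c(files, f)
  manifest <- list(
    config = unclass_config(result$config),
    seed = result$config$seed,
    package_version = as.character(packageVersion("ictalnet")),
    checksums = as.list(tools::md5sum(files))
  )
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, f))
}

unclass_config <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Read back a raster written by [write_outputs()]
#'
#' @param path path to a `raster.csv`.
#' @return data.frame with `neuron`, `time_ms`, `cell_class`.
#' @export
read_raster <- function(path) {
  read.csv(path, colClasses = c(neuron = "integer", time_ms = "integer",
                                cell_class = "character"))
}
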