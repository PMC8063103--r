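#' Write a simulation result as delimited text plus a JSON sidecar
#'
#' Writes `<prefix>_traces.tsv` (time, voltage, sodium, mean SR calcium),
#' `<prefix>_linescan.tsv` (rows = domains, columns = time points, mM) and
#' `<prefix>_meta.json` (protocol and provenance).
#'
#' @param result a `simulation_result`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_simulation_result <- function(result, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traces <- data.frame(t = result$t)
  for (fld in c("V", "Na_i", "Ca_SR_mean"))
    if (!is.null(result[[fld]])) traces[[fld]] <- result[[fld]]
  utils::write.table(traces, file.path(dir, paste0(prefix, "_traces.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$Ca_cyto,
                     file.path(dir, paste0(prefix, "_linescan.tsv")),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- c(result$meta,
            list(protocol = unclass(result$protocol),
                 n_domains = nrow(result$Ca_cyto)))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, prefix))
}

#' Read a line-scan matrix from delimited text
#'
#' Expects rows = domains, columns = time points (the format written by
#' [write_simulation_result()]); any delimiter accepted by
#' [utils::read.table()] works.
#'
#' @param path file path.
#' @param sep field separator.
#' @export
read_linescan <- function(path, sep = "\t") {
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}
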