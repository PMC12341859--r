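#' Write a results table with provenance header
#'
#' Deterministic tab-separated output: `#`-prefixed `key=value` metadata
#' lines recording the run parameters, a column header, then one row per
#' locus with numbers printed to 12 significant digits (so a read-back
#' reproduces the values to printed precision).
#'
#' @param tab A data.frame (e.g. from [mle_table()]); may have zero rows.
#' @param path Output path.
#' @param params Named list/vector of run parameters for the header
#'   (e.g. Ne, u01, u10, grid specification).
#' @return Invisibly, `path`.
#' @export
write_results <- function(tab, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(v) {
                         paste(format(v, digits = 15, trim = TRUE,
                                      scientific = FALSE),
                               collapse = ",")
                       }, character(1L))), con)
  }
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab)) {
    cells <- vapply(seq_along(tab), function(j) {
      col <- tab[[j]]
      if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
    }, character(nrow(tab)))
    cells <- matrix(cells, nrow = nrow(tab))
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the table.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
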