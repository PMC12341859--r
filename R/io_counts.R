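#' Read a tab-separated allele-count table
#'
#' The count-table dialect is self-describing: optional `#`-prefixed comment
#' lines, then a header line `ID  t1  t1  t2  t2  ...` in which every
#' sampling time labels a consecutive pair of columns (haploid sample size,
#' then derived-allele count), then one row per locus.  All loci share the
#' header's sampling times.  This is the format written by
#' [write_count_table()], so simulator output round-trips exactly.
#'
#' @param path Path to the table.
#'
#' @return A list of [temporal_samples()], named by locus ID (empty list for
#'   a header-only file).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("count table has no header line")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 3L || hdr[1] != "ID") {
    stop("count-table header must be 'ID' followed by paired time columns")
  }
  tl <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(tl)) stop("non-numeric sampling time in count-table header")
  if (length(tl) %% 2 != 0) {
    stop("count-table header must pair each time's size and count columns")
  }
  K <- length(tl) / 2
  t_size <- tl[2 * seq_len(K) - 1]
  t_count <- tl[2 * seq_len(K)]
  if (any(t_size != t_count)) {
    stop("count-table header times must repeat in size/count pairs")
  }
  if (is.unsorted(t_size)) {
    stop("count-table sampling times are unsorted")
  }
  out <- list()
  for (r in seq_along(lines)[-1]) {
    f <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr)) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   lineno[r], length(hdr), length(f)))
    }
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric entry", lineno[r]))
    sizes <- v[2 * seq_len(K) - 1]
    counts <- v[2 * seq_len(K)]
    bad <- which(counts > sizes)
    if (length(bad)) {
      stop(sprintf("line %d: count %g exceeds size %g at time %g",
                   lineno[r], counts[bad[1]], sizes[bad[1]],
                   t_size[bad[1]]))
    }
    out[[f[1]]] <- temporal_samples(t_size, sizes, counts, id = f[1])
  }
  out
}

#' Write an allele-count table
#'
#' Writes [temporal_samples()] (or a [simulate_samples()] result) in the
#' dialect read by [read_count_table()], with optional `#`-prefixed
#' metadata lines.
#'
#' @param x A `sim_result` or a list of `temporal_samples` sharing times.
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key=value`
#'   header lines.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(x, path, meta = NULL) {
  if (inherits(x, "sim_result")) x <- as_temporal_samples(x)
  st <- stack_loci(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  hdr <- c("ID", as.character(rep(st$times, each = 2)))
  writeLines(paste(hdr, collapse = "\t"), con)
  K <- length(st$times)
  for (i in seq_len(nrow(st$counts))) {
    pair <- as.vector(rbind(st$sizes[i, ], st$counts[i, ]))
    writeLines(paste(c(st$ids[i], format(pair, trim = TRUE,
                                         scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-information table
#'
#' Tab-separated with a header; required columns `ID` (sample identifier,
#' unique) and `time` (sampling generation, analysis-forward); optional
#' column `ploidy` with values `diploid` or `pseudo-haploid`.
#'
#' @param path Path to the table.
#'
#' @return A data.frame with columns `ID`, `time`, and `ploidy` (NA when
#'   absent).
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("ID", "time") %in% names(df))) {
    stop("sample-information table must have columns 'ID' and 'time'")
  }
  if (anyDuplicated(df$ID)) stop("sample IDs must be unique")
  if (!is.numeric(df$time) || any(!is.finite(df$time))) {
    stop("sample times must be finite numbers")
  }
  df$time <- as.numeric(df$time)
  if (is.null(df$ploidy)) df$ploidy <- NA_character_
  bad <- !is.na(df$ploidy) & !df$ploidy %in% c("diploid", "pseudo-haploid")
  if (any(bad)) {
    stop("ploidy must be 'diploid' or 'pseudo-haploid' when given")
  }
  df[, c("ID", "time", "ploidy")]
}
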