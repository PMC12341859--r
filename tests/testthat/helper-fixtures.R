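# Fixtures built in code: random temporal samples and a small VCF writer.

random_loci <- function(n, times, size, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    temporal_samples(times, rep(size, length(times)),
                     sample(0:size, length(times), replace = TRUE),
                     id = paste0("locus", i))
  })
}

# minimal VCF v4.2 text file; gt is a loci x samples character matrix
write_test_vcf <- function(path, chrom, pos, id, ref, alt, gt) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(gt)), collapse = "\t")), con)
  for (i in seq_along(pos)) {
    writeLines(paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".",
                       "PASS", ".", "GT", gt[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

write_test_info <- function(path, ids, times, ploidy = NULL) {
  df <- data.frame(ID = ids, time = times)
  if (!is.null(ploidy)) df$ploidy <- ploidy
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
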