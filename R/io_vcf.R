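#' Read temporal allele counts from a VCF file
#'
#' Parses biallelic SNP records from a VCF (GT field required) and
#' aggregates per-sample genotypes into per-time (size, count) pairs using a
#' sample-information table.  The VCF ALT allele is taken as the focal
#' allele; no ancestral-allele polarization is attempted.
#'
#' Genotype interpretation: diploid GT (`0/0`, `0/1`, `1/1`) contributes
#' (size 2, count = number of ALT alleles); haploid GT (`0`, `1`) size 1;
#' missing (`./.` or `.`) size 0.  Samples listed in `force_hap` are
#' pseudo-haploid: `0/0` is one REF observation, `1/1` one ALT observation,
#' and a heterozygous GT is an error naming the sample and site.  Samples in
#' `force_dip` are always read as diploid.  Multi-allelic and non-SNP
#' records are skipped (a message reports how many).
#'
#' @param path Path to a VCF (v4.x) file; plain text or gzip.
#' @param info Sample information, a data.frame as from
#'   [read_sample_info()] or the path to one.
#' @param force_hap,force_dip Character vectors of sample IDs whose
#'   genotypes are forced pseudo-haploid / diploid; must be disjoint and
#'   present in the VCF.
#'
#' @return An object of class `locus_records`: list with `chrom`, `pos`,
#'   `id`, `ref`, `alt` (per-locus vectors), `times` (sorted unique sampling
#'   generations), `sizes` and `counts` (loci x times matrices), and
#'   `n_skipped`.
#' @export
read_vcf_counts <- function(path, info, force_hap = character(),
                            force_dip = character()) {
  if (is.character(info)) info <- read_sample_info(info)
  if (length(intersect(force_hap, force_dip))) {
    stop("force_hap and force_dip must be disjoint")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcf@gt
  samples <- colnames(gt)[-1]
  missing_force <- setdiff(c(force_hap, force_dip), samples)
  if (length(missing_force)) {
    stop("force-set sample(s) absent from the VCF: ",
         paste(missing_force, collapse = ", "))
  }
  unknown <- setdiff(samples, info$ID)
  if (length(unknown)) {
    stop("sample(s) in VCF but absent from the sample information: ",
         paste(unknown, collapse = ", "))
  }
  s_time <- info$time[match(samples, info$ID)]
  s_ploidy <- info$ploidy[match(samples, info$ID)]
  hap <- samples %in% force_hap |
    (!samples %in% force_dip & !is.na(s_ploidy) &
       s_ploidy == "pseudo-haploid")
  times <- sort(unique(s_time))
  t_idx <- match(s_time, times)

  is_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  }
  fix <- fix[is_snp, , drop = FALSE]
  gtm <- gt[is_snp, -1, drop = FALSE]
  # strip phasing and any trailing FORMAT subfields
  gtm[] <- sub(":.*$", "", gsub("|", "/", gtm, fixed = TRUE))

  L <- nrow(gtm)
  K <- length(times)
  sizes <- matrix(0, L, K)
  counts <- matrix(0, L, K)
  site_lab <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  for (j in seq_along(samples)) {
    g <- gtm[, j]
    k <- t_idx[j]
    alleles <- strsplit(g, "/", fixed = TRUE)
    n_all <- lengths(alleles)
    a1 <- vapply(alleles, function(a) if (length(a)) a[1] else ".",
                 character(1L))
    a2 <- vapply(alleles,
                 function(a) if (length(a) > 1) a[2] else NA_character_,
                 character(1L))
    obs1 <- a1 %in% c("0", "1")
    obs2 <- !is.na(a2) & a2 %in% c("0", "1")
    if (hap[j]) {
      het <- obs1 & obs2 & a1 != a2
      if (any(het)) {
        stop(sprintf(
          "heterozygous genotype for pseudo-haploid sample %s at %s",
          samples[j], site_lab[which(het)[1]]))
      }
      # one observation per individual, whether encoded as a homozygous
      # diploid GT, a haploid GT, or a half-missing GT
      n_obs <- as.numeric(obs1) + as.numeric(obs2)
      size <- as.numeric(n_obs >= 1)
      count <- ifelse(n_obs >= 1 &
                        ((obs1 & a1 == "1") | (obs2 & !is.na(a2) &
                                                 a2 == "1")), 1, 0)
    } else {
      size <- as.numeric(obs1) + as.numeric(obs2)
      count <- ifelse(obs1 & a1 == "1", 1, 0) +
        ifelse(obs2 & a2 == "1", 1, 0)
    }
    # partially missing diploid GT (e.g. "./1"): count only observed alleles
    sizes[, k] <- sizes[, k] + size
    counts[, k] <- counts[, k] + count
  }
  id <- unname(fix[, "ID"])
  id[is.na(id) | id == "."] <- site_lab[is.na(id) | id == "."]
  structure(list(chrom = unname(fix[, "CHROM"]),
                 pos = unname(as.integer(fix[, "POS"])),
                 id = id, ref = unname(fix[, "REF"]),
                 alt = unname(fix[, "ALT"]),
                 times = times, sizes = sizes, counts = counts,
                 n_skipped = n_skipped),
            class = "locus_records")
}

#' Filter loci by pooled minor-allele frequency and subset
#'
#' Keeps loci whose pooled frequency `f = sum(counts) / sum(sizes)`
#' satisfies `min(f, 1 - f) >= min_maf`, optionally intersected with a
#' requested subset of locus IDs or a genomic region; order is preserved.
#' Loci with zero pooled size are dropped with a warning.
#'
#' @param records A `locus_records` from [read_vcf_counts()].
#' @param min_maf Pooled minor-allele-frequency threshold in `[0, 0.5]`.
#' @param ids Optional character vector of locus IDs to keep.
#' @param region Optional region string `"chrom:from-to"` (1-based,
#'   inclusive).
#'
#' @return The filtered `locus_records`.
#' @export
filter_loci <- function(records, min_maf = 0, ids = NULL, region = NULL) {
  stopifnot(inherits(records, "locus_records"),
            min_maf >= 0, min_maf <= 0.5)
  pooled_n <- rowSums(records$sizes)
  keep <- pooled_n > 0
  if (any(!keep)) {
    warning(sum(!keep), " locus/loci with zero pooled size dropped")
  }
  f <- ifelse(pooled_n > 0, rowSums(records$counts) / pooled_n, NA)
  keep <- keep & pmin(f, 1 - f) >= min_maf
  if (!is.null(ids)) keep <- keep & records$id %in% ids
  if (!is.null(region)) {
    m <- regmatches(region,
                    regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("region must be of the form 'chrom:from-to'")
    keep <- keep & records$chrom == m[2] &
      records$pos >= as.integer(m[3]) & records$pos <= as.integer(m[4])
  }
  keep[is.na(keep)] <- FALSE
  structure(list(chrom = records$chrom[keep], pos = records$pos[keep],
                 id = records$id[keep], ref = records$ref[keep],
                 alt = records$alt[keep], times = records$times,
                 sizes = records$sizes[keep, , drop = FALSE],
                 counts = records$counts[keep, , drop = FALSE],
                 n_skipped = records$n_skipped),
            class = "locus_records")
}

#' @rdname read_vcf_counts
#' @param records A `locus_records` object.
#' @export
records_to_samples <- function(records) {
  stopifnot(inherits(records, "locus_records"))
  lapply(seq_along(records$id), function(i) {
    temporal_samples(records$times, records$sizes[i, ],
                     records$counts[i, ], id = records$id[i])
  })
}
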