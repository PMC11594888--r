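#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via `VariantAnnotation`) into a [geno_matrix()].
#' Only biallelic SNP records are kept; multiallelic and non-SNP records are
#' skipped with a message reporting how many. Genotypes `./.` (or `.`)
#' become missing. Per-sample supporting reads are taken from FORMAT `DP`,
#' falling back to the sum of `AD`, falling back to `NA`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(vcf) == 0) stop("VCF has zero samples: ", path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt)
  ref_len <- Biostrings::width(rr$REF)
  alt1 <- rep(NA_character_, length(rr))
  has1 <- n_alt == 1L
  alt1[has1] <- as.character(unlist(alt[has1]))
  is_snp <- has1 & ref_len == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T")
  n_multi <- sum(n_alt > 1L)
  n_nonsnp <- sum(!is_snp) - n_multi
  if (n_multi || n_nonsnp)
    message(sprintf("read_vcf: skipped %d multiallelic and %d non-SNP records",
                    n_multi, n_nonsnp))
  vcf <- vcf[is_snp, ]
  rr <- rr[is_snp]
  if (nrow(vcf) == 0) stop("no biallelic SNP records in ", path)

  gt <- VariantAnnotation::geno(vcf)$GT
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  calls <- t(apply(gt, 2, code))            # samples x variants
  colnames(calls) <- NULL

  dp <- NULL
  fmt <- VariantAnnotation::geno(vcf)
  if ("DP" %in% names(fmt)) {
    dp <- t(fmt$DP)
  } else if ("AD" %in% names(fmt)) {
    ad <- fmt$AD
    dp <- t(apply(ad, c(1, 2), function(x) sum(unlist(x))))
  }
  mean_dp <- if (is.null(dp)) rep(NA_real_, nrow(vcf)) else
    colMeans(dp, na.rm = TRUE)

  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt1[is_snp],
    qual = rr$QUAL,
    mean_dp = mean_dp,
    stringsAsFactors = FALSE)
  geno_matrix(calls, colnames(vcf), variants, dp = dp)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits an uncompressed VCF with QUAL and per-sample `GT:DP:AD` fields
#' (AD is reconstructed from the call and depth when a depth matrix is
#' present). Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  v <- g$variants
  n_sam <- length(g$samples)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popsweep",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(v)), function(j) {
    calls <- g$calls[, j]
    gt <- ifelse(is.na(calls), "./.", gt_str[calls + 1L])
    if (!is.null(g$dp)) {
      dp <- g$dp[, j]
      alt_reads <- ifelse(is.na(calls), 0L, as.integer(round(dp * calls / 2)))
      fld <- sprintf("%s:%d:%d,%d", gt, dp, dp - alt_reads, alt_reads)
    } else fld <- gt
    paste(c(v$chrom[j], sprintf("%d", as.integer(v$pos[j])), ".",
            v$ref[j], v$alt[j],
            format(v$qual[j], trim = TRUE), "PASS", ".",
            if (!is.null(g$dp)) "GT:DP:AD" else "GT", fld),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
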