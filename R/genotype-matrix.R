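#' Genotype matrix container
#'
#' Samples-by-variants container of diploid biallelic SNP calls coded
#' 0 (hom ref), 1 (het), 2 (hom alt) and `NA` (missing). Variants carry
#' chromosome, 1-based position, ref/alt allele, site quality and mean
#' per-sample supporting-read depth.
#'
#' @param calls integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of sample ids (row order of `calls`).
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `mean_dp` (one row per column of `calls`).
#' @param dp optional integer matrix of per-sample read depths, same
#'   dimensions as `calls`.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, samples, variants, dp = NULL) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(samples))
    stop("calls must have one row per sample")
  if (ncol(calls) != nrow(variants))
    stop("calls must have one column per variant")
  need <- c("chrom", "pos", "ref", "alt", "qual", "mean_dp")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants is missing columns: ", paste(miss, collapse = ", "))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  sp <- split(variants$pos, variants$chrom)
  if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1))))
    stop("variant positions must be strictly increasing within chromosome")
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  structure(
    list(samples = as.character(samples),
         variants = as.data.frame(variants, stringsAsFactors = FALSE),
         calls = calls, dp = dp),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%.2f%% missing)\n",
              length(x$samples), nrow(x$variants),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Subset a genotype matrix
#'
#' @param g a [geno_matrix()].
#' @param samples sample ids or logical/integer index over samples.
#' @param variants logical/integer index over variants.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, variants = NULL) {
  si <- seq_along(g$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$samples) else
      si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  vi <- seq_len(nrow(g$variants))
  if (!is.null(variants)) vi <- vi[variants]
  geno_matrix(g$calls[si, vi, drop = FALSE], g$samples[si],
              g$variants[vi, , drop = FALSE],
              dp = if (!is.null(g$dp)) g$dp[si, vi, drop = FALSE])
}

#' Alternate-allele frequencies
#'
#' Per-variant alt-allele frequency over a subset of samples,
#' `(het + 2 * hom alt) / (2 * non-missing calls)`; missing calls are
#' excluded from the denominator. Variants with no non-missing call in the
#' subset get `NA`.
#'
#' @param g a [geno_matrix()].
#' @param subset sample ids (default: all samples).
#' @return numeric vector of frequencies in `[0, 1]` (or `NA`).
#' @export
allele_frequencies <- function(g, subset = g$samples) {
  if (!length(subset)) stop("subset must be nonempty")
  i <- match(subset, g$samples)
  if (anyNA(i)) stop("unknown sample id(s) in subset")
  m <- g$calls[i, , drop = FALSE]
  colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
}

# internal: alt allele count and called-chromosome count per variant
.alt_counts <- function(calls) {
  list(alt = colSums(calls, na.rm = TRUE),
       nchr = 2L * colSums(!is.na(calls)))
}
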