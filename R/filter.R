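#' Quality-control filtering of SNPs
#'
#' Applies the standard resequencing QC chain to a [geno_matrix()], in this
#' fixed order: site quality, read support, minor-allele frequency,
#' missingness. A variant is attributed to the first rule it fails, so the
#' per-rule removal counts in the report sum to `n_input - n_pass`.
#'
#' "Read support >= 4" is interpreted as mean per-sample depth at the site
#' (the closest site-level analogue of a caller-level depth flag); set
#' `support_mode = "site"` to instead require total site depth >= the
#' threshold.
#'
#' @param g a [geno_matrix()].
#' @param min_quality minimum site QUAL (inclusive).
#' @param min_support minimum supporting-read depth (inclusive), see
#'   `support_mode`.
#' @param min_maf minimum minor-allele frequency over non-missing calls
#'   (inclusive).
#' @param max_missing maximum fraction of missing calls (inclusive).
#' @param support_mode `"mean"` (default, mean per-sample depth) or
#'   `"site"` (summed depth across samples).
#' @return list with elements `genotypes` (the filtered [geno_matrix()],
#'   order preserved) and `report` (a `filter_report`: `n_input`, `n_pass`,
#'   and removals per rule).
#' @export
filter_variants <- function(g, min_quality = 20, min_support = 4,
                            min_maf = 0.05, max_missing = 0.1,
                            support_mode = c("mean", "site")) {
  support_mode <- match.arg(support_mode)
  n <- nrow(g$variants)
  if (n == 0) stop("empty genotype matrix")

  qual_ok <- !is.na(g$variants$qual) & g$variants$qual >= min_quality
  support <- if (support_mode == "mean") g$variants$mean_dp else
    g$variants$mean_dp * length(g$samples)
  supp_ok <- is.na(support) | support >= min_support   # unknown depth passes
  af <- allele_frequencies(g)
  maf <- pmin(af, 1 - af)
  maf_ok <- !is.na(maf) & maf >= min_maf
  miss <- colMeans(is.na(g$calls))
  miss_ok <- miss <= max_missing

  fail_rule <- rep(NA_character_, n)
  fail_rule[!miss_ok] <- "missingness"
  fail_rule[!maf_ok] <- "maf"          # earlier rules overwrite later ones
  fail_rule[!supp_ok] <- "support"
  fail_rule[!qual_ok] <- "quality"
  keep <- is.na(fail_rule)

  report <- structure(list(
    n_input = n, n_pass = sum(keep),
    removed = c(quality = sum(fail_rule == "quality", na.rm = TRUE),
                support = sum(fail_rule == "support", na.rm = TRUE),
                maf = sum(fail_rule == "maf", na.rm = TRUE),
                missingness = sum(fail_rule == "missingness", na.rm = TRUE)),
    params = list(min_quality = min_quality, min_support = min_support,
                  min_maf = min_maf, max_missing = max_missing,
                  support_mode = support_mode)),
    class = "filter_report")
  if (!any(keep))
    warning("all variants removed by filtering")
  list(genotypes = subset_geno(g, variants = keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d pass\n", x$n_input, x$n_pass))
  for (r in names(x$removed))
    cat(sprintf("  removed by %-11s %d\n", paste0(r, ":"), x$removed[[r]]))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(rule = c("input", names(report$removed), "pass"),
                   n = c(report$n_input, unname(report$removed),
                         report$n_pass))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
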