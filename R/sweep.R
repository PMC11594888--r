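#' Sliding windows over chromosomes
#'
#' Windows start at 1, 1+step, ... and are truncated at the chromosome end;
#' a final partial window is kept if it contains at least 1 bp, so the
#' window count per chromosome is `floor((L - 1) / step) + 1`.
#'
#' @param chrom_lengths named vector, chromosome -> length in bp.
#' @param size window size in bp (default 100 kb).
#' @param step step between window starts (default 50 kb, i.e. 50% overlap);
#'   must satisfy `0 < step <= size`.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, size = 100000, step = 50000) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed size")
  parts <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    if (L < 1) return(NULL)
    starts <- seq(1, L, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
}

# per-site Weir & Cockerham (1984) variance components for two populations
# returns data.frame(a, b, c, valid)
.wc_site_components <- function(calls1, calls2) {
  n1 <- colSums(!is.na(calls1))
  n2 <- colSums(!is.na(calls2))
  p1 <- colSums(calls1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls2, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(calls1 == 1L, na.rm = TRUE)
  h2 <- colMeans(calls2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  valid <- n1 > 0 & n2 > 0 & nbar > 1
  data.frame(a = a, b = b, c = cc, valid = valid)
}

# assign site indices to (possibly overlapping) windows
.sites_in_windows <- function(variants, windows) {
  lapply(seq_len(nrow(windows)), function(w)
    which(variants$chrom == windows$chrom[w] &
            variants$pos >= windows$start[w] &
            variants$pos <= windows$end[w]))
}

#' Windowed Weir-Cockerham Fst
#'
#' Per-site variance components a, b, c of the Weir & Cockerham (1984)
#' estimator are accumulated within each window and combined as the
#' weighted (ratio of sums) estimate `sum(a) / sum(a + b + c)` - the
#' vcftools windowed convention. Windows without usable SNPs get `NA`.
#' Negative estimates are reported as computed.
#'
#' @param g a [geno_matrix()].
#' @param pops list of two character vectors of sample ids (the two
#'   populations), e.g. `list(TL = ..., SL = ...)`.
#' @param windows data.frame from [make_windows()].
#' @return `windows` with added columns `n_snps` and `fst`.
#' @export
window_fst <- function(g, pops, windows) {
  if (length(pops) != 2 || !all(lengths(pops) > 0))
    stop("pops must be a list of two nonempty sample sets")
  i1 <- match(pops[[1]], g$samples)
  i2 <- match(pops[[2]], g$samples)
  if (anyNA(i1) || anyNA(i2)) stop("unknown sample id(s) in pops")
  comp <- .wc_site_components(g$calls[i1, , drop = FALSE],
                              g$calls[i2, , drop = FALSE])
  idx <- .sites_in_windows(g$variants, windows)
  windows$n_snps <- vapply(idx, function(s) sum(comp$valid[s]), integer(1))
  windows$fst <- vapply(idx, function(s) {
    s <- s[comp$valid[s]]
    if (!length(s)) return(NA_real_)
    denom <- sum(comp$a[s] + comp$b[s] + comp$c[s])
    if (denom == 0) return(NA_real_)
    sum(comp$a[s]) / denom
  }, numeric(1))
  windows
}

#' Windowed nucleotide diversity
#'
#' Per-site pairwise diversity `pi = c_ref * c_alt / choose(n_chr, 2)` over
#' the non-missing chromosomes of the population, summed within each window
#' and divided by the window length in bp (monomorphic and uncovered
#' positions contribute 0, the vcftools windowed-pi convention).
#'
#' @param g a [geno_matrix()].
#' @param pop character vector of sample ids.
#' @param windows data.frame from [make_windows()].
#' @param col name of the output column (default `"pi"`).
#' @return `windows` with added columns `<col>` and `n_snps_<col>`.
#' @export
window_pi <- function(g, pop, windows, col = "pi") {
  if (!length(pop)) stop("pop must be nonempty")
  i <- match(pop, g$samples)
  if (anyNA(i)) stop("unknown sample id(s) in pop")
  calls <- g$calls[i, , drop = FALSE]
  nchr <- 2 * colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  site_pi <- ifelse(nchr >= 2,
                    alt * (nchr - alt) / (nchr * (nchr - 1) / 2), 0)
  idx <- .sites_in_windows(g$variants, windows)
  windows[[paste0("n_snps_", col)]] <-
    vapply(idx, function(s) sum(site_pi[s] > 0), integer(1))
  windows[[col]] <- vapply(seq_along(idx), function(w) {
    len <- windows$end[w] - windows$start[w] + 1
    sum(site_pi[idx[[w]]]) / len
  }, numeric(1))
  windows
}

#' Fst distribution bins
#'
#' Fractions of windows with defined Fst falling below 0.05, between 0.05
#' and 0.15 (inclusive), and above 0.15.
#'
#' @param fst numeric vector of window Fst values (NAs ignored), or a
#'   windows data.frame with an `fst` column.
#' @return named numeric vector `c(low, mid, high)` summing to 1.
#' @export
fst_bins <- function(fst) {
  if (is.data.frame(fst)) fst <- fst$fst
  fst <- fst[!is.na(fst)]
  if (!length(fst)) stop("no defined Fst values")
  c(low = mean(fst < 0.05),
    mid = mean(fst >= 0.05 & fst <= 0.15),
    high = mean(fst > 0.15))
}

#' Joint Fst / nucleotide-diversity sweep screen
#'
#' Selects windows in the top tail of both statistics: windowed Fst at or
#' above its `quantile`-th genome-wide percentile, and a diversity statistic
#' at or above its own. In `"ratio"` mode (default) the diversity statistic
#' is `log2(pi_other / pi_focal)`, so depleted diversity in the focal
#' population ranks high; `"raw"` mode ranks by low focal diversity
#' directly (`-pi_focal`). Zero diversity values are replaced by a
#' pseudocount (1% of the smallest nonzero value) in ratio mode. Windows
#' with fewer than `min_snps` usable SNPs are excluded from both the
#' percentile computation and selection.
#'
#' @param windows data.frame carrying `fst` plus two diversity columns.
#' @param focal_pop name of the focal population; its diversity column is
#'   `paste0("pi_", focal_pop)`.
#' @param other_pop name of the contrast population (default: inferred as
#'   the other `pi_` column).
#' @param quantile percentile for both thresholds (default 0.95); computed
#'   genome-wide with linear interpolation.
#' @param pi_mode `"ratio"` or `"raw"`.
#' @param min_snps minimum usable SNPs per window (default 5).
#' @return list of class `sweep_result`: `windows` (input plus `statistic`,
#'   `ranked`, `selected`), `thresholds` (fst and statistic cutoffs),
#'   `focal`, `quantile`, `pi_mode`.
#' @export
joint_select <- function(windows, focal_pop, other_pop = NULL,
                         quantile = 0.95, pi_mode = c("ratio", "raw"),
                         min_snps = 5) {
  pi_mode <- match.arg(pi_mode)
  pi_cols <- grep("^pi_", names(windows), value = TRUE)
  focal_col <- paste0("pi_", focal_pop)
  if (!focal_col %in% names(windows))
    stop("no diversity column ", focal_col)
  if (is.null(other_pop)) {
    other_col <- setdiff(pi_cols, focal_col)[1]
    if (is.na(other_col)) stop("cannot infer the contrast diversity column")
  } else other_col <- paste0("pi_", other_pop)

  ranked <- !is.na(windows$fst) & windows$n_snps >= min_snps
  if (sum(ranked) < 20)
    warning("fewer than 20 ranked windows; percentiles are unstable")
  pf <- windows[[focal_col]]
  po <- windows[[other_col]]
  if (pi_mode == "ratio") {
    nz <- c(pf[ranked], po[ranked])
    nz <- nz[nz > 0]
    if (!length(nz)) stop("all diversity values are zero")
    eps <- min(nz) * 0.01
    if (any(c(pf[ranked], po[ranked]) == 0))
      message("joint_select: zero diversity windows given pseudocount ",
              format(eps))
    statistic <- log2(pmax(po, eps) / pmax(pf, eps))
  } else {
    statistic <- -pf
  }
  fst_thr <- stats::quantile(windows$fst[ranked], quantile, names = FALSE)
  stat_thr <- stats::quantile(statistic[ranked], quantile, names = FALSE)
  selected <- ranked & windows$fst >= fst_thr & statistic >= stat_thr
  windows$statistic <- statistic
  windows$ranked <- ranked
  windows$selected <- selected
  structure(list(windows = windows,
                 thresholds = c(fst = fst_thr, statistic = stat_thr),
                 focal = focal_pop, quantile = quantile, pi_mode = pi_mode),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "sweep_result (focal %s, %s mode): %d/%d windows selected at q=%.2f\n",
    x$focal, x$pi_mode, sum(x$windows$selected), sum(x$windows$ranked),
    x$quantile))
  invisible(x)
}

#' Genes overlapping selected windows
#'
#' Lists, for each selected window, the genes whose transcript span overlaps
#' it by at least 1 bp, plus the deduplicated genome-wide union.
#'
#' @param windows data.frame with `chrom`, `start`, `end` (e.g. the selected
#'   rows of a [joint_select()] result).
#' @param models list of [gene_model()] objects.
#' @return list with `per_window` (list of character vectors, one per
#'   window row) and `union` (sorted unique gene ids).
#' @export
windows_to_genes <- function(windows, models) {
  if (!nrow(windows))
    return(list(per_window = list(), union = character()))
  span <- .model_ranges(models)$span
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  # windows and models may legitimately cover different chromosome sets
  h <- suppressWarnings(GenomicRanges::findOverlaps(win, span))
  per <- split(span$gene[S4Vectors::subjectHits(h)],
               factor(S4Vectors::queryHits(h), levels = seq_len(nrow(windows))))
  per <- lapply(per, function(x) sort(unique(x)))
  names(per) <- NULL
  list(per_window = per, union = sort(unique(unlist(per))))
}
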