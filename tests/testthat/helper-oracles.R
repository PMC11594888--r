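# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by brute force / literal formula
# transcription, separate from the package's implementation paths.

toy_geno <- function(calls, chrom = "chr1", pos = NULL, qual = 100,
                     mean_dp = 10, samples = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); p <- ncol(calls)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(p) * 100L
  geno_matrix(calls, samples,
              data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                         qual = qual, mean_dp = mean_dp,
                         stringsAsFactors = FALSE))
}

# literal per-site transcription of the Weir & Cockerham (1984) two-
# population variance components, scalar arithmetic, one site at a time
wc_oracle_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

wc_fst_oracle <- function(calls1, calls2) {
  comps <- sapply(seq_len(ncol(calls1)), function(j)
    wc_oracle_site(calls1[, j], calls2[, j]))
  sum(comps["a", ]) / sum(comps)
}

# nucleotide diversity by exhaustive enumeration of chromosome pairs
pi_oracle_site <- function(calls) {
  calls <- calls[!is.na(calls)]
  alleles <- unlist(lapply(calls, function(g) switch(g + 1,
                                                     c(0, 0), c(0, 1), c(1, 1))))
  n <- length(alleles)
  if (n < 2) return(0)
  diffs <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (alleles[i] != alleles[j]) diffs <- diffs + 1
  }
  diffs / pairs
}

# exact hypergeometric upper tail by combinatorial summation
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(n, i) * choose(N - n, K - i)) / choose(N, K)
}

# p-distance by double loop over samples and loci
pdist_oracle <- function(calls) {
  n <- nrow(calls)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (l in seq_len(ncol(calls))) {
      gi <- calls[i, l]; gj <- calls[j, l]
      if (is.na(gi) || is.na(gj)) next
      den <- den + 1
      if (gi == 1 || gj == 1) num <- num + 0.5  # any het involved
      else if (gi != gj) num <- num + 1
    }
    D[i, j] <- num / den
  }
  diag(D) <- 0
  D
}

# brute-force single-variant annotation category by direct interval scan
annotate_oracle <- function(chrom, pos, models) {
  cats <- character(0)
  up <- FALSE; dn <- FALSE
  for (m in models) {
    if (m$chrom != chrom) next
    if (pos >= m$start && pos <= m$end) {
      in_cds <- !is.null(m$cds) &&
        any(pos >= m$cds$start & pos <= m$cds$end)
      if (in_cds) { cats <- c(cats, "Exonic"); next }
      splice <- FALSE
      if (nrow(m$exons) > 1) {
        for (i in 1:(nrow(m$exons) - 1)) {
          is_ <- m$exons$end[i] + 1; ie <- m$exons$start[i + 1] - 1
          if (pos >= is_ && pos <= ie &&
              (pos - is_ < 2 || ie - pos < 2)) splice <- TRUE
        }
      }
      in_exon <- any(pos >= m$exons$start & pos <= m$exons$end)
      cats <- c(cats, if (splice) "Splicing" else "Intronic")
      if (in_exon && !splice) cats[length(cats)] <- "Intronic"
      next
    }
    before <- pos < m$start && pos >= m$start - 1000
    after <- pos > m$end && pos <= m$end + 1000
    if (m$strand == "+") {
      if (before) up <- TRUE
      if (after) dn <- TRUE
    } else {
      if (after) up <- TRUE
      if (before) dn <- TRUE
    }
  }
  if ("Exonic" %in% cats) return("Exonic")
  if ("Splicing" %in% cats) return("Splicing")
  if ("Intronic" %in% cats) return("Intronic")
  if (up && dn) return("Upstream/Downstream")
  if (up) return("Upstream")
  if (dn) return("Downstream")
  "Intergenic"
}

# expand an IUPAC motif to all concrete sequences
iupac_expand <- function(motif) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sets <- lapply(strsplit(motif, "")[[1]], function(ch) tab[[ch]])
  apply(do.call(expand.grid, rev(sets)), 1, function(x)
    paste(rev(x), collapse = ""))
}
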