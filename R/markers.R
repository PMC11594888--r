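#' Marker population-genetic statistics from genotype counts
#'
#' For a biallelic locus with genotype counts `(n_AA, n_Aa, n_aa)`:
#' allele frequency `p = (2 n_AA + n_Aa) / (2n)`, homozygosity
#' `Ho = p^2 + q^2`, heterozygosity `He = 1 - Ho`, effective allele number
#' `Ne = 1 / Ho`, polymorphism information content
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, and the Hardy-Weinberg chi-square
#' (no continuity correction, df = 1) of the observed genotype counts
#' against expectations from the sample allele frequencies.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @param locus optional locus label.
#' @return list of class `marker_stats`: `locus`, `n`, `p`, `q`,
#'   `genotype_freq`, `chi_square`, `chi_p`, `pic`, `ho`, `he`, `ne`.
#' @export
marker_stats <- function(counts, locus = "") {
  if (length(counts) != 3 || any(counts < 0))
    stop("counts must be (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n == 0) stop("total count must be positive")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  fs <- freq_stats(c(p, q))
  if (p == 0 || q == 0) {
    chi <- 0
  } else {
    expd <- n * c(p^2, 2 * p * q, q^2)
    chi <- sum((counts - expd)^2 / expd)
  }
  structure(list(locus = locus, n = n, p = unname(p), q = unname(q),
                 genotype_freq = unname(counts / n),
                 chi_square = unname(chi),
                 chi_p = pchisq(unname(chi), df = 1, lower.tail = FALSE),
                 pic = fs$pic, ho = fs$ho, he = fs$he, ne = fs$ne),
            class = "marker_stats")
}

#' @export
print.marker_stats <- function(x, ...) {
  cat(sprintf(
    "marker %s: p=%.3f q=%.3f PIC=%.3f Ho=%.3f He=%.3f Ne=%.3f HWE chi2=%.3f\n",
    if (nzchar(x$locus)) x$locus else "(unnamed)",
    x$p, x$q, x$pic, x$ho, x$he, x$ne, x$chi_square))
  invisible(x)
}

#' Marker statistics from allele frequencies
#'
#' PIC, homozygosity, heterozygosity and effective allele number from a
#' vector of allele frequencies (any number of alleles; must sum to 1).
#' The general PIC is `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies.
#' @return list with `pic`, `ho`, `he`, `ne`.
#' @export
freq_stats <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  ho <- sum(p^2)
  cross <- (sum(p^2)^2 - sum(p^4)) / 2     # sum over i<j of p_i^2 p_j^2
  list(pic = 1 - ho - 2 * cross, ho = ho, he = 1 - ho, ne = 1 / ho)
}

#' Leg length from body measurements
#'
#' Defined as body height minus chest depth, in cm.
#'
#' @param height,chest_depth measurements in cm (vectors allowed).
#' @return numeric vector of leg lengths.
#' @export
leg_length <- function(height, chest_depth) {
  if (any(height <= 0) || any(chest_depth <= 0))
    stop("measurements must be positive")
  out <- height - chest_depth
  if (any(out < 0)) warning("negative leg length(s) computed")
  out
}

# significance letters by greedy clique cover of the non-significance
# graph; groups ordered by ascending mean get letters a, b, c, ...
.sig_letters <- function(means, sig) {
  k <- length(means)
  if (k == 1) return("a")
  ord <- order(means)
  adj <- !sig                      # TRUE = not significantly different
  diag(adj) <- TRUE
  # all maximal cliques by brute force (k is tiny for genotype classes)
  subsets <- lapply(seq_len(2^k - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s)
    all(adj[s, s]), logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(i)
    !any(vapply(cl, function(o)
      length(o) > length(cl[[i]]) && all(cl[[i]] %in% o), logical(1))),
    logical(1))
  cl <- cl[maximal]
  # order cliques by the rank of their lowest-mean member
  cl <- cl[order(vapply(cl, function(s) min(match(s, ord)), numeric(1)))]
  letters_out <- rep("", k)
  for (i in seq_along(cl))
    letters_out[cl[[i]]] <- paste0(letters_out[cl[[i]]], letters[i])
  letters_out
}

#' Genotype-phenotype association at a single marker
#'
#' One-way fixed-effect ANOVA of a quantitative trait on genotype class
#' (`y = mu + G_k + e`), followed by all pairwise comparisons with two
#' procedures: LSD (pooled-variance t tests on the ANOVA residual df) and
#' Dunnett's T3 (Welch t statistics with a studentized-maximum-modulus
#' style correction, `p_adj = 1 - (2 P(T <= |t|) - 1)^C` over the `C`
#' comparisons). Group means are labelled with significance letters at
#' p < 0.05 (letters from the LSD p-values by default).
#'
#' Classes with a single observation are kept in the ANOVA and LSD (with a
#' warning) but excluded from T3, which needs a within-class variance.
#'
#' @param pheno numeric trait values (e.g. leg lengths).
#' @param genotypes factor or character of genotype labels, same length.
#' @param letter_method `"lsd"` or `"t3"`: which p-values drive the letters.
#' @param dispersion `"sd"` (default) or `"se"` for the group table.
#' @return list of class `assoc_table`: `groups` (data.frame: `genotype`,
#'   `n`, `mean`, `dispersion`, `label`), `pairwise` (data.frame with LSD
#'   and T3 statistics and p-values), `anova` (`F`, `df1`, `df2`, `p`).
#' @export
glm_association <- function(pheno, genotypes,
                            letter_method = c("lsd", "t3"),
                            dispersion = c("sd", "se")) {
  letter_method <- match.arg(letter_method)
  dispersion <- match.arg(dispersion)
  genotypes <- factor(genotypes)
  ok <- !is.na(pheno) & !is.na(genotypes)
  pheno <- pheno[ok]; genotypes <- droplevels(genotypes[ok])
  k <- nlevels(genotypes)
  if (k < 2) stop("need at least 2 genotype classes")
  n_g <- tabulate(genotypes)
  if (sum(n_g >= 2) < 2)
    stop("need at least 2 classes with at least 2 observations")
  if (any(n_g == 1))
    warning("class(es) with n = 1 excluded from Dunnett T3")

  means <- tapply(pheno, genotypes, mean)
  sds <- tapply(pheno, genotypes, sd)
  N <- length(pheno)
  fit <- lm(pheno ~ genotypes)
  an <- anova(fit)
  mse <- an$`Mean Sq`[2]
  df_res <- an$Df[2]

  pairs <- t(combn(k, 2))
  t3_eligible <- n_g >= 2
  C3 <- sum(t3_eligible[pairs[, 1]] & t3_eligible[pairs[, 2]])
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    diff <- means[i] - means[j]
    se_lsd <- sqrt(mse * (1 / n_g[i] + 1 / n_g[j]))
    t_lsd <- diff / se_lsd
    p_lsd <- 2 * pt(-abs(t_lsd), df_res)
    if (t3_eligible[i] && t3_eligible[j]) {
      vi <- sds[i]^2 / n_g[i]; vj <- sds[j]^2 / n_g[j]
      se_w <- sqrt(vi + vj)
      t_w <- diff / se_w
      df_w <- (vi + vj)^2 / (vi^2 / (n_g[i] - 1) + vj^2 / (n_g[j] - 1))
      p_t3 <- 1 - (2 * pt(abs(t_w), df_w) - 1)^C3
    } else {
      t_w <- NA_real_; df_w <- NA_real_; p_t3 <- NA_real_
    }
    data.frame(g1 = levels(genotypes)[i], g2 = levels(genotypes)[j],
               diff = unname(diff), lsd_t = unname(t_lsd),
               lsd_p = unname(p_lsd), t3_t = unname(t_w),
               t3_df = unname(df_w), t3_p = unname(p_t3),
               stringsAsFactors = FALSE)
  }))

  pmat <- matrix(1, k, k)
  pv <- if (letter_method == "lsd") pw$lsd_p else pw$t3_p
  for (r in seq_len(nrow(pairs))) {
    pmat[pairs[r, 1], pairs[r, 2]] <- pv[r]
    pmat[pairs[r, 2], pairs[r, 1]] <- pv[r]
  }
  sig <- !is.na(pmat) & pmat < 0.05
  labels <- .sig_letters(as.numeric(means), sig)

  disp <- if (dispersion == "sd") sds else sds / sqrt(n_g)
  groups <- data.frame(genotype = levels(genotypes), n = n_g,
                       mean = as.numeric(means),
                       dispersion = as.numeric(disp),
                       label = labels, stringsAsFactors = FALSE)
  structure(list(groups = groups, pairwise = pw,
                 anova = list(F = an$`F value`[1], df1 = an$Df[1],
                              df2 = df_res, p = an$`Pr(>F)`[1]),
                 dispersion = dispersion, letter_method = letter_method),
            class = "assoc_table")
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d)=%.3f, p=%.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %s (n=%d): %.3f +/- %.3f %s\n", g$genotype[i], g$n[i],
                g$mean[i], g$dispersion[i], g$label[i]))
  invisible(x)
}
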