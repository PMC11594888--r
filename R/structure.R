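#' Genotype p-distance between two calls
#'
#' Per-locus dissimilarity of two diploid genotypes at a biallelic site:
#' identical homozygotes are 0, opposite homozygotes 1, and any comparison
#' involving a heterozygote (including het vs het) is 0.5.
#'
#' @param geno_i,geno_j calls coded 0/1/2 (vectors allowed); no missing.
#' @return numeric in `{0, 0.5, 1}`.
#' @export
pair_distance <- function(geno_i, geno_j) {
  if (anyNA(geno_i) || anyNA(geno_j))
    stop("pair_distance requires non-missing calls")
  abs(geno_i - geno_j) / 2 + 0.5 * (geno_i == 1 & geno_j == 1)
}

#' Pairwise p-distance matrix
#'
#' Mean [pair_distance()] over the loci non-missing in both individuals
#' (pairwise deletion); the number of shared loci per pair is recorded.
#'
#' @param g a [geno_matrix()].
#' @return list of class `dist_matrix`: `samples`, `D` (symmetric matrix,
#'   zero diagonal), `L` (shared-locus counts).
#' @export
p_distance_matrix <- function(g) {
  n <- length(g$samples)
  if (n < 2) stop("need at least 2 samples")
  D <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  L <- matrix(ncol(g$calls), n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    gi <- g$calls[i, ]
    for (j in (i + 1):n) {
      gj <- g$calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      if (!any(ok))
        stop(sprintf("samples %s and %s share no called loci",
                     g$samples[i], g$samples[j]))
      d <- mean(pair_distance(gi[ok], gj[ok]))
      D[i, j] <- D[j, i] <- d
      L[i, j] <- L[j, i] <- sum(ok)
    }
  }
  structure(list(samples = g$samples, D = D, L = L), class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. Ties in the Q-matrix
#' minimum are broken by the lowest (row, column) index pair; negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sibling branch (so the pairwise path length is preserved), with a
#' message. The result is an unrooted `ape::phylo` tree.
#'
#' @param d a `dist_matrix` from [p_distance_matrix()], or a symmetric
#'   numeric matrix with dimnames.
#' @return an `ape` `phylo` object.
#' @export
nj_tree <- function(d) {
  D <- if (inherits(d, "dist_matrix")) d$D else as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-12)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels                      # newick fragment per active node
  clamped <- 0L
  clamp <- function(bi, bj) {
    # clamp negatives to 0, moving the length onto the sibling branch
    if (bi < 0) { bj <- bj + bi; bi <- 0; clamped <<- clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; clamped <<- clamped + 1L }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (length(nodes) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    b <- clamp(bi, bj)
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(b[1]),
                        nodes[j], fmt(b[2]))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- pmax(c(b1, b2, b3), 0)
  if (any(c(b1, b2, b3) < 0)) clamped <- clamped + sum(c(b1, b2, b3) < 0)
  if (clamped > 0)
    message(sprintf("nj_tree: clamped %d negative branch length(s)", clamped))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(bl[1]),
                 nodes[2], fmt(bl[2]), nodes[3], fmt(bl[3]))
  ape::read.tree(text = nwk)
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# each split is represented by the tip-label set NOT containing the first
# label of `all_labels`, sorted and pasted
.tree_splits <- function(tree, all_labels = sort(tree$tip.label)) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- all_labels[1]
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(all_labels, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  # drop trivial splits (whole set or single tips)
  keep <- lengths(parts) > 1 & lengths(parts) < length(labs)
  keys[keep]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples variant columns with replacement, rebuilds the p-distance NJ
#' tree per replicate, and reports, for each internal bipartition of the
#' full-data tree, the fraction of replicate trees containing it.
#'
#' @param g a [geno_matrix()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling RNG.
#' @return list with `tree` (the full-data `phylo`), `splits` (data.frame:
#'   `split` key, `support` fraction).
#' @export
bootstrap_support <- function(g, n_boot = 1000, seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  full <- nj_tree(p_distance_matrix(g))
  all_labels <- sort(g$samples)
  target <- unique(.tree_splits(full, all_labels))
  hits <- setNames(numeric(length(target)), target)
  set.seed(seed)
  p <- ncol(g$calls)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(p, p, replace = TRUE)
    gb <- suppressMessages(
      geno_matrix(g$calls[, cols, drop = FALSE], g$samples,
                  .renumber_variants(g$variants[cols, , drop = FALSE])))
    tb <- suppressMessages(nj_tree(p_distance_matrix(gb)))
    sp <- unique(.tree_splits(tb, all_labels))
    hit <- target %in% sp
    hits[hit] <- hits[hit] + 1
  }
  list(tree = full,
       splits = data.frame(split = target, support = unname(hits) / n_boot,
                           stringsAsFactors = FALSE))
}

# bootstrap columns break the strictly-increasing-position invariant;
# renumber on a synthetic chromosome
.renumber_variants <- function(v) {
  v$chrom <- "boot"
  v$pos <- seq_len(nrow(v))
  v
}

#' Standardize genotypes for PCA
#'
#' Per variant k with mean call `E(d_k)` over non-missing samples:
#' `M_ik = (d_ik - E(d_k)) / sqrt((E(d_k)/2) (1 - E(d_k)/2) * 2)`,
#' the usual allele-frequency-based (EIGENSTRAT-style) normalization.
#' Missing calls are imputed to the variant mean (0 after centering);
#' monomorphic variants are dropped.
#'
#' @param g a [geno_matrix()].
#' @return numeric matrix (samples x retained variants) with zero column
#'   means; attribute `kept` holds the retained variant indices.
#' @export
standardize_genotypes <- function(g) {
  calls <- g$calls
  E <- colMeans(calls, na.rm = TRUE)
  poly <- vapply(seq_len(ncol(calls)), function(j) {
    x <- calls[, j]; x <- x[!is.na(x)]
    length(unique(x)) > 1
  }, logical(1))
  if (!any(poly)) stop("all variants are monomorphic")
  calls <- calls[, poly, drop = FALSE]
  E <- E[poly]
  scale <- sqrt((E / 2) * (1 - E / 2) * 2)
  M <- sweep(calls, 2, E, `-`)
  M[is.na(M)] <- 0
  M <- sweep(M, 2, scale, `/`)
  attr(M, "kept") <- which(poly)
  M
}

#' PCA on standardized genotypes
#'
#' Eigendecomposition of the n x n sample covariance `X = M M' / S` where
#' `S` is the number of variants. Sample coordinates are the eigenvectors of
#' `X` (one column per component), the convention of genotype-PCA tools.
#'
#' @param M standardized matrix from [standardize_genotypes()].
#' @param n_components number of components to return (default 3; reduced
#'   with a warning when fewer samples are available).
#' @return list of class `pca_result`: `eigenvalues` (all, descending),
#'   `coords` (n x n_components), `var_explained` (fractions for the
#'   returned components).
#' @export
pca <- function(M, n_components = 3) {
  n <- nrow(M)
  S <- ncol(M)
  X <- tcrossprod(M) / S
  e <- eigen(X, symmetric = TRUE)
  k <- min(n_components, n - 1)
  if (k < n_components)
    warning("fewer samples than requested components; returning ", k)
  coords <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(M)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = e$values,
                 coords = coords,
                 var_explained = e$values[seq_len(k)] / sum(pmax(e$values, 0))),
            class = "pca_result")
}
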