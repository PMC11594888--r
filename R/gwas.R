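#' Centered genomic kinship matrix
#'
#' `K = W W' / p` where the columns of `W` are the per-variant mean-centered
#' genotype calls (missing calls imputed to the variant mean) and `p` is the
#' number of variants - the "centered relatedness matrix" convention of
#' mixed-model GWAS tools.
#'
#' @param g a [geno_matrix()].
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
kinship_centered <- function(g) {
  p <- ncol(g$calls)
  if (p == 0) stop("no variants")
  W <- g$calls
  mu <- colMeans(W, na.rm = TRUE)
  W <- sweep(W, 2, mu, `-`)
  W[is.na(W)] <- 0
  K <- tcrossprod(W) / p
  dimnames(K) <- list(g$samples, g$samples)
  K
}

# restricted log-likelihood of the variance-ratio parameter lambda
# (sigma_g^2 / sigma_e^2), given eigenvalues d of K and rotated y, X
.reml_loglik <- function(log_lambda, d, ys, Xs) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  n <- length(ys); q <- ncol(Xs)
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  beta <- solve(XtWX, XtWy)
  res <- ys - Xs %*% beta
  rss <- sum(w * res^2)
  -0.5 * ((n - q) * log(rss) + sum(log(lambda * d + 1)) +
            determinant(XtWX, logarithm = TRUE)$modulus[1])
}

#' Mixed-linear-model association scan
#'
#' Tests each SNP's additive effect on the phenotype under
#' `y = X alpha + x beta + u + e`, `u ~ (0, sigma_g^2 K)`,
#' `e ~ (0, sigma_e^2 I)`. The kinship matrix is eigendecomposed once and
#' the REML likelihood of `lambda = sigma_g^2 / sigma_e^2` is profiled
#' under the covariates-only null model (grid on `log lambda in [-5, 5] *
#' log(10)` plus local refinement); that `lambda` is then reused for every
#' SNP (the standard approximation at genome scale; set
#' `per_snp_lambda = TRUE` to re-optimize per SNP). Each SNP is tested by
#' generalized least squares with a Wald F statistic on 1 and n - q - 1
#' degrees of freedom, so with `K = I` (or `lambda -> 0`) results coincide
#' with per-SNP ordinary least squares.
#'
#' Missing genotypes are mean-imputed per SNP; monomorphic SNPs are skipped
#' with `NA` results.
#'
#' @param y numeric phenotype vector aligned to `g$samples`.
#' @param g a [geno_matrix()].
#' @param K kinship matrix from [kinship_centered()] (sample order must
#'   match `g`).
#' @param covariates optional numeric matrix of extra covariate columns
#'   (an intercept is always included), e.g. top PCs for structure
#'   correction.
#' @param per_snp_lambda re-optimize the variance ratio for every SNP
#'   (slower; default `FALSE`).
#' @return list of class `gwas_result`: `assoc` (data.frame: `chrom`,
#'   `pos`, `beta`, `se`, `stat`, `p`), `lambda` (variance ratio at the
#'   null optimum), `lambda_gc` (genomic-control inflation factor),
#'   `reml` (profile grid, for diagnostics), `n`, `n_tests`.
#' @export
mlm_associate <- function(y, g, K, covariates = NULL,
                          per_snp_lambda = FALSE) {
  n <- length(y)
  if (n != length(g$samples)) stop("y must align with g$samples")
  if (sd(y) == 0) stop("constant phenotype")
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")

  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y)
  X0s <- Ut %*% X0

  grid <- seq(-5, 5, length.out = 81) * log(10)
  ll <- vapply(grid, .reml_loglik, numeric(1), d = d, ys = ys, Xs = X0s)
  i0 <- which.max(ll)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(.reml_loglik, c(lo, hi), d = d, ys = ys, Xs = X0s,
                  maximum = TRUE, tol = 1e-8)
  lambda <- if (opt$objective >= ll[i0]) exp(opt$maximum) else exp(grid[i0])

  G <- g$calls
  mu <- colMeans(G, na.rm = TRUE)
  poly <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]; x <- x[!is.na(x)]
    length(unique(x)) > 1
  }, logical(1))
  G <- sweep(G, 2, mu, `-`)
  G[is.na(G)] <- 0
  Gs <- Ut %*% G

  fit_at <- function(lam, cols = seq_len(ncol(Gs))) {
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    yw <- ys * sw
    Xw <- X0s * sw
    Gw <- Gs[, cols, drop = FALSE] * sw
    # Frisch-Waugh: residualize on the null design
    qr0 <- qr(Xw)
    yr <- qr.resid(qr0, yw)
    Gr <- qr.resid(qr0, Gw)
    sxx <- colSums(Gr^2)
    sxy <- colSums(Gr * yr)
    beta <- sxy / sxx
    df <- n - ncol(Xw) - 1
    rss <- sum(yr^2) - beta * sxy
    sigma2 <- rss / df
    se <- sqrt(sigma2 / sxx)
    stat <- (beta / se)^2
    list(beta = beta, se = se, stat = stat,
         p = pf(stat, 1, df, lower.tail = FALSE))
  }

  if (per_snp_lambda) {
    res <- lapply(which(poly), function(j) {
      Xj <- cbind(X0s, Gs[, j])
      llj <- vapply(grid, .reml_loglik, numeric(1), d = d, ys = ys, Xs = Xj)
      ij <- which.max(llj)
      oj <- optimize(.reml_loglik,
                     c(grid[max(1, ij - 1)], grid[min(length(grid), ij + 1)]),
                     d = d, ys = ys, Xs = Xj, maximum = TRUE, tol = 1e-8)
      fit_at(exp(oj$maximum), cols = j)
    })
    take <- function(f) vapply(res, function(r) r[[f]][1], numeric(1))
    out <- data.frame(beta = NA_real_, se = NA_real_, stat = NA_real_,
                      p = NA_real_)[rep(1, ncol(g$calls)), ]
    out$beta[poly] <- take("beta"); out$se[poly] <- take("se")
    out$stat[poly] <- take("stat"); out$p[poly] <- take("p")
  } else {
    f <- fit_at(lambda)
    out <- data.frame(beta = f$beta, se = f$se, stat = f$stat, p = f$p)
    out[!poly, ] <- NA_real_
  }
  assoc <- cbind(g$variants[c("chrom", "pos")], out)
  rownames(assoc) <- NULL
  pvals <- assoc$p[!is.na(assoc$p)]
  structure(list(assoc = assoc, lambda = lambda,
                 lambda_gc = qq_lambda(pvals)$lambda,
                 reml = data.frame(log_lambda = grid, loglik = ll),
                 n = n, n_tests = sum(poly)),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf(
    "gwas_result: %d samples, %d SNPs tested, lambda=%.3g, lambda_GC=%.3f\n",
    x$n, x$n_tests, x$lambda, x$lambda_gc))
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of SNPs tested.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (any(n_tests < 1)) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Genomic-control lambda and Q-Q table
#'
#' `lambda = median(chi^2_1 quantiles of the p-values) / 0.4549` (the
#' chi-square(1) median), plus sorted observed/expected -log10 p pairs for
#' Q-Q plotting.
#'
#' @param p numeric vector of p-values.
#' @return list with `lambda` and `table` (data.frame: `expected`,
#'   `observed`, both -log10 p).
#' @export
qq_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no valid p-values")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
  obs <- sort(p)
  exp_p <- ppoints(length(p))
  list(lambda = lambda,
       table = data.frame(expected = -log10(exp_p),
                          observed = -log10(obs)))
}
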