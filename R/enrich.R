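#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, n, K)`: drawing `K` genes (the selection) from a
#' universe of `N` of which `n` belong to the term, what is the chance of
#' `k` or more hits?
#'
#' @param k observed hits (selected genes in the term).
#' @param K selection size.
#' @param n term size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Read a GMT term-set file
#'
#' One term per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (term id -> member genes), with
#'   a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  desc <- vapply(parts, `[`, character(1), 2)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(desc, ids)
  sets
}

#' Term enrichment table
#'
#' Hypergeometric overrepresentation of a selected gene list against
#' user-supplied term sets. Term membership is intersected with the
#' universe; terms with no selected member are omitted. Raw p-values are
#' primary (flagged at p < 0.05); a Benjamini-Hochberg column is added when
#' `bh = TRUE` (recommended when many terms are tested).
#'
#' @param selected character vector of selected gene ids (must all be in
#'   the universe).
#' @param term_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all testable genes; defaults to the
#'   union of all term-set members.
#' @param bh add a BH-adjusted p column.
#' @return data.frame with `term`, `k`, `K`, `n`, `N`, `p`, `significant`
#'   (raw p < 0.05) and optionally `p_bh`, sorted by `p`.
#' @export
enrich_table <- function(selected, term_sets, universe = NULL, bh = FALSE) {
  if (is.null(universe)) universe <- unique(unlist(term_sets))
  if (!length(universe)) stop("universe is empty")
  selected <- unique(selected)
  bad <- setdiff(selected, universe)
  if (length(bad))
    stop("selected gene(s) not in universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ...")
  N <- length(universe)
  K <- length(selected)
  rows <- lapply(names(term_sets), function(id) {
    members <- intersect(term_sets[[id]], universe)
    n <- length(members)
    k <- length(intersect(selected, members))
    if (k < 1) return(NULL)
    data.frame(term = id, k = k, K = K, n = n, N = N,
               p = hypergeom_test(k, K, n, N), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  if (bh) out$p_bh <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
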