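#' Stranded gene model with exon and CDS structure
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with `start`, `end` (1-based inclusive), sorted,
#'   non-overlapping.
#' @param cds data.frame with `start`, `end`; must lie within exons. May be
#'   empty for a non-coding model.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$start), , drop = FALSE]
    inside <- vapply(seq_len(nrow(cds)), function(i)
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end),
      logical(1))
    if (!all(inside)) stop("CDS intervals must lie within exons")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons$start), end = max(exons$end),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), %d exons, %d CDS segments\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), if (is.null(x$cds)) 0L else nrow(x$cds)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' One gene / mRNA / exon / CDS block per model, with CDS phase computed in
#' transcript orientation.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gid <- m$gene_id
    tid <- paste0(gid, ".t1")
    row <- function(type, start, end, attrs, phase = ".")
      paste(m$chrom, "popsweep", type, start, end, ".", m$strand, phase,
            attrs, sep = "\t")
    lines <- c(lines,
               row("gene", m$start, m$end, sprintf("ID=%s", gid)),
               row("mRNA", m$start, m$end,
                   sprintf("ID=%s;Parent=%s", tid, gid)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, row("exon", m$exons$start[i], m$exons$end[i],
                            sprintf("Parent=%s", tid)))
    if (!is.null(m$cds) && nrow(m$cds)) {
      cds <- m$cds
      ord <- if (m$strand == "+") order(cds$start) else -order(cds$start)
      cds <- cds[if (m$strand == "+") order(cds$start) else
        rev(order(cds$start)), , drop = FALSE]
      len <- cds$end - cds$start + 1L
      phase <- (3L - (cumsum(c(0L, len[-length(len)])) %% 3L)) %% 3L
      for (i in seq_len(nrow(cds)))
        lines <- c(lines, row("CDS", cds$start[i], cds$end[i],
                              sprintf("Parent=%s", tid), phase[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS features (via `rtracklayer`) into a list
#' of [gene_model()] objects, one per gene (exons and CDS pooled across
#' transcripts of the same gene).
#'
#' @param path path to a GFF3 file.
#' @return list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  tx <- df[df$type == "mRNA", , drop = FALSE]
  parent_of <- function(d) vapply(d$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  tx_gene <- setNames(parent_of(tx), tx$ID)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tids <- names(tx_gene)[tx_gene == gid]
    sub <- df[df$type %in% c("exon", "CDS") & parent_of(df) %in% tids, ,
              drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end")]
    cd <- sub[sub$type == "CDS", c("start", "end")]
    ex <- unique(ex[order(ex$start), , drop = FALSE])
    cd <- unique(cd[order(cd$start), , drop = FALSE])
    out[[i]] <- gene_model(gid, as.character(genes$seqnames[i]),
                           as.character(genes$strand[i]),
                           exons = ex, cds = if (nrow(cd)) cd else NULL)
  }
  out
}

# internal: flatten a list of gene models into per-feature GRanges
.model_ranges <- function(models) {
  gid <- vapply(models, `[[`, character(1), "gene_id")
  chrom <- vapply(models, `[[`, character(1), "chrom")
  strand <- vapply(models, `[[`, character(1), "strand")
  span <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(vapply(models, `[[`, numeric(1), "start"),
                            vapply(models, `[[`, numeric(1), "end")),
    gene = gid, strand_chr = strand)

  per_gene <- function(get) {
    parts <- lapply(seq_along(models), function(i) {
      d <- get(models[[i]])
      if (is.null(d) || !nrow(d)) return(NULL)
      GenomicRanges::GRanges(chrom[i], IRanges::IRanges(d$start, d$end),
                             gene = gid[i])
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(GenomicRanges::GRanges())
    # models legitimately span different chromosome sets
    suppressWarnings(do.call(c, parts))
  }
  exons <- per_gene(function(m) m$exons)
  cds <- per_gene(function(m) m$cds)

  # splice windows: first and last 2 bp of every intron
  splice_parts <- lapply(seq_along(models), function(i) {
    ex <- models[[i]]$exons
    if (nrow(ex) < 2) return(NULL)
    istart <- ex$end[-nrow(ex)] + 1L
    iend <- ex$start[-1] - 1L
    ok <- iend >= istart
    istart <- istart[ok]; iend <- iend[ok]
    if (!length(istart)) return(NULL)
    s <- c(istart, pmax(istart, iend - 1L))
    e <- c(pmin(iend, istart + 1L), iend)
    GenomicRanges::GRanges(chrom[i], IRanges::IRanges(s, e), gene = gid[i])
  })
  splice_parts <- splice_parts[!vapply(splice_parts, is.null, logical(1))]
  splice <- if (length(splice_parts)) do.call(c, splice_parts) else
    GenomicRanges::GRanges()

  # strand-aware 1 kb flanks beyond the transcript span
  up_start <- ifelse(strand == "+",
                     pmax(1, GenomicRanges::start(span) - 1000L),
                     GenomicRanges::end(span) + 1L)
  up_end <- ifelse(strand == "+", GenomicRanges::start(span) - 1L,
                   GenomicRanges::end(span) + 1000L)
  dn_start <- ifelse(strand == "+", GenomicRanges::end(span) + 1L,
                     pmax(1, GenomicRanges::start(span) - 1000L))
  dn_end <- ifelse(strand == "+", GenomicRanges::end(span) + 1000L,
                   GenomicRanges::start(span) - 1L)
  ok_up <- up_end >= up_start
  ok_dn <- dn_end >= dn_start
  upstream <- GenomicRanges::GRanges(chrom[ok_up],
    IRanges::IRanges(up_start[ok_up], up_end[ok_up]), gene = gid[ok_up])
  downstream <- GenomicRanges::GRanges(chrom[ok_dn],
    IRanges::IRanges(dn_start[ok_dn], dn_end[ok_dn]), gene = gid[ok_dn])

  list(span = span, exons = exons, cds = cds, splice = splice,
       upstream = upstream, downstream = downstream)
}
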