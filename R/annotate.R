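#' Functional classification of SNPs against gene models
#'
#' Assigns each variant exactly one category with the precedence
#' Exonic > Splicing > Intronic > Upstream/Downstream (both at once, for
#' different genes) > Upstream > Downstream > Intergenic, the mutually
#' exclusive scheme used by standard annotators:
#'
#' * Exonic: overlapping a coding exon (CDS); sub-classified by
#'   [coding_consequence()] into Synonymous / Non-synonymous / Stop gain /
#'   Stop loss.
#' * Splicing: intronic, within 2 bp of an exon/intron boundary.
#' * Intronic: within the transcript span but not exonic.
#' * Upstream / Downstream: within a strand-aware 1 kb flank beyond the
#'   transcript span; a variant upstream of one gene and downstream of
#'   another is "Upstream/Downstream".
#' * Intergenic: none of the above.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (e.g.
#'   `g$variants` of a [geno_matrix()]).
#' @param models list of [gene_model()] objects.
#' @param reference named `DNAStringSet` (one sequence per chromosome);
#'   required for exonic sub-classification and checked against `ref`.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `category`, `exonic` (subcategory or `"none"`), `genes`
#'   (comma-separated affected gene ids, `""` for intergenic).
#' @export
classify_variants <- function(variants, models, reference = NULL) {
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  fr <- .model_ranges(models)
  n <- length(v)

  hit_genes <- function(subject) {
    h <- suppressWarnings(GenomicRanges::findOverlaps(v, subject))
    split(subject$gene[S4Vectors::subjectHits(h)],
          factor(S4Vectors::queryHits(h), levels = seq_len(n)))
  }

  cds_g <- hit_genes(fr$cds)
  splice_g <- hit_genes(fr$splice)
  span_g <- hit_genes(fr$span)
  up_g <- hit_genes(fr$upstream)
  dn_g <- hit_genes(fr$downstream)

  has <- function(lst) lengths(lst) > 0
  category <- rep("Intergenic", n)
  genes <- rep("", n)
  pick <- function(cond, label, glist) {
    sel <- cond & category == "Intergenic"
    category[sel] <<- label
    genes[sel] <<- vapply(glist[sel], function(x)
      paste(sort(unique(x)), collapse = ","), character(1))
  }
  pick(has(cds_g), "Exonic", cds_g)
  pick(has(splice_g), "Splicing", splice_g)
  pick(has(span_g), "Intronic", span_g)
  both <- has(up_g) & has(dn_g)
  pick(both, "Upstream/Downstream",
       mapply(c, up_g, dn_g, SIMPLIFY = FALSE))
  pick(has(up_g), "Upstream", up_g)
  pick(has(dn_g), "Downstream", dn_g)

  exonic <- rep("none", n)
  if (any(category == "Exonic")) {
    if (is.null(reference))
      stop("reference is required to sub-classify exonic variants")
    model_of <- setNames(models,
                         vapply(models, `[[`, character(1), "gene_id"))
    for (i in which(category == "Exonic")) {
      gs <- sort(unique(cds_g[[i]]))
      cons <- vapply(gs, function(gid)
        coding_consequence(variants[i, ], model_of[[gid]], reference),
        character(1))
      # most severe across transcripts/genes
      sev <- c("Stop gain" = 1, "Stop loss" = 2, "Non-synonymous" = 3,
               "Synonymous" = 4)
      exonic[i] <- cons[which.min(sev[cons])]
    }
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             category = category, exonic = exonic, genes = genes,
             stringsAsFactors = FALSE)
}

#' Classify a single variant
#'
#' Convenience wrapper around [classify_variants()] for one site.
#'
#' @param chrom,pos,ref,alt the variant.
#' @inheritParams classify_variants
#' @return one-row data.frame, see [classify_variants()].
#' @export
classify_variant <- function(chrom, pos, ref, alt, models,
                             reference = NULL) {
  classify_variants(data.frame(chrom = chrom, pos = pos, ref = ref,
                               alt = alt, stringsAsFactors = FALSE),
                    models, reference)
}

#' Coding consequence of a SNP inside a CDS
#'
#' Rebuilds the affected codon from the CDS in transcript orientation
#' (reverse-complemented on the minus strand), substitutes the alt allele
#' and translates both codons under the standard genetic code. Stop gain /
#' loss take precedence over the synonymous / non-synonymous distinction.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param model a [gene_model()] whose CDS contains the variant.
#' @param reference named `DNAStringSet`.
#' @return one of `"Synonymous"`, `"Non-synonymous"`, `"Stop gain"`,
#'   `"Stop loss"`.
#' @export
coding_consequence <- function(variant, model, reference) {
  chrom_seq <- reference[[variant$chrom]]
  if (is.null(chrom_seq)) stop("no reference sequence for ", variant$chrom)
  ref_base <- as.character(Biostrings::subseq(chrom_seq, variant$pos,
                                              variant$pos))
  if (ref_base != variant$ref)
    stop(sprintf("reference mismatch at %s:%d (reference %s, variant ref %s)",
                 variant$chrom, variant$pos, ref_base, variant$ref))
  cds <- model$cds[order(model$cds$start), , drop = FALSE]
  if (!any(variant$pos >= cds$start & variant$pos <= cds$end))
    stop("variant not inside the CDS of ", model$gene_id)

  # genomic CDS positions in transcript order
  gpos <- unlist(lapply(seq_len(nrow(cds)),
                        function(i) cds$start[i]:cds$end[i]))
  seq <- paste(vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(chrom_seq, cds$start[i], cds$end[i])),
    character(1)), collapse = "")
  if (model$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    gpos <- rev(gpos)
  }
  if (nchar(seq) %% 3 != 0)
    warning(sprintf("CDS length of %s not divisible by 3; classifying by %s",
                    model$gene_id, "the available codon"))
  tpos <- match(variant$pos, gpos)
  alt_base <- if (model$strand == "-")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(variant$alt))) else variant$alt
  codon_i <- (tpos - 1) %/% 3
  cstart <- codon_i * 3 + 1
  if (cstart + 2 > nchar(seq))
    return("Synonymous")   # trailing partial codon: no interpretable change
  ref_codon <- substr(seq, cstart, cstart + 2)
  alt_codon <- ref_codon
  substr(alt_codon, tpos - cstart + 1, tpos - cstart + 1) <- alt_base
  aa <- function(cod) Biostrings::GENETIC_CODE[[cod]]
  ref_aa <- aa(ref_codon); alt_aa <- aa(alt_codon)
  if (ref_aa != "*" && alt_aa == "*") return("Stop gain")
  if (ref_aa == "*" && alt_aa != "*") return("Stop loss")
  if (ref_aa == alt_aa) "Synonymous" else "Non-synonymous"
}

#' Summarize annotation categories
#'
#' Tabulates category (and exonic subcategory) counts and percentages of an
#' explicitly supplied total. The denominator is a parameter rather than the
#' table sum because published totals routinely include records outside the
#' printed component rows.
#'
#' @param annotations data.frame from [classify_variants()], or a named
#'   vector / data.frame of pre-computed counts (`category`, `count`).
#' @param total denominator for percentages; defaults to the number of
#'   annotated variants.
#' @return data.frame with `category`, `count`, `percent` (2 d.p.).
#' @export
summarize_annotations <- function(annotations, total = NULL) {
  if (is.data.frame(annotations) && "count" %in% names(annotations)) {
    counts <- setNames(annotations$count, annotations$category)
  } else if (!is.data.frame(annotations) && !is.null(names(annotations))) {
    counts <- annotations
  } else {
    cat_lab <- ifelse(annotations$category == "Exonic",
                      paste0("Exonic:", annotations$exonic),
                      annotations$category)
    counts <- table(cat_lab)
    counts <- setNames(as.integer(counts), names(counts))
  }
  if (is.null(total)) total <- sum(counts)
  if (total <= 0) stop("total must be positive")
  if (total < sum(counts))
    stop("total is smaller than the number of annotated variants")
  data.frame(category = names(counts),
             count = as.integer(counts),
             percent = round(100 * as.numeric(counts) / total, 2),
             stringsAsFactors = FALSE)
}
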