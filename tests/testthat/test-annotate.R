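# A hand-built 12 kb chromosome with four genes:
#   geneA (+): exons/CDS 2001-2300 and 3001-3300, planted codons at the
#              CDS start and end for consequence tests
#   geneB (-): exon/CDS 8001-8300, genomic CAT at 8298-8300 = ATG start
#   geneC (+): non-coding exon 5001-6000
#   geneD (+): non-coding exon 6501-7000 (gap C..D = 500 bp, so the gap is
#              both downstream of C and upstream of D)
make_annot_fixture <- function() {
  base <- rep("A", 12000)
  base[2001:2003] <- c("G", "C", "T")   # GCT = Ala
  base[2004:2006] <- c("T", "G", "G")   # TGG = Trp
  base[3298:3300] <- c("T", "A", "A")   # TAA = stop
  base[8298:8300] <- c("C", "A", "T")   # revcomp ATG on - strand
  ref <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(ref) <- "chrT"
  models <- list(
    gene_model("geneA", "chrT", "+",
               exons = data.frame(start = c(2001, 3001),
                                  end = c(2300, 3300)),
               cds = data.frame(start = c(2001, 3001),
                                end = c(2300, 3300))),
    gene_model("geneB", "chrT", "-",
               exons = data.frame(start = 8001, end = 8300),
               cds = data.frame(start = 8001, end = 8300)),
    gene_model("geneC", "chrT", "+",
               exons = data.frame(start = 5001, end = 6000)),
    gene_model("geneD", "chrT", "+",
               exons = data.frame(start = 6501, end = 7000)))
  list(ref = ref, models = models)
}

test_that("category precedence and flank logic match the scheme", {
  fx <- make_annot_fixture()
  cat_at <- function(pos, ref_allele = "A", alt = "C")
    classify_variant("chrT", pos, ref_allele, alt, fx$models,
                     fx$ref)$category
  expect_equal(cat_at(1501), "Upstream")          # 500 bp 5' of geneA
  expect_equal(cat_at(2302), "Splicing")          # 2 bp into the intron
  expect_equal(cat_at(2500), "Intronic")
  expect_equal(cat_at(2999), "Splicing")          # 2 bp before next exon
  expect_equal(cat_at(2100), "Exonic")
  expect_equal(cat_at(6200), "Upstream/Downstream")  # between geneC and D
  expect_equal(cat_at(3500), "Downstream")        # 200 bp 3' of geneA
  expect_equal(cat_at(8500), "Upstream")          # 5' flank of - strand geneB
  expect_equal(cat_at(11500), "Intergenic")
})

test_that("coding consequences follow the genetic code on both strands", {
  fx <- make_annot_fixture()
  sub_at <- function(pos, ref_allele, alt)
    classify_variant("chrT", pos, ref_allele, alt, fx$models, fx$ref)$exonic
  expect_equal(sub_at(2003, "T", "C"), "Synonymous")      # GCT -> GCC (Ala)
  expect_equal(sub_at(2002, "C", "A"), "Non-synonymous")  # GCT -> GAT (Asp)
  expect_equal(sub_at(2005, "G", "A"), "Stop gain")       # TGG -> TAG
  expect_equal(sub_at(3298, "T", "C"), "Stop loss")       # TAA -> CAA
  # minus strand: genomic 8300 T>C is transcript ATG -> GTG (Met -> Val)
  expect_equal(sub_at(8300, "T", "C"), "Non-synonymous")
  # minus strand synonymous at a wobble position: transcript codon 2 is
  # revcomp of genomic 8295-8297 ("AAA") = TTT (Phe); genomic 8295 A>G
  # makes it TTC, still Phe
  expect_equal(sub_at(8295, "A", "G"), "Synonymous")
})

test_that("classification errors and invariants hold", {
  fx <- make_annot_fixture()
  expect_error(classify_variant("chrT", 2003, "G", "C", fx$models, fx$ref),
               "reference mismatch at chrT:2003")
  # invariant: subcategory != none iff Exonic
  pos <- c(1501, 2100, 2500, 11500)
  ann <- classify_variants(data.frame(chrom = "chrT", pos = pos,
                                      ref = c("A", "A", "A", "A"),
                                      alt = "C"), fx$models, fx$ref)
  expect_identical(ann$exonic != "none", ann$category == "Exonic")
  # order invariance under gene-model shuffling
  ann2 <- classify_variants(data.frame(chrom = "chrT", pos = pos,
                                       ref = "A", alt = "C"),
                            rev(fx$models), fx$ref)
  expect_equal(ann$category, ann2$category)
})

test_that("classifier agrees with a brute-force interval scan on simdata", {
  cfg <- sim_config(n_variants = 800, seed = 13, n_tall = 3, n_short = 3,
                    chrom_lengths = c(chr1 = 2e6),
                    sweep_regions = data.frame(chrom = "chr1", start = 5e5,
                                               end = 7e5, focal = "SL",
                                               boost = 0.9),
                    causal_snp = NULL)
  sim <- simulate_genotypes_and_phenotypes(cfg)
  ann <- classify_variants(sim$genotypes$variants, sim$gene_models,
                           sim$reference)
  oracle <- vapply(seq_len(nrow(ann)), function(i)
    annotate_oracle(ann$chrom[i], ann$pos[i], sim$gene_models),
    character(1))
  expect_equal(ann$category, oracle)
  # every category count sums to the number classified
  expect_equal(sum(table(ann$category)), nrow(ann))
})

test_that("gene models survive a GFF3 round trip", {
  fx <- make_annot_fixture()
  path <- tempfile(fileext = ".gff3")
  write_gene_models(fx$models, path)
  back <- read_gene_models(path)
  expect_equal(length(back), length(fx$models))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$gene_id, fx$models[[i]]$gene_id)
    expect_equal(back[[i]]$strand, fx$models[[i]]$strand)
    expect_equal(back[[i]]$exons$start, fx$models[[i]]$exons$start)
    expect_equal(back[[i]]$exons$end, fx$models[[i]]$exons$end)
  }
})

test_that("summary table normalizes against an explicit denominator", {
  counts <- c(Upstream = 40870, `Exonic:Stop gain` = 244,
              `Exonic:Stop loss` = 36, `Exonic:Synonymous` = 35791,
              `Exonic:Non-synonymous` = 23807, Intronic = 2976338,
              Splicing = 120, Downstream = 47182,
              `Upstream/Downstream` = 1030, Intergenic = 5455335)
  s <- summarize_annotations(counts, total = 8641229)
  pct <- setNames(s$percent, s$category)
  expect_equal(unname(pct["Intergenic"]), 63.13)
  expect_equal(unname(pct["Intronic"]), 34.44)
  exonic <- sum(s$count[startsWith(s$category, "Exonic")])
  expect_equal(round(100 * exonic / 8641229, 2), 0.69)

  one <- summarize_annotations(c(Intronic = 1), total = 1)
  expect_equal(one$percent, 100)
  expect_error(summarize_annotations(counts, total = 0), "positive")
  expect_error(summarize_annotations(counts, total = 10), "smaller")
})
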