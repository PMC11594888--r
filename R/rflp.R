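#' Restriction enzyme
#'
#' @param name enzyme name.
#' @param motif recognition motif, IUPAC ambiguity codes allowed, length
#'   >= 4.
#' @param cut_offset number of motif bases left of the cut, in
#'   `[0, nchar(motif)]` (EcoRI `G^AATTC` has offset 1).
#' @return object of class `enzyme`.
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  if (nchar(motif) < 4) stop("motif must be at least 4 bases")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif))
    stop("motif contains non-IUPAC characters")
  if (cut_offset < 0 || cut_offset > nchar(motif))
    stop("cut_offset must lie within the motif")
  structure(list(name = name, motif = motif,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' Read an enzyme table
#'
#' TSV with columns `name`, `motif`, `cut_offset`.
#'
#' @param path path to the table.
#' @return list of [restriction_enzyme()] objects.
#' @export
read_enzymes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    restriction_enzyme(df$name[i], df$motif[i], df$cut_offset[i]))
}

#' PCR amplicon carrying a SNP
#'
#' @param sequence uppercase nucleotide sequence.
#' @param snp_offset 0-based offset of the SNP within the sequence.
#' @param ref,alt the two alleles; the sequence must carry `ref` at the
#'   offset.
#' @return object of class `amplicon`.
#' @export
amplicon <- function(sequence, snp_offset, ref, alt) {
  sequence <- toupper(sequence)
  if (snp_offset < 0 || snp_offset >= nchar(sequence))
    stop("snp_offset outside the sequence")
  if (substr(sequence, snp_offset + 1, snp_offset + 1) != ref)
    stop("sequence does not carry the ref allele at the SNP offset")
  structure(list(sequence = sequence, snp_offset = as.integer(snp_offset),
                 ref = toupper(ref), alt = toupper(alt)),
            class = "amplicon")
}

#' Find restriction cut positions
#'
#' Matches the IUPAC-expanded motif on the forward strand (optionally also
#' the reverse strand, for non-palindromic motifs) and returns cut
#' coordinates: the number of bases to the left of each cut.
#'
#' @param seq nucleotide sequence (character).
#' @param enzyme an [restriction_enzyme()].
#' @param both_strands also scan the reverse strand (default `FALSE`;
#'   irrelevant for palindromic motifs).
#' @return sorted integer vector of cut coordinates in `(0, nchar(seq))`.
#' @export
find_sites <- function(seq, enzyme, both_strands = FALSE) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) stop("invalid nucleotide code in sequence")
  subject <- Biostrings::DNAString(seq)
  hit_starts <- function(pattern)
    Biostrings::start(Biostrings::matchPattern(pattern, subject,
                                               fixed = FALSE))
  starts <- hit_starts(enzyme$motif)
  cuts <- starts - 1L + enzyme$cut_offset
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$motif)))
    if (rc != enzyme$motif) {
      starts_rc <- hit_starts(rc)
      # cut on the forward coordinate system, measured from the motif end
      cuts <- c(cuts, starts_rc - 1L + nchar(enzyme$motif) -
                  enzyme$cut_offset)
    }
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0 & cuts < nchar(seq)]
}

#' Predicted digestion fragment pattern
#'
#' Substitutes the requested allele at the SNP offset, digests at all
#' recognition sites, and returns fragment lengths in descending order. A
#' heterozygote's pattern is the multiset union of the two homozygote
#' patterns (both allele templates are present in the PCR product).
#'
#' @param amp an [amplicon()].
#' @param enzyme an [restriction_enzyme()].
#' @param allele `"ref"`, `"alt"` or `"het"`.
#' @param both_strands passed to [find_sites()].
#' @return integer vector of fragment lengths, descending; fragments always
#'   sum to the amplicon length (twice the length for `"het"`).
#' @export
fragment_pattern <- function(amp, enzyme, allele = c("ref", "alt", "het"),
                             both_strands = FALSE) {
  allele <- match.arg(allele)
  if (allele == "het")
    return(sort(c(fragment_pattern(amp, enzyme, "ref", both_strands),
                  fragment_pattern(amp, enzyme, "alt", both_strands)),
                decreasing = TRUE))
  seq <- amp$sequence
  substr(seq, amp$snp_offset + 1, amp$snp_offset + 1) <-
    if (allele == "ref") amp$ref else amp$alt
  cuts <- find_sites(seq, enzyme, both_strands)
  sort(diff(c(0L, cuts, nchar(seq))), decreasing = TRUE)
}

#' Enzymes whose digestion pattern distinguishes the SNP alleles
#'
#' An enzyme is usable for PCR-RFLP genotyping when its recognition-site
#' count differs between the ref and alt allele templates (the SNP creates
#' or destroys a site).
#'
#' @param amp an [amplicon()].
#' @param enzymes list of [restriction_enzyme()] objects.
#' @param both_strands passed to [find_sites()].
#' @return data.frame with `enzyme`, `n_sites_ref`, `n_sites_alt`,
#'   `usable`.
#' @export
snp_alters_site <- function(amp, enzymes, both_strands = FALSE) {
  seq_ref <- amp$sequence
  seq_alt <- amp$sequence
  substr(seq_alt, amp$snp_offset + 1, amp$snp_offset + 1) <- amp$alt
  rows <- lapply(enzymes, function(e) {
    nr <- length(find_sites(seq_ref, e, both_strands))
    na_ <- length(find_sites(seq_alt, e, both_strands))
    data.frame(enzyme = e$name, n_sites_ref = nr, n_sites_alt = na_,
               usable = nr != na_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
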