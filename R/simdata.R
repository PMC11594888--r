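#' Simulation configuration for a two-population resequencing study
#'
#' Describes a two-population (tall-legged "TL" / short-legged "SL") genotype
#' and phenotype simulation built on the Balding-Nichols model: every variant
#' has an ancestral allele frequency, and each population's frequency is a
#' Beta draw around it with dispersion set by the background Fst. Selected
#' ("sweep") regions additionally push the focal population toward fixation,
#' producing the low-diversity / high-differentiation signature a windowed
#' Fst + nucleotide-diversity screen looks for. One variant can be designated
#' causal for leg length with an additive effect in cm per alt allele.
#'
#' Defaults mirror a desk-scale study: 15 + 15 samples, 2 chromosomes of
#' 5 Mb, 20,000 independent SNPs, background Fst 0.03, three 200 kb sweep
#' regions focal in SL, and a causal SNP of 3 cm per allele on a neutral
#' chromosome arm.
#'
#' @param n_tall,n_short samples per population.
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp).
#' @param n_variants total number of simulated SNPs.
#' @param background_fst drift parameter F of the Balding-Nichols Beta,
#'   strictly in (0, 1).
#' @param sweep_regions data.frame with columns `chrom`, `start`, `end`,
#'   `focal` ("TL" or "SL"), `boost` in (0, 1]; `NULL` for none.
#' @param causal_snp list with `chrom`, `pos`, `effect` (cm per alt allele),
#'   or `NULL` for no causal variant.
#' @param pheno_mean,pheno_sd baseline leg length mean and residual sd (cm).
#' @param missing_rate per-call missingness fraction in \[0, 0.5\].
#' @param seed integer seed; all randomness flows from it.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_tall = 15, n_short = 15,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_variants = 20000,
                       background_fst = 0.03,
                       sweep_regions = data.frame(
                         chrom = c("chr1", "chr2", "chr2"),
                         start = c(1000001, 2000001, 4000001),
                         end   = c(1200000, 2200000, 4200000),
                         focal = "SL", boost = 0.9,
                         stringsAsFactors = FALSE),
                       causal_snp = list(chrom = "chr1", pos = 3000000,
                                         effect = 3.0),
                       pheno_mean = 28, pheno_sd = 1.0,
                       missing_rate = 0.02, seed = 1) {
  chrom_lengths <- unlist(chrom_lengths)   # accept list form (JSON configs)
  storage.mode(chrom_lengths) <- "double"  # avoid integer overflow in bp math
  if (n_variants < 1) stop("degenerate config: n_variants must be >= 1")
  if (n_tall < 1 || n_short < 1) stop("both populations must be nonempty")
  if (is.null(names(chrom_lengths)) || any(chrom_lengths < 1))
    stop("chrom_lengths must be a named vector of positive lengths")
  if (!(background_fst > 0 && background_fst < 1))
    stop("background_fst must lie strictly in (0, 1)")
  if (missing_rate < 0 || missing_rate > 0.5)
    stop("missing_rate must lie in [0, 0.5]")
  if (!is.null(sweep_regions) && nrow(sweep_regions)) {
    if (!all(sweep_regions$chrom %in% names(chrom_lengths)))
      stop("sweep region on unknown chromosome")
    if (any(sweep_regions$end > chrom_lengths[sweep_regions$chrom]) ||
        any(sweep_regions$start < 1) ||
        any(sweep_regions$start > sweep_regions$end))
      stop("sweep regions must lie within chrom_lengths")
    if (any(sweep_regions$boost <= 0 | sweep_regions$boost > 1))
      stop("sweep boost must lie in (0, 1]")
    if (!all(sweep_regions$focal %in% c("TL", "SL")))
      stop("sweep focal population must be 'TL' or 'SL'")
  }
  if (!is.null(causal_snp)) {
    if (!causal_snp$chrom %in% names(chrom_lengths))
      stop("causal SNP on unknown chromosome")
    if (causal_snp$pos < 1 || causal_snp$pos > chrom_lengths[[causal_snp$chrom]])
      stop("causal SNP position outside chromosome")
  }
  structure(list(n_tall = n_tall, n_short = n_short,
                 chrom_lengths = chrom_lengths, n_variants = n_variants,
                 background_fst = background_fst,
                 sweep_regions = sweep_regions, causal_snp = causal_snp,
                 pheno_mean = pheno_mean, pheno_sd = pheno_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# variant positions: proportional allocation across chromosomes, sorted,
# with the causal position forced to be among them
.sim_positions <- function(config) {
  L <- config$chrom_lengths
  n <- config$n_variants
  alloc <- floor(n * L / sum(L))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  pos <- lapply(names(L), function(ch)
    sort(sample.int(L[[ch]], alloc[[ch]])))
  names(pos) <- names(L)
  cs <- config$causal_snp
  if (!is.null(cs)) {
    p <- pos[[cs$chrom]]
    if (!cs$pos %in% p) {
      p[which.min(abs(p - cs$pos))] <- cs$pos   # replace nearest site
      pos[[cs$chrom]] <- sort(unique(p))
    }
  }
  data.frame(chrom = rep(names(L), lengths(pos)),
             pos = unlist(pos, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Simulate per-population allele frequencies
#'
#' Draws an ancestral frequency per variant from Uniform(0.05, 0.95) (the
#' causal site, if any, is fixed at 0.5 so it segregates in both groups),
#' then per-population frequencies from the Balding-Nichols Beta with shape
#' `alpha = p(1-F)/F`, `beta = (1-p)(1-F)/F`, where `F` is the background
#' Fst. Inside a sweep region the focal population's frequency is moved a
#' fraction `boost` of the way toward the nearest fixed state (0 or 1).
#'
#' Called internally by [simulate_genotypes_and_phenotypes()]; exposed so the
#' frequency layer can be examined and tested on its own (it seeds the RNG
#' from `config$seed`).
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `chrom`, `pos`, `p_anc`, `p_TL`, `p_SL`,
#'   `in_sweep` (row index into `config$sweep_regions` or `NA`) and
#'   `is_causal`.
#' @export
simulate_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sim_frequencies(config)
}

.sim_frequencies <- function(config) {
  v <- .sim_positions(config)
  n <- nrow(v)
  v$p_anc <- runif(n, 0.05, 0.95)
  v$is_causal <- FALSE
  cs <- config$causal_snp
  if (!is.null(cs)) {
    i <- which(v$chrom == cs$chrom & v$pos == cs$pos)
    v$p_anc[i] <- 0.5
    v$is_causal[i] <- TRUE
  }
  F <- config$background_fst
  draw <- function(p) {
    if (F < 1e-8) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  v$p_TL <- draw(v$p_anc)
  v$p_SL <- draw(v$p_anc)
  v$in_sweep <- NA_integer_
  sw <- config$sweep_regions
  if (!is.null(sw) && nrow(sw)) {
    for (k in seq_len(nrow(sw))) {
      hit <- v$chrom == sw$chrom[k] & v$pos >= sw$start[k] & v$pos <= sw$end[k]
      v$in_sweep[hit] <- k
      col <- paste0("p_", sw$focal[k])
      f <- v[[col]][hit]
      target <- round(f)                      # nearest fixed state
      v[[col]][hit] <- f + sw$boost[k] * (target - f)
    }
  }
  v
}

#' Simulate genotypes, phenotypes, gene models and reference
#'
#' Draws diploid genotypes as Binomial(2, population frequency) at
#' independent sites, masks calls at the configured missing rate, and builds
#' phenotypes under the additive single-locus model: leg length =
#' `pheno_mean + effect * dosage + N(0, pheno_sd)`. Chest depth is drawn
#' N(30, 1.5) cm and body height is chest depth + leg length, so that the
#' derived trait height - chest depth reproduces the simulated leg length
#' exactly. Gene models (3-exon, CDS-complete genes) are placed inside every
#' sweep region and scattered over neutral sequence.
#'
#' The RNG is seeded once from `config$seed`: identical configs give
#' byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param reference if `FALSE`, skip generating the (large) random reference
#'   sequence; annotation-related fields are then absent.
#' @return a list of class `sim_output` with elements `genotypes`
#'   (a [geno_matrix()]), `phenotypes` (data.frame: `sample`, `group`,
#'   `height_cm`, `chest_depth_cm`, `leg_length_cm`), `gene_models`,
#'   `reference` (a `DNAStringSet` or `NULL`), `frequencies` and `truth`
#'   (list with `sweeps` and `causal`).
#' @export
simulate_genotypes_and_phenotypes <- function(config, reference = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freq <- .sim_frequencies(config)
  n_var <- nrow(freq)
  samples <- c(sprintf("TL%02d", seq_len(config$n_tall)),
               sprintf("SL%02d", seq_len(config$n_short)))
  groups <- rep(c("TL", "SL"), c(config$n_tall, config$n_short))
  n_sam <- length(samples)

  p <- rbind(matrix(freq$p_TL, config$n_tall, n_var, byrow = TRUE),
             matrix(freq$p_SL, config$n_short, n_var, byrow = TRUE))
  calls <- matrix(rbinom(n_sam * n_var, 2L, p), n_sam, n_var)

  # phenotype from the true (pre-masking) causal dosage
  dosage <- if (any(freq$is_causal)) calls[, which(freq$is_causal)] else 0
  effect <- if (is.null(config$causal_snp)) 0 else config$causal_snp$effect
  leg <- config$pheno_mean + effect * dosage + rnorm(n_sam, 0, config$pheno_sd)
  chest <- rnorm(n_sam, 30, 1.5)
  pheno <- data.frame(sample = samples, group = groups,
                      height_cm = round(chest + leg, 3),
                      chest_depth_cm = round(chest, 3),
                      stringsAsFactors = FALSE)
  pheno$leg_length_cm <- pheno$height_cm - pheno$chest_depth_cm

  # site metadata: ref/alt bases, site quality, per-sample depth
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  qual <- round(runif(n_var, 50, 999), 1)
  dp <- matrix(rpois(n_sam * n_var, 8), n_sam, n_var)
  if (config$missing_rate > 0)
    calls[matrix(runif(n_sam * n_var) < config$missing_rate,
                 n_sam, n_var)] <- NA_integer_

  variants <- data.frame(chrom = freq$chrom, pos = freq$pos,
                         ref = unname(ref), alt = unname(alt), qual = qual,
                         mean_dp = colMeans(dp), stringsAsFactors = FALSE)
  g <- geno_matrix(calls, samples, variants, dp = dp)

  models <- .sim_gene_models(config)
  ref_seq <- if (reference) .sim_reference(config, variants) else NULL

  structure(list(genotypes = g, phenotypes = pheno, gene_models = models,
                 reference = ref_seq, frequencies = freq,
                 truth = list(sweeps = config$sweep_regions,
                              causal = config$causal_snp)),
            class = "sim_output")
}

# genes: two per sweep region plus neutral genes spread over each chromosome
.sim_gene_models <- function(config) {
  exon_len <- c(300L, 450L, 300L)   # CDS total 1050, divisible by 3
  intron_len <- 2000L
  span <- sum(exon_len) + 2L * intron_len
  mk <- function(id, chrom, start, strand) {
    ex_start <- start + c(0L, cumsum(exon_len[-3] + intron_len))
    exons <- data.frame(start = ex_start, end = ex_start + exon_len - 1L)
    gene_model(id, chrom, strand, exons = exons, cds = exons)
  }
  genes <- list(); id <- 0L
  sw <- config$sweep_regions
  if (!is.null(sw) && nrow(sw)) {
    for (k in seq_len(nrow(sw))) {
      for (off in c(10000L, 100000L)) {
        if (sw$start[k] + off + span > sw$end[k]) next
        id <- id + 1L
        genes[[length(genes) + 1L]] <-
          mk(sprintf("gene%03d", id), sw$chrom[k], sw$start[k] + off,
             if (id %% 2L) "+" else "-")
      }
    }
  }
  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    for (start in seq(50001L, L - span, by = max(span * 4L, 500000L))) {
      id <- id + 1L
      genes[[length(genes) + 1L]] <-
        mk(sprintf("gene%03d", id), ch, as.integer(start),
           if (id %% 2L) "+" else "-")
    }
  }
  genes
}

.sim_reference <- function(config, variants) {
  seqs <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    s <- Biostrings::DNAString(paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
    i <- variants$chrom == ch
    if (any(i))
      s <- Biostrings::replaceLetterAt(s, variants$pos[i], variants$ref[i])
    s
  })
  names(seqs) <- names(config$chrom_lengths)
  Biostrings::DNAStringSet(seqs)
}

#' Write simulated data to disk
#'
#' Emits `genotypes.vcf` (VCF 4.2 with QUAL and per-sample GT:DP:AD),
#' `phenotypes.tsv`, `reference.fa` (if present), `genes.gff3` and
#' `truth.tsv` (one row per sweep region plus one `causal` row). All files
#' round-trip through [read_vcf()], [read_gene_models()] and plain
#' `read.delim`.
#'
#' @param sim a `sim_output` from [simulate_genotypes_and_phenotypes()].
#' @param directory output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_outputs <- function(sim, directory) {
  stopifnot(inherits(sim, "sim_output"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)
  paths <- c(vcf = file.path(directory, "genotypes.vcf"),
             pheno = file.path(directory, "phenotypes.tsv"),
             gff = file.path(directory, "genes.gff3"),
             truth = file.path(directory, "truth.tsv"))
  write_vcf(sim$genotypes, paths[["vcf"]],
            contig_lengths = .contig_lengths_from(sim))
  write.table(sim$phenotypes[c("sample", "group", "height_cm",
                               "chest_depth_cm")],
              paths[["pheno"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_models(sim$gene_models, paths[["gff"]])
  if (!is.null(sim$reference)) {
    paths <- c(paths, fasta = file.path(directory, "reference.fa"))
    Biostrings::writeXStringSet(sim$reference, paths[["fasta"]])
  }
  truth <- data.frame(type = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      focal = character(), value = numeric())
  sw <- sim$truth$sweeps
  if (!is.null(sw) && nrow(sw))
    truth <- rbind(truth, data.frame(type = "sweep", chrom = sw$chrom,
                                     start = sw$start, end = sw$end,
                                     focal = sw$focal, value = sw$boost))
  cs <- sim$truth$causal
  if (!is.null(cs))
    truth <- rbind(truth, data.frame(type = "causal", chrom = cs$chrom,
                                     start = cs$pos, end = cs$pos,
                                     focal = NA, value = cs$effect))
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

.contig_lengths_from <- function(sim) {
  if (!is.null(sim$reference)) {
    w <- Biostrings::width(sim$reference)
    names(w) <- names(sim$reference)
    return(w)
  }
  v <- sim$genotypes$variants
  tapply(v$pos, v$chrom, max)
}
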