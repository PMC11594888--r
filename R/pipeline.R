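#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> filter -> annotate -> structure -> sweep ->
#' gwas -> markers -> enrich on one simulated dataset, writing every
#' stage's tables under `out_dir` and a JSON manifest with parameters and
#' MD5 checksums of all outputs. All randomness flows from `config$seed`
#' via per-stage derived seeds, so a rerun with the same config reproduces
#' identical checksums.
#'
#' The configuration is a nested list (or a path to a JSON file with the
#' same shape) with optional blocks `sim` (arguments of [sim_config()]),
#' `filter` (arguments of [filter_variants()]), `sweep` (`size`, `step`,
#' `quantile`, `pi_mode`, `min_snps`), `structure` (`n_boot`), `enrich`
#' (`n_terms`), and a global `seed`. Missing blocks use module defaults.
#'
#' Because no public cohort is bundled, the enrichment stage tests the
#' sweep-selected gene list against randomly drawn term sets over the
#' simulated gene universe (a null reference, labelled as such in the
#' output).
#'
#' @param config nested list or path to a JSON config file.
#' @param out_dir output directory.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  manifest <- list(package = "popsweep",
                   version = as.character(utils::packageVersion("popsweep")),
                   seed = seed, stages = list())
  outputs <- character()
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res$params
    outputs <<- c(outputs, res$files)
    res$value
  }
  tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  ## --- simulate -----------------------------------------------------
  sim <- stage("sim", function() {
    args <- config$sim
    args$seed <- seed
    cfg <- do.call(sim_config, args %||% list(seed = seed))
    s <- simulate_genotypes_and_phenotypes(cfg)
    files <- write_outputs(s, out_dir)
    list(value = s, params = unclass(cfg)[setdiff(names(cfg), "sweep_regions")],
         files = files)
  })
  g0 <- sim$genotypes
  pheno <- sim$phenotypes
  models <- sim$gene_models

  ## --- filter -------------------------------------------------------
  filt <- stage("filter", function() {
    args <- c(list(g = g0), config$filter)
    f <- do.call(filter_variants, args)
    files <- c(write_vcf(f$genotypes, file.path(out_dir, "filtered.vcf")),
               write_filter_report(f$report,
                                   file.path(out_dir, "filter_report.tsv")))
    list(value = f$genotypes, params = f$report$params, files = files)
  })

  ## --- annotate -----------------------------------------------------
  stage("annotate", function() {
    ann <- classify_variants(filt$variants, models, sim$reference)
    summ <- summarize_annotations(ann)
    files <- c(tsv(ann, "annotations.tsv"),
               tsv(summ, "annotation_summary.tsv"))
    list(value = ann, params = list(), files = files)
  })

  ## --- structure ----------------------------------------------------
  stage("structure", function() {
    n_boot <- config$structure$n_boot %||% 100
    bs <- bootstrap_support(filt, n_boot = n_boot, seed = seed + 1L)
    nwk <- file.path(out_dir, "nj_tree.nwk")
    ape::write.tree(bs$tree, file = nwk)
    M <- standardize_genotypes(filt)
    pc <- pca(M)
    files <- c(nwk,
               tsv(bs$splits, "nj_bootstrap.tsv"),
               tsv(data.frame(sample = rownames(pc$coords), pc$coords),
                   "pca_coords.tsv"))
    list(value = pc, params = list(n_boot = n_boot), files = files)
  })

  ## --- sweep --------------------------------------------------------
  pops <- split(pheno$sample, pheno$group)
  sweep_res <- stage("sweep", function() {
    sc <- config$sweep
    win <- make_windows(.contig_lengths_from(sim),
                        size = sc$size %||% 100000,
                        step = sc$step %||% 50000)
    win <- window_fst(g0, pops[c("TL", "SL")], win)
    win <- window_pi(g0, pops$TL, win, col = "pi_TL")
    win <- window_pi(g0, pops$SL, win, col = "pi_SL")
    q <- sc$quantile %||% 0.95
    mode <- sc$pi_mode %||% "ratio"
    msnp <- sc$min_snps %||% 5
    res <- lapply(c(TL = "TL", SL = "SL"), function(f)
      joint_select(win, f, quantile = q, pi_mode = mode, min_snps = msnp))
    win$selected_TL <- res$TL$windows$selected
    win$selected_SL <- res$SL$windows$selected
    sel <- win[win$selected_TL | win$selected_SL, , drop = FALSE]
    bed <- data.frame(chrom = sel$chrom, start = sel$start - 1L,
                      end = sel$end,
                      name = ifelse(sel$selected_TL & sel$selected_SL,
                                    "TL,SL",
                                    ifelse(sel$selected_TL, "TL", "SL")))
    bed_path <- file.path(out_dir, "selected_windows.bed")
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    genes <- lapply(res, function(r)
      windows_to_genes(r$windows[r$windows$selected, , drop = FALSE],
                       models)$union)
    files <- c(tsv(win, "window_stats.tsv"), bed_path,
               tsv(data.frame(group = rep(names(genes), lengths(genes)),
                              gene = unlist(genes)), "selected_genes.tsv"))
    list(value = list(windows = win, genes = genes),
         params = list(quantile = q, pi_mode = mode, min_snps = msnp),
         files = files)
  })

  ## --- gwas ---------------------------------------------------------
  gwas_res <- stage("gwas", function() {
    y <- pheno$leg_length_cm[match(filt$samples, pheno$sample)]
    K <- kinship_centered(filt)
    r <- mlm_associate(y, filt, K)
    thr <- bonferroni_threshold(0.05, r$n_tests)
    qq <- qq_lambda(r$assoc$p)
    files <- c(tsv(r$assoc, "gwas_assoc.tsv"),
               tsv(qq$table, "gwas_qq.tsv"))
    list(value = list(result = r, threshold = thr),
         params = list(threshold = thr, lambda = r$lambda,
                       lambda_gc = r$lambda_gc),
         files = files)
  })

  ## --- markers ------------------------------------------------------
  stage("markers", function() {
    assoc <- gwas_res$result$assoc
    top <- which.min(assoc$p)
    calls <- filt$calls[, top]
    v <- filt$variants[top, ]
    gt_lab <- c(paste0(v$ref, v$ref), paste0(v$ref, v$alt),
                paste0(v$alt, v$alt))
    counts <- c(sum(calls == 0, na.rm = TRUE), sum(calls == 1, na.rm = TRUE),
                sum(calls == 2, na.rm = TRUE))
    ms <- marker_stats(counts, locus = sprintf("%s:%d", v$chrom, v$pos))
    ok <- !is.na(calls)
    at <- glm_association(pheno$leg_length_cm[match(filt$samples,
                                                    pheno$sample)][ok],
                          gt_lab[calls[ok] + 1L])
    files <- c(tsv(data.frame(locus = ms$locus, p = ms$p, q = ms$q,
                              chi_square = ms$chi_square, pic = ms$pic,
                              ho = ms$ho, he = ms$he, ne = ms$ne),
                   "marker_stats.tsv"),
               tsv(at$groups, "marker_association.tsv"))
    list(value = ms, params = list(locus = ms$locus), files = files)
  })

  ## --- enrich -------------------------------------------------------
  stage("enrich", function() {
    universe <- vapply(models, `[[`, character(1), "gene_id")
    n_terms <- config$enrich$n_terms %||% 20
    set.seed(seed + 2L)
    term_sets <- lapply(seq_len(n_terms), function(i)
      sample(universe, max(2, rpois(1, 5))))
    names(term_sets) <- sprintf("NULLTERM%03d", seq_len(n_terms))
    sel <- intersect(sweep_res$genes$SL, universe)
    tab <- if (length(sel))
      enrich_table(sel, term_sets, universe) else
        data.frame(term = character(), p = numeric())
    files <- tsv(tab, "enrichment_null_reference.tsv")
    list(value = tab, params = list(n_terms = n_terms), files = files)
  })

  manifest$checksums <- as.list(tools::md5sum(sort(unname(outputs))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
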