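## Pipeline orchestration: a configuration object, stage runners over
## the on-disk dataset, and a deterministic markdown/JSON report that
## assembles the synthetic analogue of the study's figure panels.

#' Pipeline configuration
#'
#' @param data_dir Directory holding the dataset (as written by
#'   [generate_dataset] or arranged with the same file names).
#' @param outdir Output directory for stage results and the report.
#' @param alpha_diff Adjusted-p threshold for DAR/DEG/DBR and
#'   differential loops (default 0.1, the DESeq2-style cutoff used
#'   throughout the analysis).
#' @param loop_q FDR threshold for loop calling (default 0.01).
#' @param abc_threshold ABC passing threshold (default 0.02).
#' @param promoter_bp Promoter window half-width (default 3000).
#' @param resolution HiChIP bin size in bp (default 1000).
#' @param min_loop_distance Minimum interaction size in bp (default
#'   1000).
#' @param max_loop_distance Maximum tested loop span (default 2 Mb).
#' @param k27_peak_min_mean Minimum mean H3K27ac count for a region to
#'   count as an H3K27ac peak when classifying loop anchors.
#' @param conditions Condition labels, numerator first.
#' @param seed Seed for the pipeline's own randomness (decoy motifs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, outdir,
                            alpha_diff = 0.1, loop_q = 0.01,
                            abc_threshold = 0.02, promoter_bp = 3000L,
                            resolution = 1000L,
                            min_loop_distance = 1000L,
                            max_loop_distance = 2e6,
                            k27_peak_min_mean = 100,
                            conditions = c("LSS", "ST"), seed = 1L) {
  stopifnot(alpha_diff > 0, alpha_diff < 1, loop_q > 0, loop_q < 1,
            abc_threshold > 0, abc_threshold < 1, resolution >= 1,
            length(conditions) == 2L)
  structure(list(data_dir = data_dir, outdir = outdir,
                 alpha_diff = alpha_diff, loop_q = loop_q,
                 abc_threshold = abc_threshold,
                 promoter_bp = as.integer(promoter_bp),
                 resolution = as.integer(resolution),
                 min_loop_distance = as.integer(min_loop_distance),
                 max_loop_distance = max_loop_distance,
                 k27_peak_min_mean = k27_peak_min_mean,
                 conditions = conditions, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

load_dataset_inputs <- function(config) {
  dd <- config$data_dir
  p <- function(f) file.path(dd, f)
  inputs <- list(
    regions = read_regions(p("regions.narrowPeak"), "narrowPeak"),
    atac = read_counts(p("atac_counts.tsv")),
    h3k27ac = read_counts(p("h3k27ac_counts.tsv")),
    klf4 = read_counts(p("klf4_counts.tsv")),
    brg1 = read_counts(p("brg1_counts.tsv")),
    rna = read_counts(p("rna_counts.tsv")),
    genes = read_genes(p("genes.tsv")),
    sequences = read_fasta(p("sequences.fa")),
    pwm = read_pwm(p("klf_like.pwm")),
    snps = read_snps(p("snps.tsv")))
  hic_path <- p("hic_contacts.tsv")
  inputs$hic <- if (file.exists(hic_path)) read_contacts(hic_path) else NULL
  pets <- list()
  for (cond in config$conditions) {
    r <- 1L
    repeat {
      f <- p(sprintf("hichip_%s_rep%d.bedpe", cond, r))
      if (!file.exists(f)) break
      pets[[sprintf("%s_%d", cond, r)]] <- f
      r <- r + 1L
    }
  }
  if (!length(pets)) stop("no HiChIP BEDPE files found under ", dd)
  inputs$hichip_files <- pets
  inputs
}

region_intervals <- function(res_table, regions) {
  i <- match(res_table$feature_id, regions$name)
  data.frame(chrom = regions$chrom[i], start = regions$start[i],
             end = regions$end[i], name = regions$name[i],
             log2fc = res_table$log2fc, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Stages: differential accessibility (DAR), expression (DEG) and
#' binding (KLF4/BRG1 DBR); motif enrichment of opening/closing DARs
#' against accessible non-differential background (the planted PWM plus
#' column-shuffled decoys); peak annotation, nearest-TSS distances,
#' DAR-DEG correlation and KLF4/BRG1 co-occupancy; ABC enhancer-gene
#' prediction per condition over the DEG set; HiChIP loop calling,
#' classification and differential testing; KLF4-at-anchor and
#' SNP-to-enhancer integration; and a markdown + JSON report. All
#' outputs are deterministic functions of (inputs, config, seed).
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with every stage's results and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_dataset_inputs(config)
  out <- function(f) file.path(config$outdir, f)
  numer <- config$conditions[1L]

  ## --- differential stages -------------------------------------------
  dar <- nb_wald_test(inp$atac, config$alpha_diff, numer)
  deg <- nb_wald_test(inp$rna, config$alpha_diff, numer)
  klf4_dbr_res <- nb_wald_test(inp$klf4, config$alpha_diff, numer)
  brg1_dbr_res <- nb_wald_test(inp$brg1, config$alpha_diff, numer)
  write_differential(dar, out("dar_results.tsv"))
  write_differential(deg, out("deg_results.tsv"))
  write_differential(klf4_dbr_res, out("klf4_dbr_results.tsv"))
  write_differential(brg1_dbr_res, out("brg1_dbr_results.tsv"))

  ## --- motif enrichment ----------------------------------------------
  up_dar <- dar$feature_id[dar$significant & dar$log2fc > 0]
  down_dar <- dar$feature_id[dar$significant & dar$log2fc < 0]
  bg <- dar$feature_id[!dar$significant]
  pwms <- c(list(inp$pwm),
            shuffle_pwm_columns(inp$pwm, 5L, seed = config$seed))
  motif_up <- if (length(up_dar))
    motif_enrichment(up_dar, bg, inp$sequences, pwms) else NULL
  motif_down <- if (length(down_dar))
    motif_enrichment(down_dar, bg, inp$sequences, pwms) else NULL
  if (!is.null(motif_up))
    utils::write.table(motif_up, out("motif_enrichment_up.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(motif_down))
    utils::write.table(motif_down, out("motif_enrichment_down.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- annotation & integration of DAR with DEG ----------------------
  sig_dar_regions <- inp$regions[inp$regions$name %in%
                                 dar$feature_id[dar$significant], ,
                                 drop = FALSE]
  ann <- annotate_peaks(sig_dar_regions, inp$genes,
                        promoter_bp = config$promoter_bp)
  utils::write.table(ann$annotation, out("dar_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dist_hist <- distance_distribution(sig_dar_regions, inp$genes)
  corr <- dar_deg_correlation(dar, deg, inp$genes, inp$regions)
  if (!is.null(corr$pairs))
    utils::write.table(corr$pairs, out("dar_deg_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  klf4_sig <- region_intervals(
    klf4_dbr_res[klf4_dbr_res$significant, , drop = FALSE], inp$regions)
  brg1_sig <- region_intervals(
    brg1_dbr_res[brg1_dbr_res$significant, , drop = FALSE], inp$regions)
  dar_up_iv <- region_intervals(
    dar[dar$significant & dar$log2fc > 0, , drop = FALSE], inp$regions)
  cooc <- if (nrow(dar_up_iv))
    cooccupancy(dar_up_iv, klf4_sig, brg1_sig) else NULL

  ## --- ABC enhancer-gene prediction ----------------------------------
  total_atac <- rowSums(inp$atac$counts)
  candidates <- make_candidate_regions(inp$regions, total_atac,
                                       top_n = 150000L)
  elements <- make_abc_elements(candidates, inp$genes)
  hic <- if (!is.null(inp$hic))
    prepare_hic(inp$hic, resolution = config$resolution) else NULL
  deg_ids <- deg$feature_id[deg$significant]
  abc_runs <- lapply(config$conditions, function(cond) {
    el <- quantify_activity(elements, inp$atac, inp$h3k27ac, cond,
                            peaks = inp$regions)
    pr <- predict_all(inp$genes, el, expressed_only = deg_ids,
                      klf4_dbr = klf4_sig,
                      threshold = config$abc_threshold, hic = hic,
                      resolution = config$resolution)
    pr$predictions$condition <- cond
    pr
  })
  names(abc_runs) <- config$conditions
  abc_pred <- do.call(rbind, lapply(abc_runs, `[[`, "predictions"))
  rownames(abc_pred) <- NULL
  abc_pass <- abc_pred[abc_pred$passes, , drop = FALSE]
  utils::write.table(abc_pass, out("abc_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## --- HiChIP loops ---------------------------------------------------
  sample_names <- names(inp$hichip_files)
  pets_by_sample <- lapply(inp$hichip_files, read_loops)
  binned_by_sample <- lapply(pets_by_sample, bin_contacts,
                             resolution = config$resolution,
                             min_distance = config$min_loop_distance)
  cond_of <- stats::setNames(sub("_[0-9]+$", "", sample_names),
                             sample_names)
  k27_mean <- rowMeans(inp$h3k27ac$counts)
  k27_peaks <- inp$regions[k27_mean[inp$regions$name] >=
                           config$k27_peak_min_mean, , drop = FALSE]
  loop_calls <- lapply(config$conditions, function(cond) {
    pooled <- do.call(rbind, pets_by_sample[cond_of == cond])
    binned <- bin_contacts(pooled, config$resolution,
                           config$min_loop_distance)
    decay <- fit_decay(binned, max_distance = config$max_loop_distance)
    called <- call_loops(binned, decay, config$loop_q,
                         config$max_loop_distance)
    called$loops <- classify_loops(called$loops, k27_peaks, inp$genes,
                                   config$promoter_bp)
    called
  })
  names(loop_calls) <- config$conditions
  ## differential testing over the union of loops called in either
  ## condition
  union_loops <- unique(do.call(rbind, lapply(loop_calls, function(x)
    x$loops[, c("loop_id", "chrom", "bin1", "bin2", "start1", "end1",
                "start2", "end2", "loop_class", "target_gene")])))
  diff_loops <- differential_loops(union_loops, binned_by_sample,
                                   cond_of, config$alpha_diff, numer)
  utils::write.table(diff_loops, out("loops_differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in config$conditions) {
    lp <- loop_calls[[cond]]$loops
    utils::write.table(lp, out(sprintf("loops_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- KLF4 at enhancer anchors; SNP-to-gene -------------------------
  ep_numer <- loop_calls[[numer]]$loops
  klf4_anchor <- klf4_at_anchors(ep_numer, klf4_sig, deg)
  utils::write.table(klf4_anchor$table, out("klf4_anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  snp_pred <- abc_pass[!abc_pass$is_promoter, , drop = FALSE]
  snps <- snp_overlap(inp$snps, snp_pred)
  utils::write.table(snps$table, out("snp_enhancer_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- summary & report ----------------------------------------------
  loop_tab <- table(factor(diff_loops$differential,
                           levels = c("gained", "lost", "stable")))
  summary <- list(
    n_dar_up = length(up_dar), n_dar_down = length(down_dar),
    n_deg_up = sum(deg$significant & deg$log2fc > 0),
    n_deg_down = sum(deg$significant & deg$log2fc < 0),
    annotation_tally = as.list(ann$tally),
    distance_histogram = as.list(dist_hist),
    dar_deg_r = corr$r, dar_deg_p = corr$p, dar_deg_n = corr$n,
    cooccupancy = if (!is.null(cooc)) list(
      n_dar = cooc$summary$n_dar,
      fractions = as.list(cooc$summary$fractions),
      delta_cor_r = if (!is.null(cooc$delta_cor)) cooc$delta_cor$r
        else NA) else NULL,
    top_motif = if (!is.null(motif_up)) motif_up$motif[1L] else NA,
    abc = list(n_passing_pairs = sum(!abc_pass$is_promoter),
               n_genes_with_enhancer =
                 length(unique(abc_pass$gene_id[!abc_pass$is_promoter])),
               fraction_deg_klf4_regulated =
                 abc_runs[[numer]]$summary$fraction_klf4_regulated),
    loops = c(stats::setNames(lapply(config$conditions, function(cond)
      nrow(loop_calls[[cond]]$loops)),
      paste0("n_loops_", config$conditions)),
      list(n_ep = sum(diff_loops$loop_class == "EP"),
           n_gained = as.integer(loop_tab[["gained"]]),
           n_lost = as.integer(loop_tab[["lost"]]))),
    klf4_anchors = klf4_anchor$summary,
    snps = snps$summary)
  jsonlite::write_json(summary, out("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       na = "null")
  write_report(summary, motif_up, out("report.md"))
  invisible(list(config = config, inputs = inp, dar = dar, deg = deg,
                 klf4_dbr = klf4_dbr_res, brg1_dbr = brg1_dbr_res,
                 motif_up = motif_up, motif_down = motif_down,
                 annotation = ann, distance_histogram = dist_hist,
                 correlation = corr, cooccupancy = cooc,
                 elements = elements, abc = abc_runs,
                 abc_predictions = abc_pred, loop_calls = loop_calls,
                 diff_loops = diff_loops, klf4_anchor = klf4_anchor,
                 snps = snps, summary = summary))
}

fmt_num <- function(x, digits = 3) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return("NA")
  format(x, digits = digits)
}

write_report <- function(summary, motif_up, path) {
  ln <- c(
    "# Shear-stress enhancer landscape: pipeline report",
    "",
    "## Differential accessibility and expression",
    sprintf("- DAR: %d gained / %d lost accessibility under %s",
            summary$n_dar_up, summary$n_dar_down, "LSS"),
    sprintf("- DEG: %d up / %d down", summary$n_deg_up,
            summary$n_deg_down),
    "",
    "## DAR annotation",
    paste(sprintf("- %s: %d", names(summary$annotation_tally),
                  unlist(summary$annotation_tally)), collapse = "\n"),
    "",
    "## Distance of DAR to nearest TSS",
    paste(sprintf("- %s bp: %d", names(summary$distance_histogram),
                  unlist(summary$distance_histogram)), collapse = "\n"),
    "",
    "## Motif enrichment (opening DAR vs accessible background)",
    if (!is.null(motif_up)) paste(utils::capture.output(
      print(motif_up[, c("motif", "fg_fraction", "bg_fraction",
                         "fold", "binom_p")], row.names = FALSE)),
      collapse = "\n") else "- no opening DARs",
    "",
    "## DAR-DEG correlation",
    sprintf("- Pearson r = %s (p = %s, n = %d pairs)",
            fmt_num(summary$dar_deg_r), fmt_num(summary$dar_deg_p),
            summary$dar_deg_n %||% 0L),
    "",
    "## KLF4/BRG1 co-occupancy of opening DAR",
    if (!is.null(summary$cooccupancy)) paste(
      sprintf("- %s: %s", names(summary$cooccupancy$fractions),
              vapply(summary$cooccupancy$fractions, fmt_num,
                     character(1))), collapse = "\n")
    else "- no opening DARs",
    "",
    "## ABC enhancer-gene predictions",
    sprintf("- %d passing enhancer-gene pairs over %d genes",
            summary$abc$n_passing_pairs,
            summary$abc$n_genes_with_enhancer),
    sprintf("- fraction of DEG with a passing KLF4-bound enhancer: %s",
            fmt_num(summary$abc$fraction_deg_klf4_regulated)),
    "",
    "## HiChIP loops",
    paste(sprintf("- %s: %s", names(summary$loops),
                  vapply(summary$loops, fmt_num, character(1))),
          collapse = "\n"),
    "",
    "## KLF4 at enhancer anchors",
    sprintf("- %d enhancer anchors with differential KLF4 regulating %d DEG",
            summary$klf4_anchors$n_anchors_diff_klf4,
            summary$klf4_anchors$n_target_deg),
    "",
    "## SNPs in predicted enhancers",
    sprintf("- %d SNPs inside predicted enhancer elements targeting %d genes",
            summary$snps$n_snps_in_elements,
            summary$snps$n_target_genes))
  writeLines(unlist(ln), path)
  invisible(path)
}
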