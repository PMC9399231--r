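## Synthetic two-condition dataset with planted ground truth. The
## generator emulates the statistical structure the analysis assumes:
## KLF-motif enhancers gain (or lose) accessibility and KLF4/BRG1/
## H3K27ac signal under laminar shear stress (LSS) relative to static
## culture (ST); enhancer activity drives linked-gene expression; a
## distance-decaying HiChIP contact map carries planted enhancer-
## promoter loops; SNPs are planted inside enhancers. Truth tables make
## every downstream stage testable without external data.

#' Configuration for the synthetic dataset
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a 10 Mb single-chromosome toy genome, 120 genes, 800
#' candidate accessible regions of which 150 are planted enhancers
#' organised into `n_target_genes` flow-responsive loci (about five
#' enhancers per target gene, 10-100 kb from its TSS, loci spaced far
#' apart so each planted enhancer-gene link is unambiguous), negative-
#' binomial counts (variance = mu + dispersion * mu^2) with a planted
#' |log2FC| of 2 in half the loci up / half down under LSS, and a
#' HiChIP map of `n_pets` pairs per condition whose planted loops are
#' boosted 8-fold under LSS.
#'
#' @param genome_length Genome size in bp (one chromosome "chr1").
#' @param n_genes Number of genes.
#' @param n_candidate_regions Total candidate accessible regions
#'   (planted enhancers + one promoter-proximal region per gene +
#'   background).
#' @param n_planted_enhancers Number of planted enhancer regions.
#' @param n_target_genes Number of flow-responsive target loci the
#'   enhancers are distributed over.
#' @param frac_dar_up Fraction of target loci whose enhancers gain
#'   accessibility under LSS.
#' @param dar_log2fc Planted |log2 fold change| for enhancer
#'   accessibility (and coupled ChIP signal).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param mean_count Baseline ATAC mean count per region.
#' @param replicates Replicates per condition.
#' @param contact_gamma Power-law exponent of the contact decay.
#' @param loop_boost Multiplicative HiChIP boost of planted loops under
#'   LSS (and the structural Hi-C enrichment of planted pairs).
#' @param n_pets HiChIP paired tags per condition (split over
#'   replicates).
#' @param seed Random seed; the generator is a pure function of the
#'   configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(genome_length = 1e7, n_genes = 120L,
                         n_candidate_regions = 800L,
                         n_planted_enhancers = 150L,
                         n_target_genes = 30L,
                         frac_dar_up = 0.5, dar_log2fc = 2.0,
                         nb_dispersion = 0.1, mean_count = 200,
                         replicates = 3L, contact_gamma = 1.0,
                         loop_boost = 8.0, n_pets = 200000L,
                         seed = 1L) {
  cfg <- list(genome_length = as.numeric(genome_length),
              n_genes = as.integer(n_genes),
              n_candidate_regions = as.integer(n_candidate_regions),
              n_planted_enhancers = as.integer(n_planted_enhancers),
              n_target_genes = as.integer(n_target_genes),
              frac_dar_up = frac_dar_up, dar_log2fc = dar_log2fc,
              nb_dispersion = nb_dispersion, mean_count = mean_count,
              replicates = as.integer(replicates),
              contact_gamma = contact_gamma, loop_boost = loop_boost,
              n_pets = as.integer(n_pets), seed = as.integer(seed))
  with(cfg, {
    stopifnot(genome_length >= 1e6, n_genes >= 1,
              n_candidate_regions >= 1, n_planted_enhancers >= 1,
              n_target_genes >= 1, replicates >= 1, n_pets >= 1)
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (mean_count <= 0) stop("mean_count must be > 0")
    if (frac_dar_up < 0 || frac_dar_up > 1)
      stop("frac_dar_up must lie in [0, 1]")
  })
  if (cfg$n_planted_enhancers + cfg$n_genes > cfg$n_candidate_regions)
    stop("n_candidate_regions must cover enhancers plus one promoter ",
         "region per gene")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "synth_config: %.0f bp genome, %d genes (%d targets), %d regions",
    " (%d enhancers), log2FC %.1f, %d+%d reps, seed %d\n"),
    x$genome_length, x$n_genes, x$n_target_genes,
    x$n_candidate_regions, x$n_planted_enhancers, x$dar_log2fc,
    x$replicates, x$replicates, x$seed))
  invisible(x)
}

## the KLF-like GC-rich 10-mer used for motif planting
klf_like_pwm <- function() {
  consensus <- c("G", "G", "G", "G", "C", "G", "G", "G", "G", "C")
  m <- matrix(0.02, 4L, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(consensus)) m[consensus[i], i] <- 0.94
  new_pwm("KLF_like", m)
}

rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## draw `n` positions with pairwise separation >= min_sep inside
## [lo, hi], optionally avoiding existing positions
draw_spaced <- function(n, lo, hi, min_sep, avoid = numeric(0)) {
  if (n * min_sep > (hi - lo))
    stop("infeasible placement: regions exceed genome capacity")
  out <- numeric(0)
  fails <- 0L
  while (length(out) < n) {
    cand <- stats::runif(1L, lo, hi)
    if (!length(out) && !length(avoid) ||
        min(abs(cand - c(out, avoid))) >= min_sep) {
      out <- c(out, cand)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > 2000L)
        stop("infeasible placement: regions exceed genome capacity")
    }
  }
  sort(round(out))
}

## sample HiChIP paired tags from the field
##   lambda(b1, b1 + d) = N * f(d) * w[b1] * w[b1 + d] / Z
## by first drawing distances from the marginal f(d) * S(d), then
## anchors proportional to w[b] * w[b + d]
sample_pets <- function(n, w, f, B) {
  nd <- length(f)
  S <- vapply(seq_len(nd), function(d)
    sum(w[seq_len(B - d)] * w[seq_len(B - d) + d]), numeric(1))
  pd <- f * S
  d_draw <- sample.int(nd, n, replace = TRUE, prob = pd)
  tab <- tabulate(d_draw, nbins = nd)
  b1 <- integer(n); b2 <- integer(n)
  k <- 1L
  for (d in which(tab > 0L)) {
    m <- tab[d]
    idx <- seq_len(B - d)
    cw <- cumsum(w[idx] * w[idx + d])
    u <- stats::runif(m) * cw[length(cw)]
    s <- findInterval(u, cw) + 1L
    b1[k:(k + m - 1L)] <- s - 1L       # 0-based bins
    b2[k:(k + m - 1L)] <- s - 1L + d
    k <- k + m
  }
  list(bin1 = b1, bin2 = b2,
       Z = sum(pd), S = S)
}

#' Generate the synthetic dataset and its truth tables
#'
#' Writes, under `outdir`: candidate regions (narrowPeak), ATAC / KLF4 /
#' BRG1 / H3K27ac count matrices over regions and an RNA count matrix
#' over genes (TSV), the gene table, region sequences (FASTA, uniform
#' base composition with the KLF-like consensus inserted at motif
#' regions), per-condition/replicate HiChIP paired tags (BEDPE), a
#' structural Hi-C contact table at 1 kb (TSV triplets over
#' element-promoter bin pairs, planted pairs enriched `loop_boost`-fold),
#' a SNP table (some SNPs inside planted enhancers, decoys outside all
#' elements), the planting PWM, truth tables (TSV) and a manifest JSON.
#' Output is a pure function of the configuration: the same seed yields
#' byte-identical files.
#'
#' @param cfg A [synth_config].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (data frames `regions`, `genes`, `loops`, `snps`) and `config`.
#' @export
generate_dataset <- function(cfg = synth_config(), outdir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  L <- cfg$genome_length
  chrom <- "chr1"
  n_enh <- cfg$n_planted_enhancers
  n_tgt <- min(cfg$n_target_genes, cfg$n_genes)
  n_prom <- cfg$n_genes
  n_bg <- cfg$n_candidate_regions - n_enh - n_prom
  if (n_bg < 0) stop("infeasible region composition")

  ## --- genes: n_tgt spaced target loci plus background genes ---------
  margin <- min(150000, L / 20)
  slot <- (L - 2 * margin) / n_tgt
  jit <- min(50000, slot / 4)
  tgt_tss <- round(margin + (seq_len(n_tgt) - 0.5) * slot +
                   stats::runif(n_tgt, -jit, jit))
  other_tss <- round(stats::runif(cfg$n_genes - n_tgt, 1000, L - 1000))
  tss <- c(tgt_tss, other_tss)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  glen <- round(stats::runif(cfg$n_genes, 5000, 50000))
  gstart <- ifelse(strand == "+", tss, pmax(0, tss + 1 - glen))
  gend <- ifelse(strand == "+", pmin(L, tss + glen), tss + 1)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                      symbol = sprintf("GENE%d", seq_len(cfg$n_genes)),
                      chrom = chrom, start = as.integer(gstart),
                      end = as.integer(gend), strand = strand,
                      stringsAsFactors = FALSE)
  is_target <- seq_len(cfg$n_genes) <= n_tgt

  ## --- candidate regions ---------------------------------------------
  region_w <- 400L
  ## planted enhancers: ~n_enh/n_tgt per target locus, 10-100 kb from
  ## the target TSS (log-uniform), either side
  enh_gene <- rep(seq_len(n_tgt), length.out = n_enh)
  enh_center <- numeric(n_enh)
  placed <- numeric(0)
  for (i in seq_len(n_enh)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 500L)
        stop("infeasible placement: enhancers exceed genome capacity")
      d <- round(exp(stats::runif(1L, log(10000), log(100000))))
      side <- sample(c(-1L, 1L), 1L)
      cand <- tss[enh_gene[i]] + side * d
      if (cand < 1000 || cand > L - 1000) next
      if (!length(placed) || min(abs(cand - placed)) >= 600) break
    }
    enh_center[i] <- cand
    placed <- c(placed, cand)
  }
  ## promoter-proximal accessible region at every gene
  prom_center <- pmin(pmax(tss + round(stats::runif(n_prom, -300, 300)),
                           region_w / 2 + 1), L - region_w / 2 - 1)
  placed <- c(placed, prom_center)
  ## background accessible regions anywhere not colliding
  bg_center <- draw_spaced(n_bg, 1000, L - 1000, 600, avoid = placed)
  center <- c(enh_center, prom_center, bg_center)
  role <- c(rep("enhancer", n_enh), rep("promoter", n_prom),
            rep("background", n_bg))
  link_gene <- c(genes$gene_id[enh_gene], rep(NA_character_, n_prom + n_bg))
  o <- order(center)
  center <- center[o]; role <- role[o]; link_gene <- link_gene[o]
  rid <- sprintf("region_%04d", seq_along(center))
  start <- as.integer(center - region_w / 2)
  summit_off <- as.integer(region_w / 2 + round(stats::runif(length(rid), -20, 20)))
  regions <- data.frame(chrom = chrom, start = start,
                        end = start + region_w, name = rid,
                        score = 0, strand = ".",
                        signal = 0, summit_offset = summit_off,
                        stringsAsFactors = FALSE)
  is_enh <- role == "enhancer"
  is_promreg <- role == "promoter"

  ## --- planted effects ------------------------------------------------
  n_up_loci <- round(cfg$frac_dar_up * n_tgt)
  locus_sign <- c(rep(1L, n_up_loci), rep(-1L, n_tgt - n_up_loci))
  locus_sign <- locus_sign[sample.int(n_tgt)]
  region_sign <- integer(length(rid))
  region_sign[is_enh] <- locus_sign[match(link_gene[is_enh],
                                          genes$gene_id)]
  region_lfc <- region_sign * cfg$dar_log2fc

  ## motif planting: every enhancer plus a 10% decoy rate elsewhere
  has_motif <- is_enh | stats::runif(length(rid)) < 0.10
  pwm <- klf_like_pwm()

  ## --- count matrices -------------------------------------------------
  reps <- cfg$replicates
  samples <- c(sprintf("LSS_%d", seq_len(reps)),
               sprintf("ST_%d", seq_len(reps)))
  condition <- stats::setNames(rep(c("LSS", "ST"), each = reps), samples)
  nb_matrix <- function(mu_lss, mu_st, ids) {
    m <- cbind(
      matrix(rnb(length(ids) * reps, rep(mu_lss, reps),
                 cfg$nb_dispersion), ncol = reps),
      matrix(rnb(length(ids) * reps, rep(mu_st, reps),
                 cfg$nb_dispersion), ncol = reps))
    dimnames(m) <- list(ids, samples)
    count_matrix(m, condition)
  }
  eff <- 2^region_lfc                       # LSS multiplier at enhancers
  atac_base <- rep(cfg$mean_count, length(rid))
  atac <- nb_matrix(atac_base * eff, atac_base, rid)
  ## H3K27ac: strong at promoters, high at enhancers, low background,
  ## coupled to accessibility at planted enhancers
  k27_base <- ifelse(is_promreg, 15 * cfg$mean_count,
                     ifelse(is_enh, 4 * cfg$mean_count,
                            0.1 * cfg$mean_count))
  k27 <- nb_matrix(k27_base * eff, k27_base, rid)
  ## KLF4 binds motif regions; planted enhancers change with the locus
  klf4_base <- ifelse(has_motif, 0.75 * cfg$mean_count,
                      0.025 * cfg$mean_count)
  klf4 <- nb_matrix(klf4_base * eff, klf4_base, rid)
  ## BRG1 is recruited at enhancers (with KLF4) and present at promoters
  brg1_base <- ifelse(is_enh, 0.75 * cfg$mean_count,
                      ifelse(is_promreg, 0.25 * cfg$mean_count,
                             0.05 * cfg$mean_count))
  brg1 <- nb_matrix(brg1_base * eff, brg1_base, rid)

  ## --- RNA: linked-gene expression driven by enhancer activity --------
  link_weight <- numeric(length(rid))
  link_weight[is_enh] <- stats::runif(sum(is_enh), 0.14, 0.22)
  gene_lfc <- vapply(genes$gene_id, function(g) {
    e <- which(is_enh & link_gene == g)
    if (!length(e)) 0 else sum(link_weight[e] * region_lfc[e])
  }, numeric(1))
  rna_base <- rep(2.5 * cfg$mean_count, cfg$n_genes)
  rna <- nb_matrix(rna_base * 2^gene_lfc, rna_base, genes$gene_id)

  ## --- sequences with planted motifs ----------------------------------
  consensus <- pwm_consensus(pwm)
  seqs <- vapply(seq_along(rid), function(i) {
    s <- random_dna(region_w)
    if (has_motif[i]) {
      at <- summit_off[i] - nchar(consensus) %/% 2L
      substr(s, at + 1L, at + nchar(consensus)) <- consensus
    }
    s
  }, character(1))
  names(seqs) <- rid

  ## --- HiChIP paired tags ---------------------------------------------
  res <- 1000L
  B <- as.integer(ceiling(L / res))
  d_max <- as.integer(min(2e6 / res, B - 1L))
  f <- (seq_len(d_max) * res + 5000)^(-cfg$contact_gamma)
  summit_bin <- (regions$start + regions$summit_offset) %/% res + 1L
  tss_bin <- as.integer(tss) %/% res + 1L      # 1-based bins here
  planted_pairs <- data.frame(
    region_id = rid[is_enh],
    gene_id = link_gene[is_enh],
    bin_e = summit_bin[is_enh] - 1L,           # 0-based for output
    bin_p = tss_bin[match(link_gene[is_enh], genes$gene_id)] - 1L,
    stringsAsFactors = FALSE)
  planted_pairs$bin1 <- pmin(planted_pairs$bin_e, planted_pairs$bin_p)
  planted_pairs$bin2 <- pmax(planted_pairs$bin_e, planted_pairs$bin_p)
  hichip_paths <- character(0)
  pet_files <- list()
  ## per-bin coverage bias follows the baseline H3K27ac level at region
  ## bins (the assay concentrates tags at acetylated peaks); it is the
  ## same in both conditions so differential signal comes only from the
  ## planted loop boost
  w <- rep(0.2, B)
  w[summit_bin] <- w[summit_bin] + k27_base / 100
  for (cond in c("LSS", "ST")) {
    pets <- sample_pets(cfg$n_pets, w, f, B)
    b1 <- pets$bin1; b2 <- pets$bin2
    if (cond == "LSS" && cfg$loop_boost != 1) {
      ## extra tags at planted loops on top of the background field
      d <- planted_pairs$bin2 - planted_pairs$bin1
      lam <- cfg$n_pets * f[d] * w[planted_pairs$bin1 + 1L] *
        w[planted_pairs$bin2 + 1L] / pets$Z
      extra <- stats::rpois(nrow(planted_pairs),
                            (cfg$loop_boost - 1) * lam)
      b1 <- c(b1, rep(planted_pairs$bin1, extra))
      b2 <- c(b2, rep(planted_pairs$bin2, extra))
    }
    n_all <- length(b1)
    rep_of <- sample(rep_len(seq_len(reps), n_all))
    pos1 <- b1 * res + sample.int(res, n_all, replace = TRUE) - 1L
    pos2 <- b2 * res + sample.int(res, n_all, replace = TRUE) - 1L
    for (r in seq_len(reps)) {
      j <- which(rep_of == r)
      bed <- data.frame(chrom1 = chrom, start1 = pos1[j],
                        end1 = pos1[j] + 1L, chrom2 = chrom,
                        start2 = pos2[j], end2 = pos2[j] + 1L,
                        stringsAsFactors = FALSE)
      path <- file.path(outdir, sprintf("hichip_%s_rep%d.bedpe",
                                        cond, r))
      write_loops(bed, path)
      hichip_paths <- c(hichip_paths, path)
      pet_files[[sprintf("%s_%d", cond, r)]] <- path
    }
  }

  ## --- structural Hi-C over element-promoter bin pairs ----------------
  hic_rows <- list()
  depth <- 5e6
  for (g in seq_len(cfg$n_genes)) {
    d_bp <- abs((summit_bin - 1L) - (tss_bin[g] - 1L)) * res
    keep <- d_bp >= res & d_bp <= 2.5e6
    if (!any(keep)) next
    pk <- paste(pmin(summit_bin[keep], tss_bin[g]) - 1L,
                pmax(summit_bin[keep], tss_bin[g]) - 1L)
    boosted <- is_enh[keep] & !is.na(link_gene[keep]) &
      link_gene[keep] == genes$gene_id[g]
    lam <- depth * (d_bp[keep] + 5000)^(-cfg$contact_gamma) *
      ifelse(boosted, cfg$loop_boost, 1)
    hic_rows[[g]] <- data.frame(key = pk, count = stats::rpois(sum(keep), lam))
  }
  hic_all <- do.call(rbind, hic_rows)
  agg <- tapply(hic_all$count, hic_all$key, max)
  kp <- strsplit(names(agg), " ", fixed = TRUE)
  hic <- data.frame(bin1 = as.integer(vapply(kp, `[`, character(1), 1L)),
                    bin2 = as.integer(vapply(kp, `[`, character(1), 2L)),
                    count = as.numeric(agg), stringsAsFactors = FALSE)
  hic <- hic[hic$count > 0, , drop = FALSE]
  hic <- hic[order(hic$bin1, hic$bin2), , drop = FALSE]

  ## --- SNPs: planted inside enhancers plus off-element decoys ---------
  n_snp_in <- min(22L, n_enh)
  snp_enh <- sample(which(is_enh), n_snp_in)
  snp_pos_in <- regions$start[snp_enh] + regions$summit_offset[snp_enh] +
    sample(-100:100, n_snp_in, replace = TRUE)
  decoy_pos <- draw_spaced(8L, 1000, L - 1000, 600,
                           avoid = center)
  ## push decoys well clear of any candidate region
  decoy_pos <- decoy_pos + 0L
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n_snp_in + length(decoy_pos))),
    chrom = chrom,
    pos = as.integer(c(snp_pos_in, decoy_pos)),
    stringsAsFactors = FALSE)
  snp_truth <- data.frame(rsid = snps$rsid,
                          in_enhancer = c(rep(TRUE, n_snp_in),
                                          rep(FALSE, length(decoy_pos))),
                          region_id = c(rid[snp_enh],
                                        rep(NA_character_,
                                            length(decoy_pos))),
                          stringsAsFactors = FALSE)

  ## --- write everything ------------------------------------------------
  paths <- list(
    regions = file.path(outdir, "regions.narrowPeak"),
    atac = file.path(outdir, "atac_counts.tsv"),
    h3k27ac = file.path(outdir, "h3k27ac_counts.tsv"),
    klf4 = file.path(outdir, "klf4_counts.tsv"),
    brg1 = file.path(outdir, "brg1_counts.tsv"),
    rna = file.path(outdir, "rna_counts.tsv"),
    genes = file.path(outdir, "genes.tsv"),
    sequences = file.path(outdir, "sequences.fa"),
    pwm = file.path(outdir, "klf_like.pwm"),
    hic = file.path(outdir, "hic_contacts.tsv"),
    snps = file.path(outdir, "snps.tsv"),
    truth_regions = file.path(outdir, "truth_regions.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"),
    truth_loops = file.path(outdir, "truth_loops.tsv"),
    truth_snps = file.path(outdir, "truth_snps.tsv"),
    manifest = file.path(outdir, "manifest.json"))
  write_regions(regions, paths$regions, "narrowPeak")
  write_counts(atac, paths$atac)
  write_counts(k27, paths$h3k27ac)
  write_counts(klf4, paths$klf4)
  write_counts(brg1, paths$brg1)
  write_counts(rna, paths$rna)
  write_genes(genes, paths$genes)
  write_fasta(seqs, paths$sequences)
  write_pwm(pwm, paths$pwm)
  write_contacts(hic, paths$hic)
  write_snps(snps, paths$snps)

  truth_regions <- data.frame(
    region_id = rid, role = role, is_dar = region_sign != 0L,
    dar_sign = region_sign, true_log2fc = region_lfc,
    has_motif = has_motif, target_gene = link_gene,
    link_weight = ifelse(is_enh, link_weight, NA_real_),
    stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_id = genes$gene_id,
                            is_target = is_target,
                            true_log2fc = gene_lfc,
                            stringsAsFactors = FALSE)
  truth_loops <- planted_pairs[, c("region_id", "gene_id", "bin1",
                                   "bin2")]
  utils::write.table(truth_regions, paths$truth_regions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_loops, paths$truth_loops, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(snp_truth, paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(cfg),
                   files = lapply(paths, basename),
                   hichip = lapply(pet_files, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$hichip <- pet_files
  invisible(list(paths = paths, config = cfg,
                 truth = list(regions = truth_regions,
                              genes = truth_genes,
                              loops = truth_loops,
                              snps = snp_truth)))
}

#' Null count matrix with no true effects
#'
#' Both conditions share identical NB(mean, dispersion) marginals
#' (variance = mean + dispersion * mean^2); a type-I-error harness.
#'
#' @param n_features Number of features (>= 1).
#' @param replicates Replicates per condition.
#' @param mean Mean count (> 0).
#' @param dispersion NB dispersion (> 0).
#' @param seed Random seed.
#' @return A [count_matrix] with conditions LSS and ST.
#' @export
generate_null_counts <- function(n_features, replicates = 3L,
                                 mean = 200, dispersion = 0.1,
                                 seed = 1L) {
  if (n_features < 1L) stop("n_features must be >= 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (mean <= 0) stop("mean must be > 0")
  set.seed(seed)
  samples <- c(sprintf("LSS_%d", seq_len(replicates)),
               sprintf("ST_%d", seq_len(replicates)))
  m <- matrix(rnb(n_features * 2L * replicates, mean, dispersion),
              nrow = n_features,
              dimnames = list(sprintf("f%05d", seq_len(n_features)),
                              samples))
  count_matrix(m, stats::setNames(rep(c("LSS", "ST"),
                                      each = replicates), samples))
}
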