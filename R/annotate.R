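## Peak annotation, nearest-gene distances, DAR-DEG correlation,
## KLF4/BRG1 co-occupancy and SNP-to-enhancer mapping.

#' Annotate peaks by genomic category
#'
#' Each peak is categorised by the position of its centre with precedence
#' promoter > TTS > exon > intron > intergenic. The promoter window is
#' TSS +/- `promoter_bp` (default 3 kb, matching the promoter definition
#' used throughout: within 3 kb of a transcription start site); the TTS
#' window is the transcription end +/- `tts_bp`. "Intron" means inside a
#' gene body without being exon/promoter/TTS; without an `exon_table`
#' no peak is called exonic.
#'
#' @param peaks Interval data frame (peak centres are interval midpoints).
#' @param genes Gene data frame (non-empty).
#' @param exon_table Optional interval data frame of exons.
#' @param promoter_bp,tts_bp Window half-widths in bp.
#' @return A list with `annotation` (per-peak data frame: `peak_id,
#'   category, nearest_gene_id, signed_distance_bp`) and `tally` (named
#'   category counts for the pie-chart report).
#' @export
annotate_peaks <- function(peaks, genes, exon_table = NULL,
                           promoter_bp = 3000L, tts_bp = 1000L) {
  if (nrow(genes) == 0L) stop("genes must be non-empty")
  peak_id <- if ("name" %in% names(peaks)) peaks$name else
    paste0("peak_", seq_len(nrow(peaks)))
  if (nrow(peaks) == 0L)
    return(list(annotation = data.frame(peak_id = character(),
                                        category = character(),
                                        nearest_gene_id = character(),
                                        signed_distance_bp = integer()),
                tally = c(promoter = 0L, TTS = 0L, exon = 0L,
                          intron = 0L, intergenic = 0L)))
  mid <- interval_midpoint(peaks)
  nt <- nearest_tss(peaks, genes)
  tss <- gene_tss(genes)
  tes <- ifelse(genes$strand == "-", as.integer(genes$start),
                as.integer(genes$end) - 1L)  # transcription end site
  category <- rep("intergenic", nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[k])
    if (!length(g)) next
    m <- mid[k]
    if (any(abs(m - tss[g]) <= promoter_bp)) {
      category[k] <- "promoter"
    } else if (any(abs(m - tes[g]) <= tts_bp)) {
      category[k] <- "TTS"
    } else if (!is.null(exon_table) &&
               any(exon_table$chrom == peaks$chrom[k] &
                   exon_table$start <= m & m < exon_table$end)) {
      category[k] <- "exon"
    } else if (any(genes$start[g] <= m & m < genes$end[g])) {
      category[k] <- "intron"
    }
  }
  annotation <- data.frame(peak_id = peak_id, category = category,
                           nearest_gene_id = nt$gene_id,
                           signed_distance_bp = nt$distance,
                           stringsAsFactors = FALSE)
  lvl <- c("promoter", "TTS", "exon", "intron", "intergenic")
  tally <- table(factor(category, levels = lvl))
  list(annotation = annotation,
       tally = stats::setNames(as.integer(tally), lvl))
}

#' Histogram of distances to the nearest TSS
#'
#' Absolute nearest-TSS distances binned into half-open intervals
#' `[lo, hi)`.
#'
#' @param peaks Interval data frame.
#' @param genes Gene data frame.
#' @param bin_edges Increasing numeric vector of edges; the last may be
#'   `Inf`. Default `c(0, 1e3, 1e4, 1e5, 1e6, Inf)`.
#' @return Named integer vector of counts per bin.
#' @export
distance_distribution <- function(peaks, genes,
                                  bin_edges = c(0, 1e3, 1e4, 1e5, 1e6, Inf)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  labs <- paste0("[", utils::head(bin_edges, -1L), ",",
                 bin_edges[-1L], ")")
  if (nrow(peaks) == 0L)
    return(stats::setNames(integer(length(labs)), labs))
  d <- abs(nearest_tss(peaks, genes)$distance)
  d <- d[!is.na(d)]
  idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx < length(bin_edges)],
                     nbins = length(labs))
  stats::setNames(as.integer(counts), labs)
}

#' Correlation between accessibility and nearest-gene expression changes
#'
#' Every significant DAR is paired with its nearest gene; pairs whose
#' gene is a significant DEG are kept (a gene nearest to several DARs
#' contributes one pair per DAR). Returns the Pearson correlation of DAR
#' log2 fold change against DEG log2 fold change with the two-tailed
#' p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param dar_results Differential result for regions ([nb_wald_test]);
#'   `feature_id` must name rows of `dar_regions`.
#' @param deg_results Differential result for genes.
#' @param genes Gene data frame.
#' @param dar_regions Interval data frame for the tested regions, with a
#'   `name` column matching `dar_results$feature_id`.
#' @return List `r`, `p`, `n`, `pairs` (the paired table). Fewer than 3
#'   pairs yields `r = NA, p = NA` with `status = "insufficient"`.
#' @export
dar_deg_correlation <- function(dar_results, deg_results, genes,
                                dar_regions) {
  sig_dar <- dar_results[dar_results$significant, , drop = FALSE]
  reg <- dar_regions[match(sig_dar$feature_id, dar_regions$name), ,
                     drop = FALSE]
  if (nrow(reg) == 0L)
    return(list(r = NA_real_, p = NA_real_, n = 0L,
                pairs = NULL, status = "insufficient"))
  nt <- nearest_tss(reg, genes)
  deg <- deg_results[deg_results$significant, , drop = FALSE]
  keep <- !is.na(nt$gene_id) & nt$gene_id %in% deg$feature_id
  pairs <- data.frame(
    region_id = sig_dar$feature_id[keep],
    gene_id = nt$gene_id[keep],
    dar_log2fc = sig_dar$log2fc[keep],
    deg_log2fc = deg$log2fc[match(nt$gene_id[keep], deg$feature_id)],
    stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L)
    return(list(r = NA_real_, p = NA_real_, n = nrow(pairs),
                pairs = pairs, status = "insufficient"))
  ct <- stats::cor.test(pairs$dar_log2fc, pairs$deg_log2fc,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       pairs = pairs, status = "ok")
}

#' KLF4/BRG1 co-occupancy of differentially accessible regions
#'
#' A DAR carries a factor when it overlaps (>= 1 bp) any region of that
#' factor's differentially bound set. Returns the four-way partition
#' (both / KLF4 only / BRG1 only / neither) with fractions, per-DAR
#' flags, and - when both `klf4_dbr` and the DAR table carry a `log2fc`
#' column - the Pearson correlation of the KLF4 binding change against
#' the accessibility change over co-occupied DARs.
#'
#' @param dar_set Interval data frame of DARs (non-empty); an optional
#'   `log2fc` column enables the signal correlation.
#' @param klf4_dbr,brg1_dbr Interval data frames of differentially bound
#'   regions; `klf4_dbr` may carry `log2fc`.
#' @return List `summary` (counts and fractions), `flags` (per-DAR
#'   logical columns `klf4`, `brg1`), and `delta_cor` (list `r`, `p`, `n`
#'   or NULL).
#' @export
cooccupancy <- function(dar_set, klf4_dbr, brg1_dbr) {
  if (nrow(dar_set) == 0L) stop("empty DAR set")
  hit_any <- function(x, set) {
    if (nrow(set) == 0L) return(rep(FALSE, nrow(x)))
    vapply(seq_len(nrow(x)), function(i)
      any(set$chrom == x$chrom[i] &
          pmin(set$end, x$end[i]) - pmax(set$start, x$start[i]) >= 1L),
      logical(1))
  }
  klf4 <- hit_any(dar_set, klf4_dbr)
  brg1 <- hit_any(dar_set, brg1_dbr)
  n <- nrow(dar_set)
  counts <- c(both = sum(klf4 & brg1), klf4_only = sum(klf4 & !brg1),
              brg1_only = sum(!klf4 & brg1), neither = sum(!klf4 & !brg1))
  delta_cor <- NULL
  if (!is.null(dar_set$log2fc) && !is.null(klf4_dbr$log2fc)) {
    co <- which(klf4 & brg1)
    if (length(co) >= 3L) {
      ## for each co-occupied DAR take the overlapping KLF4 DBR with the
      ## largest |log2fc|
      kfc <- vapply(co, function(i) {
        j <- which(klf4_dbr$chrom == dar_set$chrom[i] &
                   pmin(klf4_dbr$end, dar_set$end[i]) -
                   pmax(klf4_dbr$start, dar_set$start[i]) >= 1L)
        klf4_dbr$log2fc[j][which.max(abs(klf4_dbr$log2fc[j]))]
      }, numeric(1))
      ct <- stats::cor.test(kfc, dar_set$log2fc[co], method = "pearson")
      delta_cor <- list(r = unname(ct$estimate), p = ct$p.value,
                        n = length(co))
    }
  }
  list(summary = list(n_dar = n, counts = counts,
                      fractions = counts / n),
       flags = data.frame(klf4 = klf4, brg1 = brg1),
       delta_cor = delta_cor)
}

#' Map SNPs to enhancer elements and their predicted target genes
#'
#' A SNP is assigned to every element whose half-open interval contains
#' its position; each assignment is expanded over the element's passing
#' ABC target genes.
#'
#' @param snps SNP data frame (`rsid, chrom, pos`).
#' @param predictions ABC prediction table ([abc_scores]) restricted to
#'   passing rows, carrying `element_id, chrom, start, end, gene_id,
#'   score`.
#' @return List `table` (rows `rsid, element_id, gene_id, abc_score`) and
#'   `summary` (`n_snps_in_elements`, `n_target_genes`).
#' @export
snp_overlap <- function(snps, predictions) {
  rows <- list()
  if (nrow(snps) && nrow(predictions)) {
    check_chrom_compat(snps$chrom, predictions$chrom,
                       "SNPs and ABC elements")
    for (i in seq_len(nrow(snps))) {
      j <- which(predictions$chrom == snps$chrom[i] &
                 predictions$start <= snps$pos[i] &
                 snps$pos[i] < predictions$end)
      if (length(j))
        rows[[length(rows) + 1L]] <- data.frame(
          rsid = snps$rsid[i],
          element_id = predictions$element_id[j],
          gene_id = predictions$gene_id[j],
          abc_score = predictions$score[j],
          stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid = character(), element_id = character(),
               gene_id = character(), abc_score = numeric(),
               stringsAsFactors = FALSE)
  list(table = tab,
       summary = list(n_snps_in_elements = length(unique(tab$rsid)),
                      n_target_genes = length(unique(tab$gene_id))))
}
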