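## Activity-by-Contact enhancer-to-gene prediction. Candidate elements
## are summit-centred 250 bp regions (top-N by reads, blacklist-filtered,
## merged); activity is the geometric mean of RPM-normalised ATAC and
## H3K27ac signal; contact is either observed Hi-C at the loop
## resolution (floored at a power law) or the power law itself; the ABC
## score of an element for a gene is its activity x contact share of all
## elements in the gene's window.

#' Build candidate enhancer regions from peaks
#'
#' Applies, in order: resize each peak to `width` bp centred on its
#' summit; rank peaks by read counts and keep the top `top_n` (ties
#' broken deterministically by (chrom, start)); drop regions overlapping
#' the blacklist by >= 1 bp; merge overlapping or book-ended regions.
#'
#' @param peaks Peak data frame with summits (see [read_regions]).
#' @param read_counts Numeric vector of per-peak read counts, either
#'   named by peak `name` or positionally aligned.
#' @param top_n Number of top peaks to retain (default 150000).
#' @param blacklist Optional interval data frame of excluded regions.
#' @param width Resize width in bp (default 250).
#' @return Merged interval data frame of candidate regions.
#' @export
make_candidate_regions <- function(peaks, read_counts, top_n = 150000L,
                                   blacklist = NULL, width = 250L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  counts <- if (!is.null(names(read_counts)))
    read_counts[peaks$name] else read_counts
  if (length(counts) != nrow(peaks) || anyNA(counts))
    stop("read_counts must cover every peak")
  resized <- resize_to_summit(peaks, width)
  o <- order(-counts, resized$chrom, resized$start)
  keep <- o[seq_len(min(top_n, nrow(resized)))]
  resized <- resized[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist)) {
    drop <- vapply(seq_len(nrow(resized)), function(i)
      any(blacklist$chrom == resized$chrom[i] &
          pmin(blacklist$end, resized$end[i]) -
          pmax(blacklist$start, resized$start[i]) >= 1L), logical(1))
    resized <- resized[!drop, , drop = FALSE]
  }
  merge_intervals(resized)
}

#' Assemble ABC elements from candidate regions and gene promoters
#'
#' Every candidate region becomes an element. Elements overlapping a
#' TSS +/- `promoter_halfwidth` window are flagged `is_promoter` and
#' serve as that gene's promoter element; a gene with no such element
#' gets a constructed TSS +/- `promoter_halfwidth` element so the
#' promoter is always present in the score denominator.
#'
#' @param candidates Interval data frame from [make_candidate_regions].
#' @param genes Gene data frame.
#' @param promoter_halfwidth Half-width of the promoter window (250 bp).
#' @return Element data frame: `element_id, chrom, start, end,
#'   is_promoter, promoter_of` (comma-separated gene ids or NA).
#' @export
make_abc_elements <- function(candidates, genes,
                              promoter_halfwidth = 250L) {
  el <- data.frame(element_id = sprintf("el_%05d", seq_len(nrow(candidates))),
                   chrom = candidates$chrom, start = candidates$start,
                   end = candidates$end, is_promoter = FALSE,
                   promoter_of = NA_character_,
                   stringsAsFactors = FALSE)
  tss <- gene_tss(genes)
  extra <- list()
  for (g in seq_len(nrow(genes))) {
    w_start <- max(0L, tss[g] - promoter_halfwidth)
    w_end <- tss[g] + promoter_halfwidth
    j <- which(el$chrom == genes$chrom[g] &
               pmin(el$end, w_end) - pmax(el$start, w_start) >= 1L)
    if (length(j)) {
      el$is_promoter[j] <- TRUE
      el$promoter_of[j] <- ifelse(is.na(el$promoter_of[j]),
                                  genes$gene_id[g],
                                  paste(el$promoter_of[j],
                                        genes$gene_id[g], sep = ","))
    } else {
      extra[[length(extra) + 1L]] <- data.frame(
        element_id = sprintf("prom_%s", genes$gene_id[g]),
        chrom = genes$chrom[g], start = w_start, end = w_end,
        is_promoter = TRUE, promoter_of = genes$gene_id[g],
        stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) el <- rbind(el, do.call(rbind, extra))
  el[order(el$chrom, el$start), , drop = FALSE]
}

## sum counts of the given assay over a condition's replicates, mapped
## onto elements by peak-summit containment
aggregate_element_counts <- function(elements, cm, condition, peaks) {
  j <- which(cm$condition == condition)
  if (!length(j)) stop("no samples for condition ", condition)
  per_feature <- rowSums(cm$counts[, j, drop = FALSE])
  if (all(elements$element_id %in% names(per_feature)))
    return(unname(per_feature[elements$element_id]))
  if (is.null(peaks))
    stop("counts are not keyed by element_id; supply the source peaks")
  summit <- peaks$start + peaks$summit_offset
  pk <- per_feature[peaks$name]
  if (anyNA(pk))
    stop("missing counts for peak(s): ",
         paste(utils::head(peaks$name[is.na(pk)], 3L), collapse = ", "))
  vapply(seq_len(nrow(elements)), function(i) {
    hit <- peaks$chrom == elements$chrom[i] &
      summit >= elements$start[i] & summit < elements$end[i]
    sum(pk[hit])
  }, numeric(1))
}

#' Quantify element activity from ATAC and H3K27ac counts
#'
#' Replicate-summed counts of the requested condition are mapped onto
#' elements (directly when the count matrices are keyed by element id,
#' else by summit containment of the source peaks), each assay is
#' normalised to reads-per-million over the candidate elements, and
#' activity is the geometric mean `sqrt(atac_rpm * h3k27ac_rpm)` (zero
#' whenever either assay is zero).
#'
#' @param elements Element data frame ([make_abc_elements]).
#' @param atac,h3k27ac [count_matrix] objects.
#' @param condition Condition label to quantify.
#' @param peaks Source peak data frame used to map counts onto elements.
#' @return `elements` with added columns `atac_reads, h3k27ac_reads,
#'   activity`.
#' @export
quantify_activity <- function(elements, atac, h3k27ac, condition,
                              peaks = NULL) {
  a <- aggregate_element_counts(elements, atac, condition, peaks)
  h <- aggregate_element_counts(elements, h3k27ac, condition, peaks)
  rpm <- function(x) if (sum(x) > 0) x / sum(x) * 1e6 else x
  elements$atac_reads <- a
  elements$h3k27ac_reads <- h
  elements$activity <- sqrt(rpm(a) * rpm(h))
  elements
}

#' Power-law (optionally Hi-C-informed) contact frequency
#'
#' Without Hi-C, contact between positions at distance `d` is
#' `(d + d0)^(-gamma)`. With Hi-C records, the observed count for the
#' (element bin, TSS bin) pair - normalised so the total observed mass
#' matches the total power-law mass at the observed distances - is used,
#' floored at the power-law value so unobserved bins never drop below
#' the structural expectation. Elements on another chromosome get 0.
#'
#' @param elements Element data frame.
#' @param gene One-row gene data frame.
#' @param hic Optional contact data frame (`bin1, bin2, count`) at
#'   `resolution`.
#' @param gamma,d0 Power-law exponent and offset (defaults 1.0, 5000).
#' @param resolution Bin size of `hic` in bp.
#' @return Numeric vector of contacts, one per element.
#' @export
contact_frequency <- function(elements, gene, hic = NULL, gamma = 1.0,
                              d0 = 5000, resolution = 1000L) {
  tss <- gene_tss(gene)[1L]
  mid <- interval_midpoint(elements)
  d <- abs(mid - tss)
  contact <- (d + d0)^(-gamma)
  contact[elements$chrom != gene$chrom[1L]] <- 0
  if (!is.null(hic) && nrow(hic)) {
    scale <- attr(hic, "contact_scale")
    if (is.null(scale)) {
      hd <- abs(hic$bin2 - hic$bin1) * resolution
      scale <- sum((hd + d0)^(-gamma)) / sum(hic$count)
    }
    key <- function(b1, b2) paste(pmin(b1, b2), pmax(b1, b2))
    obs <- stats::setNames(hic$count * scale, key(hic$bin1, hic$bin2))
    eb <- mid %/% resolution
    tb <- tss %/% resolution
    o <- obs[key(eb, tb)]
    same <- elements$chrom == gene$chrom[1L]
    got <- same & !is.na(o)
    contact[got] <- pmax(o[got], contact[got])
  }
  contact
}

#' Precompute the Hi-C normalisation scale
#'
#' Attaching the scale avoids recomputing it for every gene.
#' @param hic Contact data frame.
#' @param gamma,d0,resolution As in [contact_frequency].
#' @return `hic` with a `contact_scale` attribute.
#' @export
prepare_hic <- function(hic, gamma = 1.0, d0 = 5000, resolution = 1000L) {
  hd <- abs(hic$bin2 - hic$bin1) * resolution
  attr(hic, "contact_scale") <- sum((hd + d0)^(-gamma)) / sum(hic$count)
  hic
}

#' ABC scores of all elements in a gene's window
#'
#' `score(e, g) = A_e * C_eg / sum_{e' in window} A_e' * C_e'g` over the
#' elements whose midpoint lies within TSS +/- `window_bp / 2`. The
#' gene's own promoter element(s) receive the maximum contact observed
#' in the window (self-contact convention). Scores lie in [0, 1] and sum
#' to 1 over the window (all zero when the denominator is zero);
#' `passes` marks scores at or above `threshold`.
#'
#' @param gene One-row gene data frame.
#' @param elements Element data frame with `activity`.
#' @param threshold Passing threshold in (0, 1); default 0.02.
#' @param window_bp Window size centred on the TSS (default 5 Mb).
#' @param hic,gamma,d0,resolution Passed to [contact_frequency].
#' @return Prediction data frame: `element_id, chrom, start, end,
#'   gene_id, is_promoter, activity, contact, score, passes`.
#' @export
abc_scores <- function(gene, elements, threshold = 0.02,
                       window_bp = 5e6, hic = NULL, gamma = 1.0,
                       d0 = 5000, resolution = 1000L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  if (is.null(elements$activity))
    stop("elements need an activity column; run quantify_activity()")
  tss <- gene_tss(gene)[1L]
  mid <- interval_midpoint(elements)
  inwin <- elements$chrom == gene$chrom[1L] &
    abs(mid - tss) <= window_bp / 2
  el <- elements[inwin, , drop = FALSE]
  if (!nrow(el))
    return(data.frame(element_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), is_promoter = logical(),
                      activity = numeric(), contact = numeric(),
                      score = numeric(), passes = logical(),
                      stringsAsFactors = FALSE))
  contact <- contact_frequency(el, gene, hic, gamma, d0, resolution)
  own_prom <- !is.na(el$promoter_of) &
    vapply(strsplit(el$promoter_of, ",", fixed = TRUE),
           function(x) gene$gene_id[1L] %in% x, logical(1))
  if (any(own_prom)) contact[own_prom] <- max(contact)
  prod <- el$activity * contact
  denom <- sum(prod)
  score <- if (denom > 0) prod / denom else rep(0, length(prod))
  data.frame(element_id = el$element_id, chrom = el$chrom,
             start = el$start, end = el$end,
             gene_id = gene$gene_id[1L], is_promoter = el$is_promoter,
             activity = el$activity, contact = contact, score = score,
             passes = score >= threshold, stringsAsFactors = FALSE)
}

#' ABC predictions for a set of genes
#'
#' Concatenates [abc_scores] over genes (optionally restricted to an
#' expressed/DEG list, the convention being to score only expressed
#' genes) and, when a KLF4 differentially-bound set is given, adds a
#' per-element `overlaps_klf4_dbr` flag plus the summary fraction of
#' genes with at least one passing KLF4-bound non-promoter element.
#'
#' @param genes Gene data frame.
#' @param elements Element data frame with `activity`.
#' @param expressed_only Optional character vector of gene ids to score.
#' @param klf4_dbr Optional interval data frame of KLF4 DBRs.
#' @param ... Passed to [abc_scores] (`threshold`, `window_bp`, `hic`,
#'   `gamma`, `d0`, `resolution`).
#' @return List `predictions` (row-bound prediction table) and `summary`
#'   (`n_genes_scored`, and with `klf4_dbr` also
#'   `n_genes_with_klf4_enhancer`, `fraction_klf4_regulated`).
#' @export
predict_all <- function(genes, elements, expressed_only = NULL,
                        klf4_dbr = NULL, ...) {
  g <- genes
  if (!is.null(expressed_only))
    g <- genes[genes$gene_id %in% expressed_only, , drop = FALSE]
  preds <- lapply(seq_len(nrow(g)), function(i)
    abc_scores(g[i, , drop = FALSE], elements, ...))
  tab <- do.call(rbind, preds)
  if (is.null(tab))
    tab <- data.frame(element_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), is_promoter = logical(),
                      activity = numeric(), contact = numeric(),
                      score = numeric(), passes = logical(),
                      stringsAsFactors = FALSE)
  summary <- list(n_genes_scored = nrow(g))
  if (!is.null(klf4_dbr) && nrow(tab)) {
    iv <- tab[, c("chrom", "start", "end")]
    tab$overlaps_klf4_dbr <- vapply(seq_len(nrow(iv)), function(i)
      any(klf4_dbr$chrom == iv$chrom[i] &
          pmin(klf4_dbr$end, iv$end[i]) -
          pmax(klf4_dbr$start, iv$start[i]) >= 1L), logical(1))
    hit <- tab$passes & tab$overlaps_klf4_dbr & !tab$is_promoter
    summary$n_genes_with_klf4_enhancer <-
      length(unique(tab$gene_id[hit]))
    summary$fraction_klf4_regulated <-
      summary$n_genes_with_klf4_enhancer / max(nrow(g), 1L)
  }
  list(predictions = tab, summary = summary)
}
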