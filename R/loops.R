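## HiChIP loop calling at fixed resolution against a distance-decay
## Poisson background with multiplicative anchor-coverage bias, loop
## classification (E-P / E-E / P-P), differential loops through the
## shared NB engine, and KLF4-at-anchor integration.

#' Bin paired contacts at a fixed resolution
#'
#' Each paired tag is assigned to the ordered bin pair
#' `(floor(pos1/res), floor(pos2/res))`. Intra-chromosomal pairs with
#' position separation below `min_distance` are discarded (as are
#' inter-chromosomal pairs: anchors must share a chromosome to be
#' loop candidates).
#'
#' @param pets Data frame of paired tags: either `chrom1, pos1, chrom2,
#'   pos2` or BEDPE columns (`chrom1, start1, end1, chrom2, start2,
#'   end2`, midpoints used).
#' @param resolution Bin size in bp (>= 1, default 1000).
#' @param min_distance Minimum pair separation in bp (default 1000).
#' @return List: `pairs` (data frame `chrom, bin1, bin2, count` with
#'   `bin1 <= bin2`), `coverage` (data frame `chrom, bin, coverage`,
#'   total counts touching each bin), `n_retained`, `resolution`.
#' @export
bin_contacts <- function(pets, resolution = 1000L, min_distance = 1000L) {
  if (resolution < 1L) stop("resolution must be >= 1")
  if (!"pos1" %in% names(pets)) {
    pets$pos1 <- (pets$start1 + pets$end1) %/% 2L
    pets$pos2 <- (pets$start2 + pets$end2) %/% 2L
  }
  keep <- pets$chrom1 == pets$chrom2 &
    abs(pets$pos2 - pets$pos1) >= min_distance
  p <- pets[keep, , drop = FALSE]
  b1 <- p$pos1 %/% resolution
  b2 <- p$pos2 %/% resolution
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  if (!nrow(p)) {
    empty_pairs <- data.frame(chrom = character(), bin1 = integer(),
                              bin2 = integer(), count = integer(),
                              stringsAsFactors = FALSE)
    return(list(pairs = empty_pairs,
                coverage = data.frame(chrom = character(),
                                      bin = integer(),
                                      coverage = numeric()),
                n_retained = 0L, resolution = resolution))
  }
  key <- paste(p$chrom1, lo, hi)
  agg <- table(key)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  pairs <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    bin1 = as.integer(vapply(parts, `[`, character(1), 2L)),
    bin2 = as.integer(vapply(parts, `[`, character(1), 3L)),
    count = as.integer(agg), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$chrom, pairs$bin1, pairs$bin2), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  cov_key <- c(paste(pairs$chrom, pairs$bin1),
               paste(pairs$chrom, pairs$bin2))
  cov <- tapply(rep(pairs$count, 2L), cov_key, sum)
  cparts <- strsplit(names(cov), " ", fixed = TRUE)
  coverage <- data.frame(
    chrom = vapply(cparts, `[`, character(1), 1L),
    bin = as.integer(vapply(cparts, `[`, character(1), 2L)),
    coverage = as.numeric(cov), stringsAsFactors = FALSE)
  list(pairs = pairs, coverage = coverage,
       n_retained = sum(pairs$count), resolution = resolution)
}

## weighted pool-adjacent-violators for a non-increasing fit
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1L) return(y)
  ## stack-based PAVA on blocks
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_len(n)) {
    cv <- y[i]; cw <- w[i]; cs <- 1L
    while (length(vals) && vals[length(vals)] < cv) {
      cv <- (cv * cw + vals[length(vals)] * wts[length(wts)]) /
        (cw + wts[length(wts)])
      cw <- cw + wts[length(wts)]
      cs <- cs + sizes[length(sizes)]
      vals <- vals[-length(vals)]; wts <- wts[-length(wts)]
      sizes <- sizes[-length(sizes)]
    }
    vals <- c(vals, cv); wts <- c(wts, cw); sizes <- c(sizes, cs)
  }
  rep(vals, sizes)
}

#' Fit a distance-decay background with anchor coverage bias
#'
#' Distances (in bins) are grouped into log-spaced bins; the raw mean
#' count per distance bin is computed over all observed and possible
#' bin pairs within the span of the data, then made monotone
#' non-increasing by pool-adjacent-violators (weighted by the number of
#' possible pairs). Anchor bias is each bin's coverage divided by the
#' mean coverage over the spanned bins.
#'
#' @param binned Output of [bin_contacts].
#' @param n_dist_bins Number of log-spaced distance bins (default 50).
#' @param max_distance Only pairs within this separation (bp) inform the
#'   fit (default 2 Mb, the same span that is tested).
#' @return A `decay_model`: list with `edges` (distance-bin edges, bp),
#'   `expected` (monotone mean count per distance bin), `bias` (data
#'   frame `chrom, bin, bias`), `span` (per-chrom bin count),
#'   `resolution`, `mean_cov`.
#' @export
fit_decay <- function(binned, n_dist_bins = 50L, max_distance = 2e6) {
  pairs <- binned$pairs
  if (!nrow(pairs)) stop("no observed pairs")
  res <- binned$resolution
  d_bp <- (pairs$bin2 - pairs$bin1) * res
  keep <- d_bp <= max_distance
  pairs <- pairs[keep, , drop = FALSE]
  d_bp <- d_bp[keep]
  if (!nrow(pairs)) stop("no observed pairs within max_distance")
  span <- tapply(pairs$bin2, pairs$chrom, max) + 1L  # bins per chrom
  dmin <- max(min(d_bp), res)
  dmax <- max(d_bp)
  edges <- if (dmax > dmin)
    exp(seq(log(dmin), log(dmax), length.out = n_dist_bins + 1L))
  else c(dmin, dmin + res)
  edges[length(edges)] <- edges[length(edges)] + 1  # include dmax
  ib <- findInterval(d_bp, edges, rightmost.closed = FALSE)
  ib[ib < 1L] <- 1L; ib[ib > length(edges) - 1L] <- length(edges) - 1L
  obs_sum <- tapply(pairs$count, factor(ib, levels = seq_len(length(edges) - 1L)), sum)
  obs_sum[is.na(obs_sum)] <- 0
  ## possible pairs per distance bin: for bin-distance d on a chrom with
  ## B bins there are B - d ordered pairs
  n_possible <- numeric(length(edges) - 1L)
  for (ch in names(span)) {
    B <- span[[ch]]
    dseq <- seq_len(min(B - 1L, floor(max_distance / res)))
    db <- dseq * res
    k <- findInterval(db, edges, rightmost.closed = FALSE)
    ok <- k >= 1L & k <= length(n_possible)
    n_possible <- n_possible + as.numeric(
      tapply(pmax(B - dseq[ok], 0L),
             factor(k[ok], levels = seq_along(n_possible)), sum,
             default = 0))
  }
  n_possible[is.na(n_possible) | n_possible == 0] <- NA
  raw <- as.numeric(obs_sum) / n_possible
  use <- !is.na(raw)
  expected <- rep(NA_real_, length(raw))
  expected[use] <- pava_nonincreasing(raw[use], n_possible[use])
  cov <- binned$coverage
  mean_cov <- sum(cov$coverage) / sum(span)
  cov$bias <- cov$coverage / mean_cov
  structure(list(edges = edges, expected = expected, bias = cov,
                 span = span, resolution = res, mean_cov = mean_cov,
                 max_distance = max_distance),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "decay_model: %d distance bins over [%g, %g) bp, %d anchor bins\n",
    sum(!is.na(x$expected)), x$edges[1L],
    x$edges[length(x$edges)], nrow(x$bias)))
  invisible(x)
}

decay_base <- function(decay, d_bp) {
  k <- findInterval(d_bp, decay$edges, rightmost.closed = FALSE)
  k[k < 1L] <- 1L
  k[k > length(decay$expected)] <- length(decay$expected)
  base <- decay$expected[k]
  ## fall back to the nearest fitted bin for any empty distance bin
  if (anyNA(base)) {
    filled <- which(!is.na(decay$expected))
    nearest <- vapply(k[is.na(base)], function(i)
      filled[which.min(abs(filled - i))], integer(1))
    base[is.na(base)] <- decay$expected[nearest]
  }
  base
}

## expected count per pair with leave-self-out coverage bias: a pair's
## own count is removed from both anchors' coverage so a strong loop
## does not absorb itself into its background
decay_expected <- function(decay, chrom, bin1, bin2, count = NULL) {
  base <- decay_base(decay, (bin2 - bin1) * decay$resolution)
  bkey <- paste(decay$bias$chrom, decay$bias$bin)
  cov <- stats::setNames(decay$bias$coverage, bkey)
  c1 <- cov[paste(chrom, bin1)]; c2 <- cov[paste(chrom, bin2)]
  c1[is.na(c1)] <- 0; c2[is.na(c2)] <- 0
  if (!is.null(count)) {
    c1 <- c1 - count
    c2 <- c2 - count
  }
  b1 <- pmax(c1, 0.5) / decay$mean_cov
  b2 <- pmax(c2, 0.5) / decay$mean_cov
  unname(base * b1 * b2)
}

## number of possible intra-chromosomal bin pairs within the tested span
n_possible_pairs <- function(span, resolution, max_distance) {
  total <- 0
  for (B in span) {
    dmax <- min(B - 1L, floor(max_distance / resolution))
    if (dmax >= 1L)
      total <- total + sum(B - seq_len(dmax))
  }
  total
}

#' Call significant loops against the decay background
#'
#' For every observed bin pair within the tested span, the expected
#' count is `decay(distance) * bias_i * bias_j`, where the anchor biases
#' leave the pair's own count out of the coverage so strong loops do not
#' absorb themselves into their background. The p-value is the
#' upper-tail Poisson `P(X >= k | expected)`; the BH step-up runs over
#' the full universe of testable pairs within `max_distance` (pairs with
#' zero counts have p = 1 and enter only through the correction's m).
#' Loops are the pairs with `q < q_threshold`.
#'
#' @param binned Output of [bin_contacts].
#' @param decay A `decay_model` fitted from the same condition's data.
#' @param q_threshold FDR threshold in (0, 1) (default 0.01).
#' @param max_distance Maximum tested separation in bp (default 2 Mb).
#' @return List `loops` (significant pairs) and `tested` (all tested
#'   pairs with `count, expected, p, q`); anchors are materialised as
#'   `chrom, start1, end1, start2, end2` bin intervals.
#' @export
call_loops <- function(binned, decay, q_threshold = 0.01,
                       max_distance = 2e6) {
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  res <- binned$resolution
  pairs <- binned$pairs
  keep <- (pairs$bin2 - pairs$bin1) * res <= max_distance
  pairs <- pairs[keep, , drop = FALSE]
  expected <- decay_expected(decay, pairs$chrom, pairs$bin1, pairs$bin2,
                             pairs$count)
  p <- stats::ppois(pairs$count - 1L, expected, lower.tail = FALSE)
  ## BH over every testable pair in the span: unobserved pairs carry
  ## p = 1 and only contribute to the correction's m, so the step-up is
  ## computed with m = number of possible pairs within max_distance
  m_total <- max(n_possible_pairs(decay$span, res, max_distance),
                 length(p))
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m_total * p[o] / seq_along(o)))), 1)
  q <- numeric(length(p)); q[o] <- q_sorted
  tested <- data.frame(chrom = pairs$chrom,
                       bin1 = pairs$bin1, bin2 = pairs$bin2,
                       start1 = pairs$bin1 * res,
                       end1 = (pairs$bin1 + 1L) * res,
                       start2 = pairs$bin2 * res,
                       end2 = (pairs$bin2 + 1L) * res,
                       count = pairs$count, expected = expected,
                       p = p, q = q, stringsAsFactors = FALSE)
  tested$loop_id <- sprintf("%s:%d-%d", tested$chrom, tested$bin1,
                            tested$bin2)
  list(loops = tested[tested$q < q_threshold, , drop = FALSE],
       tested = tested)
}

classify_anchor <- function(chrom, start, end, tss_windows, k27_peaks) {
  is_p <- any(tss_windows$chrom == chrom &
              pmin(tss_windows$end, end) -
              pmax(tss_windows$start, start) >= 1L)
  if (is_p) return("P")
  is_e <- nrow(k27_peaks) > 0L &&
    any(k27_peaks$chrom == chrom &
        pmin(k27_peaks$end, end) - pmax(k27_peaks$start, start) >= 1L)
  if (is_e) "E" else "other"
}

#' Classify loops as enhancer-promoter, enhancer-enhancer or
#' promoter-promoter
#'
#' An anchor is "P" when it overlaps any TSS +/- `promoter_bp` window,
#' "E" when it instead overlaps an H3K27ac peak. Loop classes follow the
#' anchor pair: {E,P} -> EP, {E,E} -> EE, {P,P} -> PP, else "other". EP
#' loops carry the target gene(s) whose promoter window the P anchor
#' hits (comma-separated).
#'
#' @param loops Loop data frame from [call_loops] (needs `chrom, start1,
#'   end1, start2, end2`).
#' @param h3k27ac_peaks Interval data frame of H3K27ac peaks.
#' @param genes Gene data frame.
#' @param promoter_bp Promoter half-width (default 3000).
#' @return `loops` with `anchor1_class, anchor2_class, loop_class,
#'   target_gene` columns.
#' @export
classify_loops <- function(loops, h3k27ac_peaks, genes,
                           promoter_bp = 3000L) {
  tss <- gene_tss(genes)
  tssw <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, tss - promoter_bp),
                     end = tss + promoter_bp + 1L,
                     gene_id = genes$gene_id, stringsAsFactors = FALSE)
  n <- nrow(loops)
  a1 <- character(n); a2 <- character(n); tg <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a1[i] <- classify_anchor(loops$chrom[i], loops$start1[i],
                             loops$end1[i], tssw, h3k27ac_peaks)
    a2[i] <- classify_anchor(loops$chrom[i], loops$start2[i],
                             loops$end2[i], tssw, h3k27ac_peaks)
    cls <- paste(sort(c(a1[i], a2[i])), collapse = "")
    if (cls == "EP") {
      ps <- if (a1[i] == "P") c(loops$start1[i], loops$end1[i]) else
        c(loops$start2[i], loops$end2[i])
      g <- tssw$gene_id[tssw$chrom == loops$chrom[i] &
                        pmin(tssw$end, ps[2L]) -
                        pmax(tssw$start, ps[1L]) >= 1L]
      tg[i] <- paste(sort(g), collapse = ",")
    }
  }
  cls <- vapply(seq_len(n), function(i) {
    s <- sort(c(a1[i], a2[i]))
    if (all(s == c("E", "P"))) "EP"
    else if (all(s == c("E", "E"))) "EE"
    else if (all(s == c("P", "P"))) "PP"
    else "other"
  }, character(1))
  loops$anchor1_class <- a1
  loops$anchor2_class <- a2
  loops$loop_class <- cls
  loops$target_gene <- tg
  loops
}

#' Differential loop testing between conditions
#'
#' Builds a loops x samples count matrix from per-replicate binned
#' contacts (a loop absent from a sample contributes 0), normalises by
#' each sample's total retained pairs, and runs the shared NB Wald test.
#' "Gained" means significant with positive log2 fold change of the
#' numerator condition; "lost" the opposite; all else "stable".
#'
#' @param loops Loop data frame with `loop_id, chrom, bin1, bin2`.
#' @param binned_by_sample Named list of [bin_contacts] outputs, one per
#'   sample (replicate).
#' @param condition_of Named character vector, sample -> condition.
#' @param alpha Significance threshold on `padj` (default 0.1).
#' @param numerator_condition Fold-change numerator (default "LSS").
#' @return `loops` with `log2fc, pvalue, padj, differential` columns.
#' @export
differential_loops <- function(loops, binned_by_sample, condition_of,
                               alpha = 0.1,
                               numerator_condition = "LSS") {
  if (!nrow(loops)) {
    loops$log2fc <- numeric(0); loops$pvalue <- numeric(0)
    loops$padj <- numeric(0); loops$differential <- character(0)
    return(loops)
  }
  key <- paste(loops$chrom, loops$bin1, loops$bin2)
  counts <- vapply(binned_by_sample, function(b) {
    bk <- paste(b$pairs$chrom, b$pairs$bin1, b$pairs$bin2)
    v <- b$pairs$count[match(key, bk)]
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(nrow(loops)))
  counts <- matrix(counts, nrow = nrow(loops),
                   dimnames = list(loops$loop_id,
                                   names(binned_by_sample)))
  totals <- vapply(binned_by_sample, function(b) b$n_retained,
                   numeric(1))
  cm <- count_matrix(counts, condition_of)
  res <- nb_wald_test(cm, alpha_sig = alpha,
                      numerator_condition = numerator_condition,
                      size_factors = totals)
  loops$log2fc <- res$log2fc[match(loops$loop_id, res$feature_id)]
  loops$pvalue <- res$pvalue[match(loops$loop_id, res$feature_id)]
  loops$padj <- res$padj[match(loops$loop_id, res$feature_id)]
  loops$differential <- ifelse(!res$significant, "stable",
                               ifelse(res$log2fc > 0, "gained", "lost"))
  loops
}

#' KLF4 binding at enhancer anchors of EP loops
#'
#' For each EP loop, the enhancer anchor is intersected with the KLF4
#' differentially-bound regions (on multiple overlaps the DBR with the
#' largest |log2fc| is reported; no overlap gives 0) and joined with the
#' target gene's differential-expression result. A second loop set
#' (e.g. from a KLF-knockdown run) flags anchors lost between runs.
#'
#' @param ep_loops Classified loops ([classify_loops]) restricted to or
#'   containing EP loops.
#' @param klf4_dbr Interval data frame with a `log2fc` column.
#' @param deg_results Differential result table for genes.
#' @param second_loops Optional second classified loop set; an anchor
#'   present here is "retained", otherwise "lost".
#' @return List `table` (per EP loop and target gene: `loop_id,
#'   enhancer_start, enhancer_end, klf4_log2fc, gene_id, gene_log2fc,
#'   gene_padj[, lost_in_second]`) and `summary`
#'   (`n_anchors_diff_klf4`, `n_target_deg`).
#' @export
klf4_at_anchors <- function(ep_loops, klf4_dbr, deg_results,
                            second_loops = NULL) {
  ep <- ep_loops[ep_loops$loop_class == "EP", , drop = FALSE]
  rows <- list()
  second_ids <- if (!is.null(second_loops)) second_loops$loop_id else NULL
  for (i in seq_len(nrow(ep))) {
    e_is_1 <- ep$anchor1_class[i] == "E"
    es <- if (e_is_1) ep$start1[i] else ep$start2[i]
    ee <- if (e_is_1) ep$end1[i] else ep$end2[i]
    kfc <- 0
    if (nrow(klf4_dbr)) {
      j <- which(klf4_dbr$chrom == ep$chrom[i] &
                 pmin(klf4_dbr$end, ee) - pmax(klf4_dbr$start, es) >= 1L)
      if (length(j))
        kfc <- klf4_dbr$log2fc[j][which.max(abs(klf4_dbr$log2fc[j]))]
    }
    genes_i <- strsplit(ep$target_gene[i], ",", fixed = TRUE)[[1L]]
    for (g in genes_i) {
      k <- match(g, deg_results$feature_id)
      rows[[length(rows) + 1L]] <- data.frame(
        loop_id = ep$loop_id[i], chrom = ep$chrom[i],
        enhancer_start = es, enhancer_end = ee, klf4_log2fc = kfc,
        gene_id = g,
        gene_log2fc = if (!is.na(k)) deg_results$log2fc[k] else NA_real_,
        gene_padj = if (!is.na(k)) deg_results$padj[k] else NA_real_,
        gene_significant = if (!is.na(k)) deg_results$significant[k]
          else FALSE,
        lost_in_second = if (!is.null(second_ids))
          !(ep$loop_id[i] %in% second_ids) else NA,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(loop_id = character(), chrom = character(),
               enhancer_start = integer(), enhancer_end = integer(),
               klf4_log2fc = numeric(), gene_id = character(),
               gene_log2fc = numeric(), gene_padj = numeric(),
               gene_significant = logical(), lost_in_second = logical(),
               stringsAsFactors = FALSE)
  list(table = tab,
       summary = list(
         n_anchors_diff_klf4 = length(unique(
           tab$loop_id[tab$klf4_log2fc != 0])),
         n_target_deg = length(unique(
           tab$gene_id[tab$gene_significant %in% TRUE &
                       tab$klf4_log2fc != 0]))))
}
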