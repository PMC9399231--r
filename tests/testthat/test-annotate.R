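ann_genes <- function() {
  data.frame(gene_id = c("g1", "g2"), symbol = c("A", "B"),
             chrom = "chr1", start = c(50000L, 200000L),
             end = c(80000L, 240000L), strand = c("+", "-"),
             stringsAsFactors = FALSE)
}

test_that("peak categories follow the stated precedence", {
  genes <- ann_genes()
  peaks <- gintervals("chr1",
                      c(49900, 78900, 60000, 500000, 239800),
                      c(50100, 79100, 60200, 500200, 240000))
  ann <- annotate_peaks(peaks, genes)$annotation
  ## centred on TSS -> promoter; near gene end -> TTS; inside body ->
  ## intron; 260 kb away -> intergenic; minus-strand TSS -> promoter
  expect_equal(ann$category,
               c("promoter", "TTS", "intron", "intergenic", "promoter"))
  ## with an exon table, exonic beats intronic
  exons <- gintervals("chr1", 59990, 60210)
  ann2 <- annotate_peaks(peaks, genes, exon_table = exons)$annotation
  expect_equal(ann2$category[3], "exon")
  ## tally partitions the peaks
  expect_equal(sum(annotate_peaks(peaks, genes)$tally), nrow(peaks))
})

test_that("annotation matches a rule-by-rule reference on random peaks", {
  set.seed(37)
  genes <- random_genes(30, chroms = "chr1", max_pos = 500000L)
  peaks <- random_intervals(500, chroms = "chr1", max_pos = 500000L)
  got <- annotate_peaks(peaks, genes, promoter_bp = 3000,
                        tts_bp = 1000)$annotation
  tss <- gene_tss(genes)
  tes <- ifelse(genes$strand == "-", genes$start, genes$end - 1L)
  for (i in seq_len(nrow(peaks))) {
    m <- peaks$start[i] + (peaks$end[i] - peaks$start[i]) %/% 2L
    want <- if (any(abs(m - tss) <= 3000)) "promoter"
      else if (any(abs(m - tes) <= 1000)) "TTS"
      else if (any(genes$start <= m & m < genes$end)) "intron"
      else "intergenic"
    expect_identical(got$category[i], want)
  }
})

test_that("distance histogram equals direct binning", {
  genes <- ann_genes()
  edges <- c(0, 1e3, 1e4, 1e5, 1e6, Inf)
  ## all peaks on a TSS -> all mass in the first bin
  on_tss <- gintervals("chr1", c(49950, 49900), c(50050, 50100))
  h <- distance_distribution(on_tss, genes, edges)
  expect_equal(unname(h), c(2L, 0L, 0L, 0L, 0L))
  ## empty peak set -> all-zero histogram
  h0 <- distance_distribution(on_tss[0, ], genes, edges)
  expect_equal(sum(h0), 0L)
  expect_error(distance_distribution(on_tss, genes, c(0, 10, 5)),
               "increasing")
  set.seed(41)
  peaks <- random_intervals(300, chroms = "chr1", max_pos = 3e6)
  got <- distance_distribution(peaks, genes, edges)
  d <- abs(nearest_tss(peaks, genes)$distance)
  want <- vapply(seq_len(5), function(k)
    sum(d >= edges[k] & d < edges[k + 1]), integer(1))
  expect_equal(unname(got), want)
})

test_that("DAR-DEG correlation handles exact lines and small inputs", {
  set.seed(47)
  genes <- random_genes(10, chroms = "chr1", max_pos = 100000L)
  tss <- gene_tss(genes)
  regions <- data.frame(chrom = "chr1", start = tss, end = tss + 100L,
                        name = sprintf("r%02d", seq_len(10)),
                        stringsAsFactors = FALSE)
  lfc <- seq(-2, 2.5, length.out = 10)
  dar <- data.frame(feature_id = regions$name, base_mean = 100,
                    log2fc = lfc, se = 0.1, pvalue = 1e-6, padj = 1e-5,
                    significant = TRUE, stringsAsFactors = FALSE)
  deg_pos <- data.frame(feature_id = genes$gene_id, base_mean = 100,
                        log2fc = 2 * lfc + 1, se = 0.1, pvalue = 1e-6,
                        padj = 1e-5, significant = TRUE,
                        stringsAsFactors = FALSE)
  r1 <- dar_deg_correlation(dar, deg_pos, genes, regions)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  deg_neg <- deg_pos
  deg_neg$log2fc <- -lfc
  expect_equal(dar_deg_correlation(dar, deg_neg, genes, regions)$r, -1,
               tolerance = 1e-12)
  ## order of inputs does not matter
  perm <- sample.int(10)
  r2 <- dar_deg_correlation(dar[perm, ], deg_pos, genes, regions)
  expect_equal(r2$r, r1$r, tolerance = 1e-12)
  ## fewer than 3 usable pairs is a defined "insufficient" result
  few <- dar[1:2, ]
  out <- dar_deg_correlation(few, deg_pos, genes, regions)
  expect_equal(out$status, "insufficient")
  expect_true(is.na(out$r))
})

test_that("co-occupancy partitions DARs and matches brute force", {
  set.seed(43)
  dar <- random_intervals(300, chroms = "chr1", max_pos = 50000L)
  dar$log2fc <- stats::rnorm(300)
  expect_error(cooccupancy(dar[0, ], dar, dar), "empty DAR")
  ## identical sets: all co-occupied; disjoint: all neither
  same <- cooccupancy(dar, dar, dar)
  expect_equal(unname(same$summary$fractions["both"]), 1)
  far <- dar
  far$start <- far$start + 1000000L
  far$end <- far$end + 1000000L
  none <- cooccupancy(dar, far, far)
  expect_equal(unname(none$summary$fractions["neither"]), 1)
  ## random sets: four-way partition equals the brute-force overlap
  ## matrix and always sums to n
  klf4 <- random_intervals(80, chroms = "chr1", max_pos = 50000L)
  klf4$log2fc <- stats::rnorm(80)
  brg1 <- random_intervals(80, chroms = "chr1", max_pos = 50000L)
  got <- cooccupancy(dar, klf4, brg1)
  expect_equal(sum(got$summary$counts), 300L)
  bf <- function(x, set) vapply(seq_len(nrow(x)), function(i)
    any(vapply(seq_len(nrow(set)), function(j)
      oracle_overlap(x[i, ], set[j, ]), logical(1))), logical(1))
  k <- bf(dar, klf4); b <- bf(dar, brg1)
  expect_equal(unname(got$summary$counts["both"]), sum(k & b))
  expect_equal(unname(got$summary$counts["neither"]), sum(!k & !b))
  expect_equal(got$flags$klf4, k)
})

test_that("SNP assignment respects half-open element boundaries", {
  preds <- data.frame(element_id = "el_1", chrom = "chr1", start = 100L,
                      end = 200L, gene_id = "g1", score = 0.4,
                      stringsAsFactors = FALSE)
  at_start <- data.frame(rsid = "rs1", chrom = "chr1", pos = 100L)
  at_end <- data.frame(rsid = "rs2", chrom = "chr1", pos = 200L)
  expect_equal(nrow(snp_overlap(at_start, preds)$table), 1L)
  expect_equal(nrow(snp_overlap(at_end, preds)$table), 0L)
  both <- snp_overlap(rbind(at_start, at_end), preds)
  expect_equal(both$summary$n_snps_in_elements, 1L)
  expect_equal(both$summary$n_target_genes, 1L)
})
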