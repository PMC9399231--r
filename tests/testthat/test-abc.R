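toy_peaks <- function(n, max_pos = 1e6, width = 400L) {
  start <- sort(sample.int(max_pos - width, n))
  data.frame(chrom = "chr1", start = start, end = start + width,
             name = sprintf("pk%04d", seq_len(n)), score = 0,
             strand = ".", signal = 0,
             summit_offset = sample.int(width, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}

test_that("candidate regions follow resize -> top-N -> blacklist -> merge", {
  set.seed(51)
  peaks <- toy_peaks(10)
  counts <- stats::setNames(rep(5, 10), peaks$name)
  cand <- make_candidate_regions(peaks, counts, top_n = 10)
  expect_true(all(cand$end - cand$start >= 250L))
  expect_error(make_candidate_regions(peaks, counts, top_n = 0),
               "top_n")
  ## two resized regions overlapping by 50 bp merge to width 450
  p2 <- data.frame(chrom = "chr1", start = c(1000L, 1200L),
                   end = c(1400L, 1600L), name = c("a", "b"),
                   summit_offset = c(200L, 200L),
                   stringsAsFactors = FALSE)
  m <- make_candidate_regions(p2, c(a = 1, b = 1), top_n = 10)
  expect_equal(nrow(m), 1L)
  expect_equal(m$end - m$start, 450L)
  ## top-N keeps the highest-count peaks with deterministic ties
  c3 <- stats::setNames(c(10, rep(1, 9)), peaks$name)
  top1 <- make_candidate_regions(peaks, c3, top_n = 1)
  s1 <- peaks$start[1] + peaks$summit_offset[1]
  expect_equal(top1$start, max(0L, s1 - 125L))
  ## blacklisted regions are dropped before merging
  bl <- gintervals("chr1", top1$start, top1$end)
  none <- make_candidate_regions(peaks[1, ], c3[1], top_n = 5,
                                 blacklist = bl)
  expect_equal(nrow(none), 0L)
})

test_that("candidate construction matches an independent step replay", {
  set.seed(53)
  peaks <- toy_peaks(2000, max_pos = 5e6)
  counts <- stats::setNames(sample.int(50, 2000, replace = TRUE),
                            peaks$name)
  bl <- random_intervals(20, chroms = "chr1", max_pos = 5e6,
                         max_len = 2000L)
  got <- make_candidate_regions(peaks, counts, top_n = 1500,
                                blacklist = bl, width = 250)
  ## independent replay of the printed order of operations
  summit <- peaks$start + peaks$summit_offset
  rs <- pmax(0L, summit - 125L)
  re <- rs + 250L
  o <- order(-counts, peaks$chrom, rs)
  keep <- sort(o[1:1500])
  drop <- vapply(keep, function(i)
    any(bl$start < re[i] & rs[i] < bl$end), logical(1))
  keep <- keep[!drop]
  ## naive merge by sweeping sorted intervals
  ms <- rs[keep]; me <- re[keep]
  ord <- order(ms)
  ms <- ms[ord]; me <- me[ord]
  out_s <- ms[1]; out_e <- me[1]
  for (i in seq_along(ms)[-1]) {
    if (ms[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], me[i])
    } else {
      out_s <- c(out_s, ms[i]); out_e <- c(out_e, me[i])
    }
  }
  expect_equal(got$start, out_s)
  expect_equal(got$end, out_e)
})

test_that("activity is the geometric mean of RPM-normalised assays", {
  peaks <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(1400L, 5400L), name = c("a", "b"),
                      summit_offset = c(200L, 200L),
                      stringsAsFactors = FALSE)
  el <- data.frame(element_id = c("e1", "e2"), chrom = "chr1",
                   start = c(1000L, 5000L), end = c(1400L, 5400L),
                   is_promoter = FALSE, promoter_of = NA_character_,
                   stringsAsFactors = FALSE)
  mk <- function(v) {
    m <- matrix(rep(v, 2), 2, 2,
                dimnames = list(c("a", "b"), c("LSS_1", "LSS_2")))
    count_matrix(m, c(LSS_1 = "LSS", LSS_2 = "LSS"))
  }
  ## equal assays: activity equals the shared RPM value
  q <- quantify_activity(el, mk(c(30, 70)), mk(c(30, 70)), "LSS",
                         peaks)
  expect_equal(q$activity, c(30, 70) / 100 * 1e6, tolerance = 1e-9)
  ## zero in either assay gives zero activity
  q0 <- quantify_activity(el, mk(c(0, 70)), mk(c(30, 70)), "LSS",
                          peaks)
  expect_equal(q0$activity[1], 0)
  ## random values equal the direct formula
  set.seed(57)
  a <- c(12, 88); h <- c(40, 10)
  q2 <- quantify_activity(el, mk(a), mk(h), "LSS", peaks)
  expect_equal(q2$activity,
               sqrt((2 * a / sum(2 * a) * 1e6) *
                    (2 * h / sum(2 * h) * 1e6)), tolerance = 1e-9)
})

test_that("power-law contact has the stated arithmetic", {
  gene <- data.frame(gene_id = "g1", symbol = "G", chrom = "chr1",
                     start = 100000L, end = 120000L, strand = "+",
                     stringsAsFactors = FALSE)
  el <- data.frame(element_id = c("e1", "e2", "e3"), chrom = "chr1",
                   start = c(104900L, 299900L, 499900L),
                   end = c(105100L, 300100L, 500100L),
                   is_promoter = FALSE, promoter_of = NA_character_,
                   stringsAsFactors = FALSE)
  ## distance 5000, gamma 1, d0 5000 -> 1/10000
  cf <- contact_frequency(el, gene)
  expect_equal(cf[1], 1 / 10000, tolerance = 1e-12)
  ## doubling a large distance halves the contact within 5%
  expect_lt(abs(cf[3] / cf[2] - 0.5), 0.05 * 0.5)
  ## other chromosome contributes zero
  el$chrom[2] <- "chr2"
  expect_equal(contact_frequency(el, gene)[2], 0)
})

test_that("observed Hi-C counts are used, floored at the power law", {
  gene <- data.frame(gene_id = "g1", symbol = "G", chrom = "chr1",
                     start = 100000L, end = 120000L, strand = "+",
                     stringsAsFactors = FALSE)
  el <- data.frame(element_id = c("e1", "e2"), chrom = "chr1",
                   start = c(150400L, 200400L),
                   end = c(150600L, 200600L),
                   is_promoter = FALSE, promoter_of = NA_character_,
                   stringsAsFactors = FALSE)
  ## bins at resolution 1000: TSS bin 100, elements 150 and 200
  hic <- data.frame(bin1 = c(100L, 100L), bin2 = c(150L, 200L),
                    count = c(80, 1))
  cf <- contact_frequency(el, gene, hic = hic)
  pl <- (abs(c(150500, 200500) - 100000) + 5000)^-1
  scale <- sum((c(50000, 100000) + 5000)^-1) / 81
  expect_equal(cf[1], 80 * scale, tolerance = 1e-9)  # above the floor
  expect_equal(cf[2], pl[2], tolerance = 1e-12)      # floored
})

test_that("ABC scores normalise, pass the threshold, and respect
           monotonicity and scale invariance", {
  set.seed(61)
  gene <- data.frame(gene_id = "g1", symbol = "G", chrom = "chr1",
                     start = 500000L, end = 520000L, strand = "+",
                     stringsAsFactors = FALSE)
  ## single element: score 1
  el1 <- data.frame(element_id = "e1", chrom = "chr1",
                    start = 520000L, end = 520400L,
                    is_promoter = FALSE, promoter_of = NA_character_,
                    activity = 3, stringsAsFactors = FALSE)
  expect_equal(abc_scores(gene, el1)$score, 1)
  expect_error(abc_scores(gene, el1, threshold = 1.5), "threshold")
  ## two elements with activity*contact products 1:3 -> 0.25 / 0.75
  d <- c(15000, 35000)
  el2 <- data.frame(element_id = c("e1", "e2"), chrom = "chr1",
                    start = 500000L + d - 200L,
                    end = 500000L + d + 200L,
                    is_promoter = FALSE, promoter_of = NA_character_,
                    activity = c(1, 3 * (d[2] + 5000) / (d[1] + 5000)),
                    stringsAsFactors = FALSE)
  sc <- abc_scores(gene, el2)
  expect_equal(sc$score, c(0.25, 0.75), tolerance = 1e-9)
  expect_true(all(sc$passes))
  ## monotonicity: raising one activity raises its score, lowers others
  el3 <- el2
  el3$activity[1] <- el3$activity[1] * 2
  sc3 <- abc_scores(gene, el3)
  expect_gt(sc3$score[1], sc$score[1])
  expect_lt(sc3$score[2], sc$score[2])
  ## scale invariance
  el4 <- el2
  el4$activity <- el4$activity * 17
  expect_equal(abc_scores(gene, el4)$score, sc$score, tolerance = 1e-12)
  ## zero-activity elements and the degenerate all-zero case
  el5 <- el2
  el5$activity <- 0
  expect_equal(abc_scores(gene, el5)$score, c(0, 0))
})

test_that("the gene promoter element takes the window-max contact", {
  genes <- data.frame(gene_id = "g1", symbol = "G", chrom = "chr1",
                      start = 500000L, end = 520000L, strand = "+",
                      stringsAsFactors = FALSE)
  cand <- gintervals("chr1", c(499900, 540000), c(500300, 540400))
  el <- make_abc_elements(cand, genes)
  expect_true(el$is_promoter[1])
  expect_equal(el$promoter_of[1], "g1")
  el$activity <- 1
  sc <- abc_scores(genes, el)
  ## the promoter's contact equals the max over the window (here the
  ## distal element's power-law contact is lower, so it is the
  ## promoter's own nearest value)
  expect_equal(sc$contact[sc$is_promoter],
               max(sc$contact), tolerance = 1e-12)
  ## a gene without any overlapping candidate gets a constructed
  ## promoter element
  g2 <- data.frame(gene_id = "g2", symbol = "H", chrom = "chr1",
                   start = 800000L, end = 820000L, strand = "+",
                   stringsAsFactors = FALSE)
  el2 <- make_abc_elements(cand, rbind(genes, g2))
  expect_true(any(grepl("prom_g2", el2$element_id)))
})

test_that("predict_all concatenates per-gene scores that each sum to 1", {
  set.seed(63)
  genes <- random_genes(8, chroms = "chr1", max_pos = 2e6)
  cand <- random_intervals(60, chroms = "chr1", max_pos = 2e6,
                           max_len = 300L)
  el <- make_abc_elements(merge_intervals(cand), genes)
  el$activity <- stats::runif(nrow(el), 0, 5)
  pr <- predict_all(genes, el)
  sums <- tapply(pr$predictions$score, pr$predictions$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  ## expressed_only restricts the gene set
  pr2 <- predict_all(genes, el, expressed_only = genes$gene_id[1:2])
  expect_equal(sort(unique(pr2$predictions$gene_id)),
               sort(genes$gene_id[1:2]))
  ## klf4 flag enables the regulated-fraction summary
  klf4 <- cand[1:10, ]
  pr3 <- predict_all(genes, el, klf4_dbr = klf4)
  expect_true(!is.null(pr3$summary$fraction_klf4_regulated))
  expect_gte(pr3$summary$fraction_klf4_regulated, 0)
  expect_lte(pr3$summary$fraction_klf4_regulated, 1)
})
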