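pets_df <- function(pos1, pos2, chrom1 = "chr1", chrom2 = "chr1") {
  data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
             pos2 = pos2, stringsAsFactors = FALSE)
}

test_that("binning uses floor arithmetic and the minimum pair size", {
  b <- bin_contacts(pets_df(1500, 3500), resolution = 1000)
  expect_equal(b$pairs$bin1, 1L)
  expect_equal(b$pairs$bin2, 3L)
  ## separation 500 with minimum 1000 is dropped
  b2 <- bin_contacts(pets_df(1000, 1500), resolution = 1000,
                     min_distance = 1000)
  expect_equal(nrow(b2$pairs), 0L)
  ## inter-chromosomal pairs are dropped
  b3 <- bin_contacts(pets_df(1500, 9500, chrom2 = "chr2"))
  expect_equal(nrow(b3$pairs), 0L)
  ## anchors are ordered even when the input is reversed
  b4 <- bin_contacts(pets_df(9500, 1500))
  expect_true(b4$pairs$bin1 < b4$pairs$bin2)
})

test_that("pair counts are conserved through binning", {
  set.seed(71)
  n <- 10000L
  p1 <- sample.int(1000000L, n)
  p2 <- p1 + sample.int(50000L, n)
  b <- bin_contacts(pets_df(p1, p2), 1000, 1000)
  expect_equal(b$n_retained, sum(abs(p2 - p1) >= 1000))
  expect_equal(sum(b$pairs$count), b$n_retained)
  ## coverage counts every retained pair twice
  expect_equal(sum(b$coverage$coverage), 2L * b$n_retained)
})

test_that("decay fit is monotone and flat on a uniform map", {
  set.seed(73)
  ## uniform count map (equal tags at every distance): near-constant fit
  d <- rep(seq(2000, 50000, by = 1000), each = 4)
  b1 <- rep(seq(0, 900000, by = 5000), length.out = length(d))
  pets <- pets_df(b1, b1 + d)
  bu <- bin_contacts(pets, 1000, 1000)
  fu <- fit_decay(bu, n_dist_bins = 10)
  ex <- fu$expected[!is.na(fu$expected)]
  expect_true(all(diff(ex) <= 1e-12))   # PAVA guarantees monotone
  expect_lt((max(ex) - min(ex)) / mean(ex), 0.25)
  ## power-law map: strictly decreasing fitted means
  n <- 40000L
  dd <- round(exp(stats::runif(n, log(1000), log(500000))) /
              (1 + stats::runif(n, 0, 3)))
  dd <- pmax(dd, 1000)
  s <- sample.int(2000000L, n)
  bp <- bin_contacts(pets_df(s, s + dd), 1000, 1000)
  fp <- fit_decay(bp, n_dist_bins = 12)
  exp_fit <- fp$expected[!is.na(fp$expected)]
  expect_true(all(diff(exp_fit) <= 0))
  expect_lt(exp_fit[length(exp_fit)], exp_fit[1])
  expect_error(fit_decay(list(pairs = data.frame()[0, ],
                              coverage = NULL, resolution = 1000)),
               "no observed pairs")
})

test_that("weighted PAVA projects onto non-increasing sequences", {
  ## single distance bin: expected equals the global mean
  y <- c(5, 7, 3, 1)
  w <- c(1, 1, 1, 1)
  fit <- enhancerflow:::pava_nonincreasing(y, w)
  expect_true(all(diff(fit) <= 1e-12))
  expect_equal(fit[1], 6)  # violating head pooled to its mean
  expect_equal(enhancerflow:::pava_nonincreasing(4, 2), 4)
})

test_that("Poisson tails match direct summation and k = 0 gives p = 1", {
  set.seed(79)
  expect_equal(stats::ppois(-1, 2.5, lower.tail = FALSE), 1)
  for (i in 1:50) {
    k <- sample(0:30, 1)
    lam <- stats::runif(1, 0.01, 20)
    expect_equal(stats::ppois(k - 1, lam, lower.tail = FALSE),
                 oracle_pois_tail(k, lam), tolerance = 1e-12)
  }
})

test_that("loop calling flags boosted pairs against the decay background", {
  set.seed(83)
  ## background power-law-ish map plus one heavily boosted pair
  n <- 30000L
  dd <- pmax(round(exp(stats::runif(n, log(1000), log(200000)))), 1000)
  s <- sample.int(500000L, n)
  pets <- pets_df(s, s + dd)
  boost <- pets_df(rep(100500, 300), rep(130500, 300))
  b <- bin_contacts(rbind(pets, boost), 1000, 1000)
  decay <- fit_decay(b)
  called <- call_loops(b, decay, q_threshold = 0.01)
  expect_true(any(called$loops$bin1 == 100L & called$loops$bin2 == 130L))
  expect_error(call_loops(b, decay, q_threshold = 0), "q_threshold")
  ## q-values are BH over the full testable universe, so sparse
  ## singletons are never significant
  single <- called$tested[called$tested$count == 1L, ]
  if (nrow(single)) expect_true(all(single$q > 0.5))
})

test_that("anchor classification follows the E/P rule table", {
  genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("A", "B"),
                      chrom = "chr1", start = c(100000L, 400000L),
                      end = c(120000L, 420000L), strand = "+",
                      stringsAsFactors = FALSE)
  k27 <- gintervals("chr1", c(200000, 250000), c(200400, 250400))
  mk_loop <- function(b1, b2) data.frame(
    chrom = "chr1", bin1 = b1, bin2 = b2,
    start1 = b1 * 1000L, end1 = (b1 + 1L) * 1000L,
    start2 = b2 * 1000L, end2 = (b2 + 1L) * 1000L,
    loop_id = sprintf("chr1:%d-%d", b1, b2),
    stringsAsFactors = FALSE)
  loops <- rbind(mk_loop(100L, 200L),   # TSS anchor + K27ac anchor
                 mk_loop(100L, 400L),   # both TSS
                 mk_loop(200L, 250L),   # both K27ac
                 mk_loop(200L, 300L))   # K27ac + nothing
  cl <- classify_loops(loops, k27, genes)
  expect_equal(cl$loop_class, c("EP", "PP", "EE", "other"))
  expect_equal(cl$target_gene[1], "g1")
  expect_true(is.na(cl$target_gene[2]))
  ## promoter precedence: a bin overlapping both a TSS window and a
  ## K27ac peak is P
  k27b <- rbind(k27, gintervals("chr1", 100000, 100400))
  cl2 <- classify_loops(loops[1, ], k27b, genes)
  expect_equal(cl2$anchor1_class, "P")
  ## deterministic and order-invariant
  cl3 <- classify_loops(loops[4:1, ], k27, genes)
  expect_equal(cl3$loop_class, rev(cl$loop_class))
})

test_that("differential loops label gained, lost and stable", {
  mk_binned <- function(counts) {
    pairs <- data.frame(chrom = "chr1", bin1 = c(10L, 50L),
                        bin2 = c(40L, 90L), count = counts,
                        stringsAsFactors = FALSE)
    list(pairs = pairs,
         coverage = data.frame(chrom = "chr1",
                               bin = c(10L, 40L, 50L, 90L),
                               coverage = rep(sum(counts), 4)),
         n_retained = sum(counts) + 1000L, resolution = 1000L)
  }
  loops <- data.frame(chrom = "chr1", bin1 = c(10L, 50L),
                      bin2 = c(40L, 90L),
                      loop_id = c("chr1:10-40", "chr1:50-90"),
                      stringsAsFactors = FALSE)
  ## identical counts across conditions: stable
  samples <- list(LSS_1 = mk_binned(c(30L, 20L)),
                  LSS_2 = mk_binned(c(30L, 20L)),
                  ST_1 = mk_binned(c(30L, 20L)),
                  ST_2 = mk_binned(c(30L, 20L)))
  cond <- c(LSS_1 = "LSS", LSS_2 = "LSS", ST_1 = "ST", ST_2 = "ST")
  st <- differential_loops(loops, samples, cond)
  expect_equal(st$differential, c("stable", "stable"))
  ## a strong LSS-specific loop is gained; missing counts are zeros
  samples2 <- list(LSS_1 = mk_binned(c(300L, 20L)),
                   LSS_2 = mk_binned(c(280L, 22L)),
                   ST_1 = mk_binned(c(3L, 21L)),
                   ST_2 = mk_binned(c(2L, 19L)))
  g <- differential_loops(loops, samples2, cond)
  expect_equal(g$differential[1], "gained")
  expect_gt(g$log2fc[1], 2)
})

test_that("KLF4-at-anchor integration reports the strongest overlap", {
  ep <- data.frame(chrom = "chr1", bin1 = 100L, bin2 = 300L,
                   start1 = 100000L, end1 = 101000L,
                   start2 = 300000L, end2 = 301000L,
                   loop_id = "chr1:100-300", anchor1_class = "E",
                   anchor2_class = "P", loop_class = "EP",
                   target_gene = "g1", stringsAsFactors = FALSE)
  deg <- data.frame(feature_id = "g1", base_mean = 10, log2fc = 1.5,
                    se = 0.2, pvalue = 1e-4, padj = 1e-3,
                    significant = TRUE, stringsAsFactors = FALSE)
  ## no overlapping DBR: summary zeros
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), log2fc = numeric(),
                      stringsAsFactors = FALSE)
  z <- klf4_at_anchors(ep, empty, deg)
  expect_equal(z$summary$n_anchors_diff_klf4, 0L)
  ## two overlapping DBRs: the larger |log2fc| wins
  dbr <- data.frame(chrom = "chr1", start = c(100100L, 100500L),
                    end = c(100400L, 100900L), log2fc = c(0.5, -2.5),
                    stringsAsFactors = FALSE)
  r <- klf4_at_anchors(ep, dbr, deg)
  expect_equal(r$table$klf4_log2fc, -2.5)
  expect_equal(r$summary$n_target_deg, 1L)
  ## a second loop set flags lost anchors
  r2 <- klf4_at_anchors(ep, dbr, deg,
                        second_loops = ep[0, , drop = FALSE])
  expect_true(r2$table$lost_in_second)
})
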