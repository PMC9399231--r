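make_cm <- function(counts, reps = ncol(counts) / 2) {
  colnames(counts) <- c(sprintf("LSS_%d", seq_len(reps)),
                        sprintf("ST_%d", seq_len(reps)))
  rownames(counts) <- sprintf("f%04d", seq_len(nrow(counts)))
  count_matrix(counts, stats::setNames(rep(c("LSS", "ST"), each = reps),
                                       colnames(counts)))
}

test_that("size factors recover scaling and match direct recomputation", {
  set.seed(3)
  base <- matrix(rpois(200, 50), 50, 4)
  ## sample 2 is exactly twice sample 1
  m <- base
  m[, 2] <- 2L * m[, 1]
  sf <- estimate_size_factors(make_cm(m))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  ## identical samples give unit factors
  ident <- make_cm(matrix(rep(rpois(50, 30), 4), 50, 4))
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 4))
  ## direct formula evaluation on a random matrix
  r <- matrix(rpois(200, 40) + 1L, 50, 4)
  cm <- make_cm(r)
  sf2 <- estimate_size_factors(cm)
  geo <- exp(rowMeans(log(r)))
  direct <- apply(r / geo, 2, stats::median)
  direct <- direct / exp(mean(log(direct)))
  expect_equal(unname(sf2), unname(direct), tolerance = 1e-12)
  expect_error(estimate_size_factors(make_cm(matrix(0, 5, 4))),
               "all-zero")
})

test_that("size factors are proportional to DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  m <- matrix(rnbinom(400, mu = 100, size = 10) + 1L, 100, 4)
  cm <- make_cm(m)
  ours <- estimate_size_factors(cm)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  ## DESeq2 takes the median on the log scale, ours on the ratio scale
  ## (the stated formula); they agree up to the even-count median tie
  expect_equal(unname(ours / theirs),
               rep(unname(ours[1] / theirs[1]), 4), tolerance = 1e-3)
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- stats::runif(sample(c(3, 20, 200), 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
  ## monotone along sorted p; permutation-invariant
  p <- stats::runif(100)
  adj <- bh_adjust(p)
  expect_true(!is.unsorted(adj[order(p)]))
  perm <- sample.int(100)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("hypergeometric enrichment equals exact summation", {
  u <- sprintf("x%03d", 1:20)
  expect_equal(hypergeometric_enrichment(u, u, u), 1)
  expect_equal(hypergeometric_enrichment(u[1:5], u[1:5], u),
               1 / choose(20, 5), tolerance = 1e-12)
  ## disjoint hit and annotated: k = 0, p from the exact sum
  p0 <- hypergeometric_enrichment(u[1:5], u[6:10], u)
  expect_equal(p0, oracle_hyper_tail(0, 5, 20, 5), tolerance = 1e-12)
  expect_gt(p0, 0.9)
  expect_error(hypergeometric_enrichment(u[1:2], u[1:2], character(0)),
               "empty universe")
  expect_error(hypergeometric_enrichment(c(u, "zz"), u[1:2], u),
               "subsets")
})

test_that("all-zero features get the degenerate contract", {
  set.seed(5)
  m <- matrix(rpois(600, 50), 100, 6)
  m[7, ] <- 0L
  res <- nb_wald_test(make_cm(m))
  expect_equal(res$log2fc[7], 0)
  expect_equal(res$pvalue[7], 1)
})

test_that("swapping condition labels negates log2fc and keeps p-values", {
  set.seed(31)
  m <- matrix(rnbinom(600, mu = 80, size = 8), 100, 6)
  cm <- make_cm(m)
  a <- nb_wald_test(cm, numerator_condition = "LSS")
  b <- nb_wald_test(cm, numerator_condition = "ST")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
})

test_that("a scaled sample is absorbed by its size factor", {
  set.seed(41)
  ## noiseless scaled data: every sample is an exact multiple of the
  ## same feature profile, so normalisation must absorb the scalings
  ## completely and every fold change is exactly zero
  profile <- rpois(100, 100) + 1L
  base <- outer(profile, c(1, 2, 4, 5))
  scaled <- base
  scaled[, 3] <- 3L * scaled[, 3]
  r1 <- nb_wald_test(make_cm(base))
  r2 <- nb_wald_test(make_cm(scaled))
  expect_equal(r1$log2fc, rep(0, 100), tolerance = 1e-12)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-6)
  ## on noisy data the scaling is absorbed up to the pseudocount
  noisy <- matrix(rpois(400, 100) + 1L, 100, 4)
  noisy2 <- noisy
  noisy2[, 3] <- 3L * noisy2[, 3]
  expect_equal(nb_wald_test(make_cm(noisy))$log2fc,
               nb_wald_test(make_cm(noisy2))$log2fc, tolerance = 5e-3)
})

test_that("the test requires two conditions with replicates", {
  m <- matrix(rpois(40, 10), 10, 4,
              dimnames = list(sprintf("f%d", 1:10),
                              c("a", "b", "c", "d")))
  cm1 <- count_matrix(m, c(a = "LSS", b = "LSS", c = "LSS", d = "LSS"))
  expect_error(nb_wald_test(cm1), "two conditions")
  cm2 <- count_matrix(m, c(a = "LSS", b = "LSS", c = "LSS", d = "ST"))
  expect_error(nb_wald_test(cm2), ">= 2 samples")
})

test_that("null counts are calibrated and planted effects are detected", {
  ## type-I error at nominal 0.05 on the null harness
  null_cm <- generate_null_counts(2000, 3, 200, 0.1, seed = 7)
  res <- nb_wald_test(null_cm, 0.1)
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  ## power on planted 4-fold features embedded among nulls
  set.seed(11)
  mu <- rbind(matrix(200, 2000, 6),
              cbind(matrix(800, 500, 3), matrix(200, 500, 3)))
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                nrow(mu))
  r <- nb_wald_test(make_cm(cnt), 0.1)
  expect_gte(mean(r$significant[2001:2500]), 0.9)
})
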