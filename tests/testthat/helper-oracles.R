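# Independent brute-force oracles and shared fixtures. Oracles are
# deliberately naive (per-base sets, exhaustive scans, direct summation)
# and never share code with the implementation they check.

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 5000L, max_len = 300L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = ".", stringsAsFactors = FALSE)
}

# per-base set intersection oracle for overlap
oracle_overlap <- function(a, b, min_bp = 1L) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1L),
                   seq(b$start, b$end - 1L))) >= min_bp
}

# bitmap-union oracle for merge: the set of covered bases per chromosome
oracle_covered_bases <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    r <- df[df$chrom == ch, , drop = FALSE]
    out[[ch]] <- sort(unique(unlist(
      lapply(seq_len(nrow(r)), function(i)
        seq(r$start[i], r$end[i] - 1L)))))
  }
  out
}

# exhaustive nearest-TSS scan
oracle_nearest <- function(region, genes) {
  mid <- region$start + (region$end - region$start) %/% 2L
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
  d <- abs(mid - tss)
  best <- which(d == min(d))
  best <- best[order(g$gene_id[best])][1L]
  list(gene_id = g$gene_id[best], distance = mid - tss[best])
}

# independent BH step-up implementation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# exact-summation tail oracles
oracle_binom_tail <- function(k, n, p) sum(stats::dbinom(k:n, n, p))
oracle_pois_tail <- function(k, lambda) {
  upper <- max(k + 200, ceiling(lambda + 40 * sqrt(lambda + 1)))
  sum(stats::dpois(k:upper, lambda))
}
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(stats::dhyper(kk, K, N - K, n))
}

random_genes <- function(n, chroms = c("chr1", "chr2"),
                         max_pos = 100000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(5000L, n, replace = TRUE) + 100L
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             symbol = sprintf("S%d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# session-level cache of the default synthetic dataset and the full
# pipeline run on it, shared across test files to keep the suite fast
.synth_cache <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.synth_cache$ds)) {
    dir <- file.path(tempdir(), "enhancerflow_default_ds")
    .synth_cache$ds <- generate_dataset(synth_config(seed = 1L), dir)
    .synth_cache$ds_dir <- dir
  }
  .synth_cache$ds
}

default_pipeline <- function() {
  if (is.null(.synth_cache$pipe)) {
    ds <- default_dataset()
    outdir <- file.path(tempdir(), "enhancerflow_default_out")
    cfg <- pipeline_config(.synth_cache$ds_dir, outdir, seed = 1L)
    .synth_cache$pipe <- run_pipeline(cfg)
  }
  .synth_cache$pipe
}

null_loop_dataset <- function() {
  if (is.null(.synth_cache$null_ds)) {
    dir <- file.path(tempdir(), "enhancerflow_null_ds")
    .synth_cache$null_ds <- generate_dataset(
      synth_config(seed = 5L, loop_boost = 1, n_pets = 50000L), dir)
    .synth_cache$null_ds_dir <- dir
  }
  .synth_cache$null_ds
}
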