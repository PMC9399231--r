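## Core genomic-interval algebra. All coordinates are 0-based half-open
## (BED convention) throughout the package; 1-based inputs (GTF) are
## converted at the I/O layer.

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' and `strand`, using 0-based half-open coordinates. This is the unit of
#' all overlap, merge and annotation work in the package.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `start < end`.
#' @param strand Character vector in `{"+", "-", "."}`; recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
#' @examples
#' gintervals("chr1", c(0, 100), c(50, 200))
gintervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$chrom))
    stop("intervals contain NA coordinates or chromosomes")
  if (any(!nzchar(df$chrom)))
    stop("intervals contain empty chromosome names")
  if (any(df$start < 0L))
    stop("interval starts must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid interval(s) with start >= end at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(df)
}

#' Midpoint of each interval
#'
#' Defined as `start + floor((end - start) / 2)`.
#'
#' @param df An interval data frame.
#' @return Integer vector of midpoints.
#' @export
interval_midpoint <- function(df) {
  as.integer(df$start + (df$end - df$start) %/% 2L)
}

#' Test whether interval pairs overlap
#'
#' Vectorised over rows of `a` and `b` (recycled to the longer). Two
#' intervals overlap when they share a chromosome and the length of their
#' intersection under half-open semantics is at least `min_bp`; book-ended
#' intervals (end == start) therefore do not overlap at the default.
#'
#' @param a,b Interval data frames.
#' @param min_bp Minimum overlap in base pairs (default 1). Must be >= 0.
#' @return Logical vector.
#' @export
#' @examples
#' a <- gintervals("chr1", 100, 200)
#' interval_overlaps(a, gintervals("chr1", 150, 250))  # TRUE
#' interval_overlaps(a, gintervals("chr1", 200, 300))  # FALSE (book-ended)
interval_overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 0) stop("min_bp must be non-negative")
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(max(nrow(a), 1L)), n)
  ib <- rep_len(seq_len(max(nrow(b), 1L)), n)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  a$chrom[ia] == b$chrom[ib] & ov >= min_bp
}

#' Merge overlapping or book-ended intervals
#'
#' Returns a sorted, pairwise non-overlapping set covering exactly the
#' union of the input bases. Book-ended intervals (end == next start) are
#' merged, matching the bedtools-merge default of distance 0.
#'
#' @param regions Interval data frame (may be empty).
#' @return Interval data frame sorted by (chrom, start).
#' @export
merge_intervals <- function(regions) {
  validate_intervals(regions)
  if (nrow(regions) == 0L)
    return(gintervals(character(), integer(), integer()))
  o <- order(regions$chrom, regions$start, regions$end)
  r <- regions[o, c("chrom", "start", "end"), drop = FALSE]
  n <- nrow(r)
  ## running maximum end within each chromosome; a new block starts where
  ## the current start exceeds the running max (book-ended start == max
  ## continues the block)
  out_chrom <- character(0); out_start <- integer(0); out_end <- integer(0)
  for (ch in unique(r$chrom)) {
    idx <- which(r$chrom == ch)
    s <- r$start[idx]; e <- r$end[idx]
    cme <- cummax(e)
    new_block <- c(TRUE, s[-1] > cme[-length(cme)])
    grp <- cumsum(new_block)
    out_chrom <- c(out_chrom, rep(ch, max(grp)))
    out_start <- c(out_start, s[new_block])
    out_end <- c(out_end, as.integer(tapply(e, grp, max)))
  }
  gintervals(out_chrom, out_start, out_end)
}

#' Resize a peak to a fixed width centred on its summit
#'
#' The returned interval has length `width` with its midpoint
#' (`start + width %/% 2`) at the summit, clipped at the chromosome start
#' (start never negative) while preserving the width.
#'
#' @param peaks Peak data frame with columns `chrom`, `start`, `end`,
#'   `summit_offset` (summit position relative to `start`).
#' @param width Target width in bp, >= 1.
#' @return Interval data frame, one row per peak, carrying over any
#'   `name` and `signal` columns.
#' @export
#' @examples
#' p <- data.frame(chrom = "chr1", start = 100, end = 300, summit_offset = 50)
#' resize_to_summit(p, 250)  # chr1:25-275
resize_to_summit <- function(peaks, width) {
  if (length(width) != 1L || is.na(width) || width < 1)
    stop("width must be a single integer >= 1")
  width <- as.integer(width)
  summit <- as.integer(peaks$start + peaks$summit_offset)
  if (any(summit < peaks$start | summit >= peaks$end))
    stop("summit falls outside its peak")
  start <- pmax(0L, summit - width %/% 2L)
  out <- gintervals(peaks$chrom, start, start + width)
  for (col in intersect(c("name", "signal"), names(peaks)))
    out[[col]] <- peaks[[col]]
  out
}

#' Transcription start sites of a gene table
#'
#' TSS is `start` for "+" genes and `end - 1` for "-" genes
#' (0-based coordinates).
#'
#' @param genes Gene data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return Integer vector of TSS positions, one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", as.integer(genes$end) - 1L,
         as.integer(genes$start))
}

#' Nearest TSS for each region
#'
#' Distance is (region midpoint) - TSS of the nearest gene on the same
#' chromosome; the sign is genomic (midpoint to the right of the TSS is
#' positive). Ties are broken by the lexicographically smallest `gene_id`.
#' Regions on a chromosome with no gene get `gene_id = NA` and
#' `distance = NA` (a defined "no-neighbour" result, not an error).
#'
#' @param regions Interval data frame.
#' @param genes Gene data frame (non-empty).
#' @return A data frame with one row per region: `gene_id`, `distance`.
#' @export
nearest_tss <- function(regions, genes) {
  if (nrow(genes) == 0L) stop("genes must be non-empty")
  mid <- interval_midpoint(regions)
  tss <- gene_tss(genes)
  out_gene <- rep(NA_character_, nrow(regions))
  out_dist <- rep(NA_integer_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    gi <- which(genes$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (!length(gi) || !length(ri)) next
    ## sort candidate TSS; ties at equal |distance| resolved by gene_id
    o <- order(tss[gi], genes$gene_id[gi])
    gtss <- tss[gi][o]; gid <- genes$gene_id[gi][o]
    pos <- findInterval(mid[ri], gtss)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(gtss))
    dlo <- abs(mid[ri] - gtss[lo])
    dhi <- abs(mid[ri] - gtss[hi])
    ## prefer the smaller distance; on exact tie take the smaller gene_id
    use_hi <- (dhi < dlo) | (dhi == dlo & gid[hi] < gid[lo])
    ## when pos == 0 only hi is valid
    use_hi[pos == 0L] <- TRUE
    best <- ifelse(use_hi, hi, lo)
    ## exact-tie scan: neighbours with equal |distance| but smaller id
    d <- abs(mid[ri] - gtss[best])
    for (k in seq_along(ri)) {
      cand <- which(abs(mid[ri[k]] - gtss) == d[k])
      if (length(cand) > 1L)
        best[k] <- cand[order(gid[cand])[1L]]
    }
    out_gene[ri] <- gid[best]
    out_dist[ri] <- mid[ri] - gtss[best]
  }
  data.frame(gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}
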