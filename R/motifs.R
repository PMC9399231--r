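## PWM scanning and binomial motif enrichment of differential vs
## background regions. The scanner scores log-odds against a uniform
## base composition; enrichment uses an exact upper-tail binomial test
## with the background hit fraction as the null rate.

BASES <- c("A", "C", "G", "T")

encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(x, BASES)   # NA for N or anything else
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

pwm_logodds <- function(pwm) log2((pwm$probs + 1e-3) / 0.25)

#' Maximum achievable PWM log-odds score
#' @param pwm A `pwm` object.
#' @return Single numeric.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm_logodds(pwm), 2L, max))

#' Consensus sequence of a PWM (most probable base per column)
#' @param pwm A `pwm` object.
#' @return Character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2L, which.max)], collapse = "")
}

scan_one_strand <- function(enc, lo, threshold) {
  L <- ncol(lo)
  n <- length(enc) - L + 1L
  if (n < 1L) return(data.frame(position = integer(), score = numeric()))
  score <- numeric(n)
  valid <- rep(TRUE, n)
  for (i in seq_len(L)) {
    b <- enc[i:(i + n - 1L)]
    miss <- is.na(b)
    valid <- valid & !miss
    b[miss] <- 1L
    score <- score + lo[cbind(b, i)]
  }
  hit <- valid & score >= threshold
  data.frame(position = which(hit) - 1L, score = score[hit])
}

#' Scan a DNA sequence with a PWM
#'
#' Windows are scored as the sum over positions of
#' `log2((p[base, i] + 1e-3) / 0.25)`; both strands are scanned (the
#' reverse complement of the sequence, with hit positions mapped back to
#' the forward strand). A window is a hit when its score reaches
#' `threshold_frac` times the maximum achievable score; windows
#' containing `N` never hit.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm A `pwm` object.
#' @param threshold_frac Fraction of the maximal score required for a
#'   hit, in (0, 1]; default 0.8.
#' @return Data frame `position` (0-based, forward-strand coordinate of
#'   the window start), `strand` ("+"/"-"), `score`, sorted by position.
#' @export
#' @examples
#' p <- new_pwm("m", matrix(c(1, 0, 0, 0), 4, 5))  # AAAAA
#' pwm_scan("GGAAAAAGG", p)
pwm_scan <- function(seq, pwm, threshold_frac = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("threshold_frac must be in (0, 1]")
  lo <- pwm_logodds(pwm)
  L <- ncol(lo)
  if (nchar(seq) < L)
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  threshold <- threshold_frac * pwm_max_score(pwm)
  fwd <- scan_one_strand(encode_dna(seq), lo, threshold)
  rev <- scan_one_strand(encode_dna(revcomp(seq)), lo, threshold)
  ## map reverse-strand window starts back to forward coordinates
  if (nrow(rev)) rev$position <- nchar(seq) - L - rev$position
  out <- rbind(
    if (nrow(fwd)) data.frame(position = fwd$position, strand = "+",
                              score = fwd$score) else NULL,
    if (nrow(rev)) data.frame(position = rev$position, strand = "-",
                              score = rev$score) else NULL)
  if (is.null(out))
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Binomial motif enrichment of foreground vs background regions
#'
#' A region "has" a motif when [pwm_scan] reports at least one hit in its
#' sequence. With background hit rate `p0 = bg_with / bg_total` (clamped
#' to `[1e-12, 1 - 1e-12]`), the enrichment p-value is the exact
#' upper-tail binomial `P(X >= fg_with | n = fg_total, p0)` and the fold
#' is `fg_fraction / p0`. Results are sorted by p-value.
#'
#' @param fg_regions,bg_regions Character vectors of region ids (names
#'   into `sequences`); foreground must be non-empty.
#' @param sequences Named character vector of region sequences.
#' @param pwms A list of `pwm` objects (a single `pwm` is accepted).
#' @param threshold_frac Passed to [pwm_scan].
#' @return Data frame with one row per motif: `motif, fg_with, fg_total,
#'   bg_with, bg_total, fg_fraction, bg_fraction, fold, binom_p`.
#' @export
motif_enrichment <- function(fg_regions, bg_regions, sequences, pwms,
                             threshold_frac = 0.8) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (!length(fg_regions)) stop("empty foreground region set")
  if (!length(bg_regions)) stop("background must have >= 1 region")
  missing <- setdiff(c(fg_regions, bg_regions), names(sequences))
  if (length(missing))
    stop("no sequence for region(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  res <- lapply(pwms, function(pwm) {
    has <- vapply(sequences[c(fg_regions, bg_regions)], function(s)
      nrow(pwm_scan(s, pwm, threshold_frac)) > 0L, logical(1))
    fg_with <- sum(has[seq_along(fg_regions)])
    bg_with <- sum(has[-seq_along(fg_regions)])
    fg_total <- length(fg_regions); bg_total <- length(bg_regions)
    p0 <- min(max(bg_with / bg_total, 1e-12), 1 - 1e-12)
    data.frame(motif = pwm$name, fg_with = fg_with, fg_total = fg_total,
               bg_with = bg_with, bg_total = bg_total,
               fg_fraction = fg_with / fg_total,
               bg_fraction = bg_with / bg_total,
               fold = (fg_with / fg_total) / p0,
               binom_p = stats::pbinom(fg_with - 1L, fg_total, p0,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$binom_p), , drop = FALSE]
}

#' Column-shuffled decoy PWMs
#'
#' Decoys preserve the column composition of the source motif but
#' permute column order (rejecting permutations that reproduce the
#' original order), which keeps base composition while destroying the
#' planted consensus.
#'
#' @param pwm Source `pwm`.
#' @param n Number of decoys.
#' @param seed Seed for the permutations.
#' @return List of `pwm` objects named `<name>_decoy<i>`.
#' @export
shuffle_pwm_columns <- function(pwm, n = 5L, seed = 1L) {
  L <- ncol(pwm$probs)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      perm <- sample.int(L)
      if (!all(perm == seq_len(L))) break
    }
    new_pwm(sprintf("%s_decoy%d", pwm$name, i), pwm$probs[, perm])
  })
}
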