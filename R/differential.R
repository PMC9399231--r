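## Negative-binomial Wald testing with BH adjustment: the single engine
## behind differential accessibility (DAR), expression (DEG), binding
## (DBR) and differential loops. This is a deliberately transparent,
## simplified DESeq2-style test (median-of-ratios normalisation,
## method-of-moments dispersion shrunk toward a fitted mean-dispersion
## trend, delta-method Wald statistic), not a numerical clone of DESeq2.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features (restricted to
#' features with an all-positive row, i.e. a positive geometric mean) of
#' the count divided by that feature's geometric mean across samples.
#' Factors are rescaled to have geometric mean 1. When no qualifying
#' feature exists the fallback is per-sample totals, likewise rescaled.
#'
#' @param m A [count_matrix] or a counts matrix.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (all(counts == 0)) stop("all-zero count matrix")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    x <- counts[pos, , drop = FALSE]
    geo <- exp(rowMeans(log(x)))
    sf <- apply(x / geo, 2L, stats::median)
  } else {
    sf <- colSums(counts)
    if (any(sf == 0)) sf[sf == 0] <- min(sf[sf > 0])
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j >= i} (m * p_(j) / j)`
#' capped at 1 and mapped back to input order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' One-tailed hypergeometric enrichment
#'
#' Upper-tail probability P(X >= k) of drawing at least
#' `k = |hit & annotated|` annotated members in `|hit|` draws without
#' replacement from a universe containing `|annotated|` successes.
#'
#' @param hit_set,annotated_set Character vectors, subsets of `universe`.
#' @param universe Character vector (non-empty) of all items.
#' @return Single p-value.
#' @export
hypergeometric_enrichment <- function(hit_set, annotated_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hit <- unique(hit_set); ann <- unique(annotated_set)
  if (!all(hit %in% universe) || !all(ann %in% universe))
    stop("hit and annotated sets must be subsets of the universe")
  k <- length(intersect(hit, ann))
  stats::phyper(k - 1L, length(ann), length(universe) - length(ann),
                length(hit), lower.tail = FALSE)
}

## Fit the mean-dispersion trend alpha(mu) = a0/mu + a1 across features by
## least squares on method-of-moments estimates, with non-negative
## coefficients; returns a function of mu.
fit_dispersion_trend <- function(mu, alpha_mom) {
  use <- mu > 0 & is.finite(alpha_mom) & alpha_mom > 0
  if (sum(use) < 10L) {
    a1 <- max(mean(alpha_mom[is.finite(alpha_mom)], na.rm = TRUE), 1e-8)
    if (!is.finite(a1)) a1 <- 0.1
    return(function(m) rep(a1, length(m)))
  }
  x <- 1 / mu[use]; y <- alpha_mom[use]
  fit <- stats::lm(y ~ x)
  a0 <- max(unname(stats::coef(fit)[2L]), 0)
  a1 <- max(unname(stats::coef(fit)[1L]), 0)
  if (a0 == 0 && a1 == 0) a1 <- 1e-8
  function(m) a0 / pmax(m, 1e-8) + a1
}

#' Negative-binomial Wald test between two conditions
#'
#' Per feature: counts are normalised by median-of-ratios size factors;
#' group means are compared as
#' `log2fc = log2((mu_A + 0.5) / (mu_B + 0.5))` where A is
#' `numerator_condition` (a pseudocount of 0.5 is added before the log so
#' the fold change is defined at zero counts). The NB dispersion
#' (variance = mu + alpha * mu^2) is estimated per feature by method of
#' moments on within-group variances, shrunk 50/50 toward a fitted
#' mean-dispersion trend `alpha(mu) = a0/mu + a1`, floored at 1e-8. The
#' standard error of log2fc comes from the delta method on the NB group
#' means, the p-value from a two-sided normal tail of `log2fc / SE`, and
#' `padj` from [bh_adjust]. All-zero features get `log2fc = 0, p = 1`.
#'
#' @param m A [count_matrix] with exactly two condition labels and at
#'   least two samples per condition.
#' @param alpha_sig Significance threshold on `padj` (default 0.1, the
#'   adjusted-p cutoff used throughout the analysis).
#' @param numerator_condition Condition used as the fold-change
#'   numerator; defaults to "LSS" when present, else the first label
#'   alphabetically.
#' @param size_factors Optional externally supplied size factors (e.g.
#'   total retained contact pairs for loop matrices).
#' @return A `data.frame` of class `differential_result` with columns
#'   `feature_id, base_mean, log2fc, se, pvalue, padj, significant`.
#' @export
nb_wald_test <- function(m, alpha_sig = 0.1, numerator_condition = NULL,
                         size_factors = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  conds <- unique(m$condition)
  if (length(conds) != 2L)
    stop("need exactly two conditions, got: ", paste(conds, collapse = ", "))
  if (is.null(numerator_condition))
    numerator_condition <- if ("LSS" %in% conds) "LSS" else sort(conds)[1L]
  if (!numerator_condition %in% conds)
    stop("numerator condition not present: ", numerator_condition)
  condA <- numerator_condition
  condB <- setdiff(conds, condA)
  jA <- which(m$condition == condA); jB <- which(m$condition == condB)
  if (length(jA) < 2L || length(jB) < 2L)
    stop("need >= 2 samples per condition")
  sf <- if (is.null(size_factors)) estimate_size_factors(m) else {
    sfv <- size_factors[colnames(m$counts)]
    if (anyNA(sfv) || any(sfv <= 0)) stop("invalid size factors")
    sfv / exp(mean(log(sfv)))
  }
  y <- sweep(m$counts, 2L, sf, "/")          # normalised counts
  muA <- rowMeans(y[, jA, drop = FALSE])
  muB <- rowMeans(y[, jB, drop = FALSE])
  base_mean <- rowMeans(y)
  log2fc <- log2((muA + 0.5) / (muB + 0.5))

  ## method-of-moments dispersion from pooled within-group variance of
  ## normalised counts: Var(K/s) ~ mu * E[1/s] + alpha * mu^2
  nA <- length(jA); nB <- length(jB)
  vA <- apply(y[, jA, drop = FALSE], 1L, stats::var)
  vB <- apply(y[, jB, drop = FALSE], 1L, stats::var)
  s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
  mu_bar <- (muA * nA + muB * nB) / (nA + nB)
  inv_s <- mean(1 / sf)
  alpha_mom <- (s2 - mu_bar * inv_s) / mu_bar^2
  alpha_mom[!is.finite(alpha_mom) | alpha_mom < 0] <- 0
  trend <- fit_dispersion_trend(mu_bar, alpha_mom)
  alpha_hat <- pmax(0.5 * alpha_mom + 0.5 * trend(mu_bar), 1e-8)

  invA <- mean(1 / sf[jA]); invB <- mean(1 / sf[jB])
  varA <- (muA * invA + alpha_hat * muA^2) / nA
  varB <- (muB * invB + alpha_hat * muB^2) / nB
  se <- sqrt((varA / (muA + 0.5)^2 + varB / (muB + 0.5)^2)) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(z))
  zero <- muA == 0 & muB == 0
  log2fc[zero] <- 0; pvalue[zero] <- 1; se[zero] <- NA_real_
  padj <- bh_adjust(pvalue)
  res <- data.frame(feature_id = rownames(m$counts),
                    base_mean = base_mean, log2fc = log2fc, se = se,
                    pvalue = pvalue, padj = padj,
                    significant = padj < alpha_sig,
                    stringsAsFactors = FALSE)
  attr(res, "numerator") <- condA
  attr(res, "denominator") <- condB
  class(res) <- c("differential_result", "data.frame")
  res
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf(
    "differential_result: %d features, %d significant (%s over %s)\n",
    nrow(x), sum(x$significant, na.rm = TRUE),
    attr(x, "numerator") %||% "A", attr(x, "denominator") %||% "B"))
  NextMethod()
}

#' Write a differential-result table to TSV
#' @param res A `differential_result` data frame.
#' @param path Output path.
#' @export
write_differential <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
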