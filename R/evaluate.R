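## Evaluation of pipeline output against the generator's planted truth:
## recall/precision of ABC links, recovery and false-positive rate of
## planted loops. Shared by the test-suite and the acceptance script.

#' Evaluate ABC predictions against planted enhancer-gene links
#'
#' A passing non-promoter (element, gene) pair is a true positive when
#' the element contains the summit of a planted enhancer whose target is
#' that gene; a planted link counts as recovered when at least one such
#' pair exists. Precision is computed over all passing non-promoter
#' pairs.
#'
#' @param predictions ABC prediction table (rows with `passes`,
#'   `is_promoter`, `element_id`, `gene_id`, `chrom`, `start`, `end`).
#'   Pool several runs (e.g. both conditions) by row-binding first.
#' @param truth_regions Truth table from [generate_dataset]
#'   (`region_id, role, target_gene`).
#' @param regions Peak data frame of the candidate regions (for summit
#'   positions).
#' @return List `recall`, `precision`, `n_links`, `n_recovered`,
#'   `n_passing_pairs`.
#' @export
evaluate_abc_truth <- function(predictions, truth_regions, regions) {
  enh <- truth_regions[truth_regions$role == "enhancer", , drop = FALSE]
  summit <- stats::setNames(regions$start + regions$summit_offset,
                            regions$name)
  schrom <- stats::setNames(regions$chrom, regions$name)
  pass <- predictions[predictions$passes & !predictions$is_promoter, ,
                      drop = FALSE]
  pass <- pass[!duplicated(pass[, c("element_id", "gene_id")]), ,
               drop = FALSE]
  ## which planted enhancer summits fall inside each passing element
  pair_correct <- logical(nrow(pass))
  link_hit <- rep(FALSE, nrow(enh))
  for (i in seq_len(nrow(pass))) {
    inside <- which(schrom[enh$region_id] == pass$chrom[i] &
                    summit[enh$region_id] >= pass$start[i] &
                    summit[enh$region_id] < pass$end[i])
    if (length(inside)) {
      ok <- enh$target_gene[inside] == pass$gene_id[i]
      pair_correct[i] <- any(ok)
      link_hit[inside[ok]] <- TRUE
    }
  }
  list(recall = if (nrow(enh)) mean(link_hit) else NA_real_,
       precision = if (nrow(pass)) mean(pair_correct) else NA_real_,
       n_links = nrow(enh), n_recovered = sum(link_hit),
       n_passing_pairs = nrow(pass))
}

#' Evaluate called loops against planted loops
#'
#' Recall is the fraction of planted bin pairs present (exact bin
#' match) in the called set. The false-positive rate is computed over
#' tested non-planted pairs restricted to the distance range of the
#' planted loops (distance-matched), as the fraction called.
#'
#' @param called Output of [call_loops] (list with `loops`, `tested`).
#' @param truth_loops Truth table (`bin1, bin2`).
#' @return List `recall`, `fpr_distance_matched`, `n_called`.
#' @export
evaluate_loop_truth <- function(called, truth_loops) {
  key <- function(df) paste(df$bin1, df$bin2)
  called_keys <- key(called$loops)
  truth_keys <- key(truth_loops)
  recall <- mean(truth_keys %in% called_keys)
  tested <- called$tested
  d <- tested$bin2 - tested$bin1
  dt <- truth_loops$bin2 - truth_loops$bin1
  inrange <- d >= min(dt) & d <= max(dt) & !(key(tested) %in% truth_keys)
  fpr <- if (any(inrange))
    mean(tested$q[inrange] < 0.01) else 0
  list(recall = recall, fpr_distance_matched = fpr,
       n_called = nrow(called$loops))
}
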