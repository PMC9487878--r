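#' Filter thresholds for the somatic discard cascade
#'
#' Defaults are the standard stringency used for tumor/normal panels: total
#' read number < 20, tumor VAF < 0.05, more than 2 mutant reads in the
#' germline control. The stated inequalities are strict, so a call at
#' exactly the threshold (depth 20, VAF 0.05, 2 germline reads) is kept.
#'
#' @param minTotalReads calls with fewer total reads are discarded.
#' @param minTumorVaf calls with lower tumor VAF are discarded.
#' @param maxGermlineAlt calls with more germline alt reads are discarded.
#' @return list of thresholds for [applyFilterCascade()].
#' @export
filterThresholds <- function(minTotalReads = 20, minTumorVaf = 0.05,
                             maxGermlineAlt = 2) {
  stopifnot(minTotalReads >= 0, minTumorVaf >= 0, minTumorVaf <= 1,
            maxGermlineAlt >= 0)
  list(minTotalReads = minTotalReads, minTumorVaf = minTumorVaf,
       maxGermlineAlt = maxGermlineAlt)
}

#' Apply the somatic-mutation discard cascade
#'
#' A call is discarded if ANY of five independent rules fires:
#' \describe{
#'   \item{LOW_DEPTH}{total read number below `minTotalReads`;}
#'   \item{LOW_VAF}{tumor variant allele frequency below `minTumorVaf`;}
#'   \item{GERMLINE_EVIDENCE}{more than `maxGermlineAlt` mutant reads in the
#'     germline control;}
#'   \item{SINGLE_STRAND}{all alt reads on one genome strand (requires at
#'     least one alt read; zero-alt calls fall to the VAF rule);}
#'   \item{POPULATION_VARIANT}{the variant is present in normal human
#'     genomes (population-database flag).}
#' }
#' Every triggered rule is recorded for each discarded call; because the
#' rules are independent predicates, the kept set does not depend on
#' `ruleOrder` (which only affects the recording order).
#'
#' @param calls data.frame with columns total_reads, tumor_alt_reads,
#'   germline_alt_reads, alt_fwd_reads, alt_rev_reads, in_population_db
#'   (tumor_vaf is recomputed from counts; calls with zero depth are flagged
#'   LOW_DEPTH, never a division error).
#' @param thresholds see [filterThresholds()].
#' @param ruleOrder permutation of the five rule names.
#' @return A [FilterReport-class]; `kept()` and `discarded()` access the
#'   partition, input order preserved in each.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(100, 200),
#'                     ref = "A", alt = "T",
#'                     total_reads = c(100, 19), tumor_alt_reads = c(20, 8),
#'                     germline_alt_reads = 0, alt_fwd_reads = c(10, 4),
#'                     alt_rev_reads = c(10, 4), in_population_db = FALSE)
#' rep <- applyFilterCascade(calls)
#' discarded(rep)$triggered_rules
#' @export
applyFilterCascade <- function(calls, thresholds = filterThresholds(),
                               ruleOrder = filterRuleNames()) {
  requireColumns(calls, c("total_reads", "tumor_alt_reads",
                          "germline_alt_reads", "alt_fwd_reads",
                          "alt_rev_reads", "in_population_db"),
                 "somatic call table")
  if (!setequal(ruleOrder, filterRuleNames()) ||
      length(ruleOrder) != length(filterRuleNames()))
    stop("ruleOrder must be a permutation of the five filter rules")
  vaf <- ifelse(calls$total_reads > 0,
                calls$tumor_alt_reads / pmax(calls$total_reads, 1), 0)
  fires <- cbind(
    LOW_DEPTH = calls$total_reads < thresholds$minTotalReads,
    LOW_VAF = calls$total_reads > 0 & vaf < thresholds$minTumorVaf,
    GERMLINE_EVIDENCE = calls$germline_alt_reads > thresholds$maxGermlineAlt,
    SINGLE_STRAND = calls$tumor_alt_reads >= 1 &
      (calls$alt_fwd_reads == 0 | calls$alt_rev_reads == 0),
    POPULATION_VARIANT = as.logical(calls$in_population_db))
  fires <- fires[, ruleOrder, drop = FALSE]
  drop <- rowSums(fires) > 0
  discardedCalls <- calls[drop, , drop = FALSE]
  if (nrow(discardedCalls)) {
    discardedCalls$triggered_rules <- apply(
      fires[drop, , drop = FALSE], 1,
      function(r) paste(ruleOrder[r], collapse = ","))
  } else {
    discardedCalls$triggered_rules <- character(0)
  }
  keptCalls <- calls[!drop, , drop = FALSE]
  rownames(keptCalls) <- NULL
  rownames(discardedCalls) <- NULL
  new("FilterReport", kept = keptCalls, discarded = discardedCalls,
      thresholds = thresholds)
}
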