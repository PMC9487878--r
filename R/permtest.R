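#' Call recurrent copy-number gains or losses across a cohort
#'
#' Simplified marginal-score permutation test over smoothed LRR tracks.
#' Tracks are binned onto a shared grid; the per-bin score is the sum over
#' tumors of the positive part of the binned LRR (gains) or of its negation
#' (losses). The null distribution is built by permuting bin labels within
#' each tumor, which preserves each tumor's LRR value distribution while
#' destroying positional recurrence. p-values use the add-one estimator
#' `(1 + #null >= observed) / (1 + nPermutations)` and are therefore never
#' below `1 / (1 + nPermutations)`; q-values are Benjamini-Hochberg over all
#' bins, and adjacent significant bins merge into segments.
#'
#' @param tracks named list (one per tumor) of smoothed LRR point tables
#'   (columns chrom, pos, smoothed_lrr), or of [LrrTrack-class] objects.
#' @param binBp bin width of the shared grid.
#' @param nPermutations permutation count; fewer than 100 is refused as the
#'   p-values would be unusably coarse.
#' @param direction "GAIN" or "LOSS".
#' @param qThreshold q-value cutoff for reporting bins.
#' @param seed optional seed for the permutation stream.
#' @return A [GenomicRanges::GRanges] of merged significant segments with
#'   metadata columns direction, mean_smoothed_lrr (cohort mean over the
#'   segment), p_value and q_value (peak bin values). Zero-length when
#'   nothing is significant. The full per-bin table is attached as
#'   `metadata(x)$bins`.
#' @examples
#' mkTrack <- function(shift) data.frame(chrom = "chr1",
#'   pos = seq(5e5, 20e6, by = 1e6),
#'   smoothed_lrr = c(rep(0, 10), rep(shift, 5), rep(0, 5)))
#' trks <- lapply(c(1, 1, 1, 0), mkTrack)
#' names(trks) <- paste0("T", 1:4)
#' callGainLoss(trks, nPermutations = 200, seed = 1)
#' @export
callGainLoss <- function(tracks, binBp = 1e6, nPermutations = 1e5,
                         direction = c("GAIN", "LOSS"), qThreshold = 0.25,
                         seed = NULL) {
  direction <- match.arg(direction)
  if (nPermutations < 100)
    stop("nPermutations must be at least 100 for stable p-values")
  if (length(tracks) < 2)
    stop("at least two tumors are required")
  tracks <- lapply(tracks, function(t) {
    if (is(t, "LrrTrack")) t <- lrrPoints(t)
    requireColumns(t, c("chrom", "pos", "smoothed_lrr"), "LRR track")
    t
  })
  # shared grid: every (chrom, bin) touched by any track
  binned <- lapply(tracks, function(t) {
    key <- paste0(t$chrom, ":", floor(t$pos / binBp))
    vapply(split(t$smoothed_lrr, key), mean, numeric(1))
  })
  allBins <- sort(unique(unlist(lapply(binned, names))))
  M <- vapply(binned, function(b) {
    v <- b[allBins]
    v[is.na(v)] <- 0  # tumor has no sites in this bin: neutral contribution
    unname(v)
  }, numeric(length(allBins)))
  M <- t(M)  # tumors x bins
  sgn <- if (direction == "GAIN") 1 else -1
  P <- pmax(sgn * M, 0)
  obs <- colSums(P)
  if (!is.null(seed)) set.seed(seed)
  exceed <- numeric(length(obs))
  for (i in seq_len(nPermutations)) {
    perm <- apply(P, 1, sample)        # bins x tumors, each column permuted
    exceed <- exceed + (rowSums(perm) >= obs - 1e-12)
  }
  pval <- (1 + exceed) / (1 + nPermutations)
  qval <- p.adjust(pval, method = "BH")
  chrom <- sub(":[^:]*$", "", allBins)
  binIdx <- as.numeric(sub("^.*:", "", allBins))
  binTable <- data.frame(chrom = chrom, start = binIdx * binBp,
                         end = (binIdx + 1) * binBp,
                         score = obs, mean_lrr = colMeans(M),
                         p_value = pval, q_value = qval)
  sig <- qval <= qThreshold & obs > 0
  if (!any(sig)) {
    out <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      chrom[sig], IRanges::IRanges(start = binIdx[sig] * binBp + 1,
                                   end = (binIdx[sig] + 1) * binBp))
    merged <- GenomicRanges::reduce(gr)
    meta <- lapply(seq_along(merged), function(k) {
      inSeg <- sig &
        chrom == as.character(GenomicRanges::seqnames(merged))[k] &
        binIdx * binBp + 1 >= GenomicRanges::start(merged)[k] &
        (binIdx + 1) * binBp <= GenomicRanges::end(merged)[k]
      data.frame(direction = direction,
                 mean_smoothed_lrr = mean(M[, inSeg, drop = FALSE]),
                 p_value = min(pval[inSeg]),
                 q_value = min(qval[inSeg]))
    })
    S4Vectors::mcols(merged) <- do.call(rbind, meta)
    out <- merged
  }
  S4Vectors::metadata(out)$bins <- binTable
  out
}
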