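#' Classify SNP zygosity from germline VAF
#'
#' Step I of the logR-ratio pipeline: a SNP is homozygous when the germline
#' VAF is at most 0.05 or at least 0.95, heterozygous when it lies in
#' 0.4-0.6 (boundaries inclusive), and excluded otherwise. Excluded sites
#' are dropped from downstream LRR computation.
#'
#' @param sites data.frame with a `germline_vaf` column.
#' @return the input with a `zygosity` column in {HOM, HET, EXCLUDED}.
#' @examples
#' selectSnps(data.frame(germline_vaf = c(0.03, 0.5, 0.2)))$zygosity
#' @export
selectSnps <- function(sites) {
  requireColumns(sites, "germline_vaf", "SNP site table")
  v <- sites$germline_vaf
  sites$zygosity <- ifelse(v <= 0.05 | v >= 0.95, "HOM",
                           ifelse(v >= 0.4 & v <= 0.6, "HET", "EXCLUDED"))
  sites
}

# nearest populated GC bin for each requested bin (ties resolved to the
# lower bin)
nearestBin <- function(bins, populated) {
  vapply(bins, function(b) populated[which.min(abs(populated - b))],
         numeric(1))
}

#' GC-correct read depths by binned-median rescaling
#'
#' Step II: within each GC bin (default width 0.01 GC fraction) the depths
#' of each sample are rescaled so the bin median equals that sample's
#' genome-wide median. The correction is multiplicative, hence
#' monotone-preserving within a bin, and zero depths remain zero. Bins with
#' fewer than `minSitesPerBin` sites borrow the factor of the nearest
#' populated bin (reported via a message).
#'
#' @param sites data.frame with gc_frac, normal_depth, tumor_depth.
#' @param binWidth GC-fraction bin width.
#' @param minSitesPerBin minimum sites for a bin to estimate its own factor.
#' @return the input with normal_depth / tumor_depth replaced by adjusted
#'   (numeric) depths; raw values retained in normal_depth_raw /
#'   tumor_depth_raw.
#' @export
gcAdjustDepths <- function(sites, binWidth = 0.01, minSitesPerBin = 50) {
  requireColumns(sites, c("gc_frac", "normal_depth", "tumor_depth"),
                 "SNP site table")
  if (!nrow(sites)) stop("gcAdjustDepths: empty site table")
  bin <- floor(sites$gc_frac / binWidth)
  counts <- table(bin)
  populated <- as.numeric(names(counts))[counts >= minSitesPerBin]
  if (!length(populated)) {
    # too sparse to bin: every bin borrows the global pool
    populated <- as.numeric(names(counts))[which.max(counts)]
  }
  sparse <- setdiff(as.numeric(names(counts)), populated)
  if (length(sparse))
    message("gcAdjustDepths: ", length(sparse),
            " GC bin(s) below ", minSitesPerBin,
            " sites fall back to the nearest populated bin")
  adjustOne <- function(d) {
    gmed <- stats::median(d)
    binMed <- tapply(d, bin, stats::median)
    eff <- setNames(as.numeric(binMed), names(binMed))
    if (length(sparse)) {
      donor <- nearestBin(sparse, populated)
      eff[as.character(sparse)] <- eff[as.character(donor)]
    }
    factor <- gmed / pmax(eff, 0.5)
    d * factor[as.character(bin)]
  }
  sites$normal_depth_raw <- sites$normal_depth
  sites$tumor_depth_raw <- sites$tumor_depth
  sites$normal_depth <- unname(adjustOne(sites$normal_depth_raw))
  sites$tumor_depth <- unname(adjustOne(sites$tumor_depth_raw))
  sites
}

#' Compute raw logR ratios
#'
#' Step III: `raw_lrr = log2((t + eps) / (n + eps))` with tumor and normal
#' adjusted depths `t`, `n` and pseudo-count `eps` guarding against zero
#' depths without biasing high-depth sites. Sites with zero depth in both
#' samples are dropped.
#'
#' @param sites data.frame with chrom, pos, normal_depth, tumor_depth
#'   (adjusted); if a `zygosity` column is present, EXCLUDED sites are
#'   dropped.
#' @param epsilon pseudo-count.
#' @return data.frame of LRR points: chrom, pos, raw_lrr (plus tumor_baf /
#'   zygosity carried through when present).
#' @export
computeLrr <- function(sites, epsilon = 0.5) {
  requireColumns(sites, c("chrom", "pos", "normal_depth", "tumor_depth"),
                 "SNP site table")
  if ("zygosity" %in% names(sites))
    sites <- sites[sites$zygosity != "EXCLUDED", , drop = FALSE]
  usable <- sites$normal_depth > 0 | sites$tumor_depth > 0
  sites <- sites[usable, , drop = FALSE]
  keep <- intersect(c("chrom", "pos", "tumor_baf", "zygosity"), names(sites))
  out <- sites[, keep, drop = FALSE]
  out$raw_lrr <- log2((sites$tumor_depth + epsilon) /
                        (sites$normal_depth + epsilon))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Smooth an LRR track with a moving-window median
#'
#' Step IV: the representative LRR at position i is the median of raw LRRs
#' over all sites within `windowBp / 2` of i on the same chromosome
#' (windows never cross chromosome boundaries and are truncated at
#' chromosome ends; even-count windows use the midpoint of the two central
#' values).
#'
#' @param points data.frame with chrom, pos, raw_lrr, sorted by (chrom, pos).
#' @param windowBp full window width in bp.
#' @return the input with a `smoothed_lrr` column.
#' @export
smoothLrr <- function(points, windowBp = 1e6) {
  requireColumns(points, c("chrom", "pos", "raw_lrr"), "LRR point table")
  points$smoothed_lrr <- NA_real_
  for (ch in unique(points$chrom)) {
    i <- which(points$chrom == ch)
    points$smoothed_lrr[i] <- movingMedian(points$pos[i],
                                           points$raw_lrr[i], windowBp)
  }
  points
}

#' Allele-specific LRR decomposition from mirrored BAF
#'
#' At heterozygous SNPs the mirrored B-allele frequency
#' `b = max(BAF, 1 - BAF)` is smoothed with the same moving-window median
#' as the LRR track, and the total LRR splits into
#' `major_lrr = smoothed_lrr + log2(2 b)` and
#' `minor_lrr = smoothed_lrr + log2(2 (1 - b))`, so that balanced regions
#' give major = minor = LRR and LOH drives minor_lrr to the floor.
#'
#' @param points smoothed LRR point table (see [smoothLrr()]).
#' @param hetSites data.frame of heterozygous sites with chrom, pos,
#'   tumor_baf.
#' @param windowBp window width for the mirrored-BAF smoothing.
#' @param floorLrr lower bound applied to minor_lrr (guards `log2(0)`).
#' @return `points` with major_lrr / minor_lrr set at heterozygous sites
#'   (NA elsewhere); major_lrr >= minor_lrr always.
#' @export
alleleSpecificLrr <- function(points, hetSites, windowBp = 1e6,
                              floorLrr = -8) {
  requireColumns(points, c("chrom", "pos", "smoothed_lrr"),
                 "LRR point table")
  requireColumns(hetSites, c("chrom", "pos", "tumor_baf"),
                 "heterozygous site table")
  points$major_lrr <- NA_real_
  points$minor_lrr <- NA_real_
  hetSites <- hetSites[!is.na(hetSites$tumor_baf), , drop = FALSE]
  if (!nrow(hetSites)) return(points)
  hetSites <- hetSites[order(hetSites$chrom, hetSites$pos), , drop = FALSE]
  b <- numeric(nrow(hetSites))
  for (ch in unique(hetSites$chrom)) {
    i <- which(hetSites$chrom == ch)
    mirrored <- pmax(hetSites$tumor_baf[i], 1 - hetSites$tumor_baf[i])
    b[i] <- movingMedian(hetSites$pos[i], mirrored, windowBp)
  }
  key <- paste(points$chrom, points$pos)
  idx <- match(paste(hetSites$chrom, hetSites$pos), key)
  ok <- !is.na(idx)
  idx <- idx[ok]
  b <- pmin(pmax(b[ok], 0.5), 1)
  lrr <- points$smoothed_lrr[idx]
  points$major_lrr[idx] <- pmax(lrr + log2(2 * b), floorLrr)
  points$minor_lrr[idx] <- pmax(lrr + log2(pmax(2 * (1 - b), 0)), floorLrr)
  points
}

#' Run the full LRR pipeline for one tumor/normal pair
#'
#' Convenience wrapper chaining [selectSnps()], [gcAdjustDepths()],
#' [computeLrr()], [smoothLrr()] and [alleleSpecificLrr()].
#'
#' @param sites raw SNP site table (see [simulateSnpDepths()] for schema).
#' @param tumorId sample identifier stored on the track.
#' @param windowBp moving-median window width.
#' @param epsilon pseudo-count for the log ratio.
#' @param binWidth,minSitesPerBin GC-correction bin controls.
#' @param floorLrr floor for minor_lrr.
#' @return An [LrrTrack-class]; `lrrPoints()` returns the point table.
#' @examples
#' cfg <- SimulationConfig(seed = 5L, snpSpacing = 1e5)
#' trk <- buildLrrTrack(simulateSnpDepths(cfg, "T0001"), "T0001")
#' trk
#' @export
buildLrrTrack <- function(sites, tumorId, windowBp = 1e6, epsilon = 0.5,
                          binWidth = 0.01, minSitesPerBin = 50,
                          floorLrr = -8) {
  sites <- selectSnps(sites)
  sites <- sites[sites$zygosity != "EXCLUDED", , drop = FALSE]
  sites <- gcAdjustDepths(sites, binWidth = binWidth,
                          minSitesPerBin = minSitesPerBin)
  points <- computeLrr(sites, epsilon = epsilon)
  points <- smoothLrr(points, windowBp = windowBp)
  het <- points[points$zygosity == "HET", , drop = FALSE]
  points <- alleleSpecificLrr(points, het, windowBp = windowBp,
                              floorLrr = floorLrr)
  new("LrrTrack", tumorId = as.character(tumorId), points = points)
}
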