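mutationKey <- function(calls)
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")

#' Compare two tumors' mutation sets for clonal origin
#'
#' Two filtered call sets share a mutation when they carry an identical
#' (chrom, pos, ref, alt) key; VAF is ignored. The pair is called
#' SAME_ORIGIN when at least `minShared` mutations are shared, otherwise
#' INDEPENDENT. Shared hits in a configurable driver list are reported
#' separately. Recurrent hotspot positions (e.g. KRAS codon 12) can collide
#' between truly independent tumors; `requireNonHotspot = TRUE` switches to
#' a stricter rule demanding at least two shared non-hotspot mutations.
#'
#' @param callsA,callsB filtered somatic call tables (post-cascade) with
#'   chrom, pos, ref, alt and optionally gene.
#' @param tumorA,tumorB identifiers.
#' @param minShared shared-mutation count declaring common origin.
#' @param driverGenes genes whose shared hits are listed in
#'   `shared_driver_genes`.
#' @param requireNonHotspot demand >= 2 shared mutations outside
#'   `hotspotKeys`.
#' @param hotspotKeys character keys ("chrom:pos:ref:alt") of known hotspot
#'   positions.
#' @return one-row data.frame: tumor_a, tumor_b, shared_mutations,
#'   shared_driver_genes (comma-separated), private_a, private_b, call,
#'   low_confidence (TRUE when either input set is empty). Symmetric up to
#'   swapping the private counts.
#' @examples
#' a <- data.frame(chrom = "chr5", pos = 1:3, ref = "A", alt = "T",
#'                 gene = c("APC", "", ""))
#' b <- a[1:2, ]
#' compareTumorPair(a, b)$call
#' @export
compareTumorPair <- function(callsA, callsB, tumorA = "A", tumorB = "B",
                             minShared = 1,
                             driverGenes = c("APC", "TP53", "KRAS"),
                             requireNonHotspot = FALSE,
                             hotspotKeys = character(0)) {
  for (calls in list(callsA, callsB))
    requireColumns(calls, c("chrom", "pos", "ref", "alt"), "call table")
  keyA <- unique(mutationKey(callsA))
  keyB <- unique(mutationKey(callsB))
  shared <- intersect(keyA, keyB)
  nonHotspot <- setdiff(shared, hotspotKeys)
  same <- if (requireNonHotspot) length(nonHotspot) >= max(2, minShared)
          else length(shared) >= minShared
  sharedDrivers <- character(0)
  if ("gene" %in% names(callsA) && length(shared)) {
    g <- callsA$gene[mutationKey(callsA) %in% shared]
    sharedDrivers <- sort(unique(g[g %in% driverGenes]))
  }
  data.frame(tumor_a = tumorA, tumor_b = tumorB,
             shared_mutations = length(shared),
             shared_driver_genes = paste(sharedDrivers, collapse = ","),
             private_a = length(setdiff(keyA, keyB)),
             private_b = length(setdiff(keyB, keyA)),
             call = if (same) "SAME_ORIGIN" else "INDEPENDENT",
             low_confidence = !nrow(callsA) || !nrow(callsB))
}

#' Concordance between clonal calls and clinical assessment
#'
#' A pair is concordant when the genomic call matches the clinical label
#' (SAME_ORIGIN vs RECURRENCE, INDEPENDENT vs DOUBLE_CANCER); pairs labeled
#' UNDETERMINED are counted separately regardless of the call.
#'
#' @param comparisons data.frame of [compareTumorPair()] rows with an added
#'   `clinical_label` column in {RECURRENCE, DOUBLE_CANCER, UNDETERMINED}.
#' @return list: n_concordant, n_discordant, n_undetermined, and
#'   `discordant_pairs` (tumor_a/tumor_b identifiers of discordant rows).
#' @export
concordanceSummary <- function(comparisons) {
  requireColumns(comparisons, c("tumor_a", "tumor_b", "call",
                                "clinical_label"), "comparison table")
  lab <- comparisons$clinical_label
  undet <- lab == "UNDETERMINED"
  expectCall <- ifelse(lab == "RECURRENCE", "SAME_ORIGIN", "INDEPENDENT")
  concord <- !undet & comparisons$call == expectCall
  discord <- !undet & !concord
  list(n_concordant = sum(concord),
       n_discordant = sum(discord),
       n_undetermined = sum(undet),
       discordant_pairs = comparisons[discord, c("tumor_a", "tumor_b"),
                                      drop = FALSE])
}
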