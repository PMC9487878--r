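inactivationCategories <- function()
  c("BIALLELIC_POINT", "POINT_PLUS_LOH", "SV_MEDIATED_BIALLELIC",
    "MONOALLELIC", "WILDTYPE")

#' Classify per-tumor, per-gene biallelic inactivation
#'
#' Integrates disruptive point mutations, loss of heterozygosity and
#' exon-disrupting structural variations into a two-hit category:
#' \describe{
#'   \item{BIALLELIC_POINT}{two or more disruptive point mutations without
#'     LOH;}
#'   \item{POINT_PLUS_LOH}{a disruptive point mutation on the retained
#'     allele plus LOH;}
#'   \item{SV_MEDIATED_BIALLELIC}{SV hits attributable to both alleles: an
#'     exon-disrupting SV combined with LOH or with a disruptive point
#'     mutation, or two SVs on distinct alleles (phase known, or one SV
#'     itself causing the LOH);}
#'   \item{MONOALLELIC}{exactly one hit of any kind;}
#'   \item{WILDTYPE}{no evidence at all.}
#' }
#' Disruptive point mutations are nonsense, frameshift and splice effects
#' (configurable); missense counts only when flagged damaging in the call
#' table. Allele phase of two SVs is generally unknown, so two SVs count as
#' distinct-allele only when phase is provided (an `allele` column) or one
#' of them causes the LOH (`causes_loh` column) - a conservative rule.
#'
#' @param tumorId,gene identifiers; all records must refer to this pair.
#' @param mutations data.frame of filtered somatic calls for this gene, with
#'   an `effect` column and optionally a logical `damaging` column for
#'   missense calls.
#' @param loh logical, loss of heterozygosity at the locus.
#' @param svs optional data.frame of SVs with columns `affected_genes`
#'   (comma-separated symbols), `disrupts_exon`, and optionally `allele` and
#'   `causes_loh`.
#' @param disruptiveEffects effect labels counted as disruptive.
#' @param minorAlleleRetained optional logical from the allele-specific
#'   copy-number caller; `TRUE` together with `loh = TRUE` is conflicting
#'   evidence and triggers a warning (the LOH input wins).
#' @return one-row data.frame: tumor_id, gene, n_disruptive_point_mutations,
#'   has_loh, n_disruptive_svs_distinct_alleles (conservative lower bound),
#'   category.
#' @examples
#' muts <- data.frame(gene = "APC", effect = c("frameshift", "nonsense"))
#' classifyGeneInactivation("T0001", "APC", muts, loh = FALSE)$category
#' @export
classifyGeneInactivation <- function(tumorId, gene, mutations = NULL,
                                     loh = FALSE, svs = NULL,
                                     disruptiveEffects = c("nonsense",
                                                           "frameshift",
                                                           "splice"),
                                     minorAlleleRetained = NA) {
  loh <- isTRUE(loh)
  if (loh && isTRUE(minorAlleleRetained))
    warning("LOH flagged but caller reports the minor allele retained; ",
            "keeping the LOH input")
  nPoint <- 0L
  if (!is.null(mutations) && nrow(mutations)) {
    requireColumns(mutations, "effect", "mutation table")
    if ("gene" %in% names(mutations) &&
        any(mutations$gene != gene, na.rm = TRUE))
      stop("mutation table contains records for another gene")
    damaging <- if ("damaging" %in% names(mutations))
      mutations$damaging else rep(FALSE, nrow(mutations))
    disruptive <- mutations$effect %in% disruptiveEffects |
      (mutations$effect == "missense" & damaging %in% TRUE)
    nPoint <- sum(disruptive)
  }
  nSv <- 0L; svCausesLoh <- FALSE; phasedAlleles <- 0L; nSvNonLoh <- 0L
  if (!is.null(svs) && nrow(svs)) {
    requireColumns(svs, c("affected_genes", "disrupts_exon"), "SV table")
    hitsGene <- vapply(strsplit(as.character(svs$affected_genes), ","),
                       function(g) gene %in% trimws(g), logical(1))
    disruptiveSv <- svs[hitsGene & svs$disrupts_exon %in% TRUE, ,
                        drop = FALSE]
    nSv <- nrow(disruptiveSv)
    causes <- if ("causes_loh" %in% names(disruptiveSv))
      disruptiveSv$causes_loh %in% TRUE else rep(FALSE, nSv)
    svCausesLoh <- any(causes)
    nSvNonLoh <- sum(!causes)
    if ("allele" %in% names(disruptiveSv))
      phasedAlleles <- length(unique(stats::na.omit(disruptiveSv$allele)))
  }
  svBiallelic <- (nSvNonLoh >= 1 && loh) ||
    (nSv >= 1 && nPoint >= 1) ||
    (phasedAlleles >= 2) ||
    (svCausesLoh && nSvNonLoh >= 1)
  category <- if (nPoint >= 2 && !loh) {
    "BIALLELIC_POINT"
  } else if (nPoint >= 1 && loh) {
    "POINT_PLUS_LOH"
  } else if (svBiallelic) {
    "SV_MEDIATED_BIALLELIC"
  } else if (nPoint + nSv + loh >= 1) {
    "MONOALLELIC"
  } else {
    "WILDTYPE"
  }
  svAlleles <- if (phasedAlleles >= 2 || (svCausesLoh && nSvNonLoh >= 1))
    2L else min(nSv, 1L)
  data.frame(tumor_id = as.character(tumorId), gene = as.character(gene),
             n_disruptive_point_mutations = as.integer(nPoint),
             has_loh = loh,
             n_disruptive_svs_distinct_alleles = as.integer(svAlleles),
             category = category)
}

#' Summarize biallelic inactivation across a cohort
#'
#' Counts tumors per inactivation category for one gene and reports two
#' fraction panels: each category over the whole cohort, and each biallelic
#' category over the biallelic total (the "of which" denominator used when
#' reporting e.g. that 48.5% of tumors carry biallelic inactivation, of
#' which 45.7% are biallelic point mutations).
#'
#' @param statuses data.frame of classification rows (one per tumor) as
#'   returned by [classifyGeneInactivation()].
#' @param gene gene symbol to summarize.
#' @return list with `counts` (named over the five categories),
#'   `n_total`, `n_biallelic`, `fraction_biallelic`, and per-category
#'   `fraction_of_total` / `fraction_of_biallelic`.
#' @export
summarizeInactivation <- function(statuses, gene) {
  requireColumns(statuses, c("tumor_id", "gene", "category"),
                 "status table")
  statuses <- statuses[statuses$gene == gene, , drop = FALSE]
  if (!nrow(statuses)) stop("no status records for gene ", gene)
  if (anyDuplicated(statuses$tumor_id))
    stop("duplicate tumor_id in status table")
  counts <- table(factor(statuses$category,
                         levels = inactivationCategories()))
  counts <- setNames(as.integer(counts), names(counts))
  biallelicCats <- c("BIALLELIC_POINT", "POINT_PLUS_LOH",
                     "SV_MEDIATED_BIALLELIC")
  nBi <- sum(counts[biallelicCats])
  nTot <- sum(counts)
  list(gene = gene,
       counts = counts,
       n_total = nTot,
       n_biallelic = nBi,
       fraction_biallelic = nBi / nTot,
       fraction_of_total = counts / nTot,
       fraction_of_biallelic = if (nBi > 0)
         counts[biallelicCats] / nBi
       else setNames(rep(NA_real_, 3), biallelicCats))
}
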