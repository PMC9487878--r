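#' Build a marker-gene recurrence contingency table
#'
#' A patient is marker-positive when a non-synonymous mutation in ANY gene
#' of `markerGenes` is present in the primary tumor. Only stage II/III
#' patients enter the table (recurrence prediction is undefined for stage
#' IV, which is excluded automatically).
#'
#' @param patientTable data.frame with one row per patient: a `stage`
#'   column in {II, III, IV}, a logical `recurrent` column, and one logical
#'   column per marker gene.
#' @param markerGenes character vector of gene symbols (must be columns of
#'   `patientTable`).
#' @return named numeric (tp, fn, fp, tn): tp = positive and recurrent,
#'   tn = negative and non-recurrent; counts sum to the stage II/III cohort
#'   size.
#' @examples
#' pts <- data.frame(stage = "II", recurrent = c(TRUE, FALSE),
#'                   KRAS = c(TRUE, FALSE))
#' buildContingency(pts, "KRAS")
#' @export
buildContingency <- function(patientTable, markerGenes) {
  if (!length(markerGenes)) stop("markerGenes must be non-empty")
  requireColumns(patientTable, c("stage", "recurrent", markerGenes),
                 "patient table")
  patientTable <- patientTable[patientTable$stage %in% c("II", "III"), ,
                               drop = FALSE]
  if (!nrow(patientTable)) stop("no stage II/III patients in the cohort")
  status <- as.matrix(patientTable[, markerGenes, drop = FALSE])
  positive <- rowSums(status, na.rm = TRUE) > 0
  recurrent <- patientTable$recurrent
  c(tp = sum(positive & recurrent),
    fn = sum(!positive & recurrent),
    fp = sum(positive & !recurrent),
    tn = sum(!positive & !recurrent))
}

#' Predictive-value panel from contingency counts
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, false
#' negative and false positive rates, positive predictive value
#' `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`. A rate whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param tp,fn,fp,tn non-negative contingency counts (tp may also be the
#'   named vector returned by [buildContingency()], in which case the other
#'   arguments are ignored).
#' @return A [PredictivePerformance-class]; `perfRates()` gives exact
#'   fractions, `perfRates(x, rounded = TRUE)` the half-up 3-decimal panel
#'   used for comparison with printed clinical tables.
#' @examples
#' perfRates(predictiveValues(23, 34, 15, 37), rounded = TRUE)
#' @export
predictiveValues <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (length(tp) == 4 && is.null(fn)) {
    counts <- tp[c("tp", "fn", "fp", "tn")]
    tp <- counts[["tp"]]; fn <- counts[["fn"]]
    fp <- counts[["fp"]]; tn <- counts[["tn"]]
  }
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  rates <- c(sensitivity = frac(tp, tp + fn),
             specificity = frac(tn, fp + tn),
             fnr = frac(fn, tp + fn),
             fpr = frac(fp, fp + tn),
             ppv = frac(tp, tp + fp),
             npv = frac(tn, tn + fn))
  new("PredictivePerformance",
      counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
      rates = rates)
}

#' Evaluate several marker-gene sets on one cohort
#'
#' Runs [buildContingency()] and [predictiveValues()] for each gene set and
#' assembles a comparison table (one row per set).
#'
#' @param patientTable see [buildContingency()].
#' @param geneSets named list of character vectors of gene symbols.
#' @param rounded round rates half-up to 3 decimals.
#' @return data.frame: gene_set, tp, fn, fp, tn, total, and the six rates.
#' @export
evaluateMarkerPanels <- function(patientTable, geneSets, rounded = TRUE) {
  if (is.null(names(geneSets)))
    names(geneSets) <- vapply(geneSets, paste, character(1), collapse = "+")
  rows <- lapply(names(geneSets), function(nm) {
    counts <- buildContingency(patientTable, geneSets[[nm]])
    perf <- predictiveValues(counts)
    data.frame(gene_set = nm, t(counts), total = sum(counts),
               t(perfRates(perf, rounded = rounded)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
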