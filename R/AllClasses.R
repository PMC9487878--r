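#' Simulation configuration for synthetic tumor/normal cohorts
#'
#' Holds every tunable of the synthetic-cohort generator: cohort composition,
#' per-gene marker mutation rates and recurrence hazard ratios, tumor purity,
#' sequencing depth and overdispersion, GC-bias amplitude, the copy-number
#' segment model, per-rule artifact rates for the somatic filter, and the
#' global seed. Construct with [SimulationConfig()].
#'
#' @slot nPatients integer, cohort size.
#' @slot stageFractions named numeric over stages II and III, summing to 1.
#' @slot markerRates named per-gene probability of a non-synonymous marker
#'   mutation.
#' @slot hazardRatios named per-gene multiplicative recurrence hazard ratio.
#' @slot purity tumor cell fraction in (0, 1].
#' @slot meanDepth mean sequencing depth (reads).
#' @slot gcBiasAmplitude amplitude of the unimodal quadratic coverage-GC bias.
#' @slot snpSpacing germline SNP spacing in bp.
#' @slot segments data.frame segment model: chrom, start, end (0-based
#'   half-open), total_copies, minor_copies.
#' @slot artifactRates named expected artifact counts per tumor, one per
#'   filter rule.
#' @slot dispersion negative-binomial size parameter for depth noise.
#' @slot baselineHazard baseline recurrence hazard per day.
#' @slot followupDays administrative censoring horizon in days.
#' @slot lossToFollowupRate exponential rate of random loss to follow-up.
#' @slot mutationsPerTumor expected true somatic mutations per tumor.
#' @slot seed integer global seed, expanded into per-tumor substreams.
#' @exportClass SimulationConfig
setClass("SimulationConfig", slots = c(
  nPatients = "integer",
  stageFractions = "numeric",
  markerRates = "numeric",
  hazardRatios = "numeric",
  purity = "numeric",
  meanDepth = "numeric",
  gcBiasAmplitude = "numeric",
  snpSpacing = "numeric",
  segments = "data.frame",
  artifactRates = "numeric",
  dispersion = "numeric",
  baselineHazard = "numeric",
  followupDays = "numeric",
  lossToFollowupRate = "numeric",
  mutationsPerTumor = "numeric",
  seed = "integer"
))

filterRuleNames <- function()
  c("LOW_DEPTH", "LOW_VAF", "GERMLINE_EVIDENCE", "SINGLE_STRAND",
    "POPULATION_VARIANT")

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msg <- c(msg, "nPatients must be a positive integer")
  sf <- object@stageFractions
  if (!setequal(names(sf), c("II", "III")) || any(sf < 0) ||
      abs(sum(sf) - 1) > 1e-8)
    msg <- c(msg, "stageFractions must be named over {II, III} and sum to 1")
  if (any(object@markerRates < 0 | object@markerRates > 1) ||
      is.null(names(object@markerRates)))
    msg <- c(msg, "markerRates must be named probabilities in [0, 1]")
  if (!setequal(names(object@hazardRatios), names(object@markerRates)) ||
      any(object@hazardRatios <= 0))
    msg <- c(msg, paste("hazardRatios must be positive and named like",
                        "markerRates"))
  if (length(object@purity) != 1L || object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be in (0, 1]")
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be > 0")
  if (object@gcBiasAmplitude < 0)
    msg <- c(msg, "gcBiasAmplitude must be >= 0")
  if (object@snpSpacing <= 0)
    msg <- c(msg, "snpSpacing must be > 0")
  seg <- object@segments
  segCols <- c("chrom", "start", "end", "total_copies", "minor_copies")
  if (!all(segCols %in% names(seg))) {
    msg <- c(msg, paste("segments must have columns",
                        paste(segCols, collapse = ", ")))
  } else if (nrow(seg)) {
    if (any(seg$start >= seg$end))
      msg <- c(msg, "segments must satisfy start < end")
    if (any(seg$total_copies < 0) || any(seg$minor_copies < 0) ||
        any(2 * seg$minor_copies > seg$total_copies))
      msg <- c(msg, "segments need 0 <= minor_copies <= total_copies / 2")
  }
  if (!all(names(object@artifactRates) %in% filterRuleNames()) ||
      any(object@artifactRates < 0))
    msg <- c(msg, paste("artifactRates must be non-negative and named among",
                        paste(filterRuleNames(), collapse = ", ")))
  if (object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0")
  if (object@baselineHazard <= 0)
    msg <- c(msg, "baselineHazard must be > 0")
  if (object@followupDays <= 0)
    msg <- c(msg, "followupDays must be > 0")
  if (object@lossToFollowupRate < 0)
    msg <- c(msg, "lossToFollowupRate must be >= 0")
  if (object@mutationsPerTumor < 0)
    msg <- c(msg, "mutationsPerTumor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort with retained ground truth
#'
#' Returned by [generateCohort()]. The clinical table is in `patients`
#' (one row per patient: stage, per-gene marker status, recurrence and
#' survival endpoints); `truth` retains everything the generator knows
#' (marker status, per-tumor true somatic calls with artifact labels,
#' the copy-number segment model).
#'
#' @slot patients data.frame clinical table.
#' @slot truth list of truth records.
#' @slot config the [SimulationConfig-class] used.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", slots = c(
  patients = "data.frame",
  truth = "list",
  config = "SimulationConfig"
))

#' Result of the somatic-mutation discard cascade
#'
#' Partition of the input calls into `kept` and `discarded`; every discarded
#' call records all rules it triggered (comma-separated in the
#' `triggered_rules` column). Construct with [applyFilterCascade()].
#'
#' @slot kept data.frame of calls passing every rule, input order preserved.
#' @slot discarded data.frame of discarded calls plus `triggered_rules`.
#' @slot thresholds list of the thresholds applied.
#' @exportClass FilterReport
setClass("FilterReport", slots = c(
  kept = "data.frame",
  discarded = "data.frame",
  thresholds = "list"
))

setValidity("FilterReport", function(object) {
  if (nrow(object@discarded) &&
      (!"triggered_rules" %in% names(object@discarded) ||
       any(!nzchar(object@discarded$triggered_rules))))
    return("every discarded call must list at least one triggered rule")
  TRUE
})

#' Per-tumor logR-ratio track
#'
#' Smoothed logR-ratio points for one tumor/normal pair, as built by
#' [buildLrrTrack()]. The `points` table has columns chrom, pos, raw_lrr,
#' smoothed_lrr and (at heterozygous SNPs) major_lrr / minor_lrr.
#'
#' @slot tumorId sample identifier.
#' @slot points data.frame of LRR points sorted by (chrom, pos).
#' @exportClass LrrTrack
setClass("LrrTrack", slots = c(
  tumorId = "character",
  points = "data.frame"
))

setValidity("LrrTrack", function(object) {
  need <- c("chrom", "pos", "raw_lrr", "smoothed_lrr")
  if (!all(need %in% names(object@points)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate as returned by [kmEstimate()]: survival is 1 at
#' time zero and non-increasing over the observed times.
#'
#' @slot time ordered observed times.
#' @slot surv survival probabilities at those times.
#' @slot atRisk number at risk just before each time.
#' @slot nEvents total number of events.
#' @slot n number of subjects.
#' @exportClass SurvivalCurve
setClass("SurvivalCurve", slots = c(
  time = "numeric",
  surv = "numeric",
  atRisk = "numeric",
  nEvents = "integer",
  n = "integer"
))

setValidity("SurvivalCurve", function(object) {
  s <- object@surv
  if (length(s) && (any(s < -1e-12 | s > 1 + 1e-12) || is.unsorted(rev(s))))
    return("survival must be non-increasing within [0, 1]")
  TRUE
})

#' Predictive performance of a binary marker
#'
#' Contingency counts and the derived rate panel (sensitivity, specificity,
#' false negative/positive rate, positive/negative predictive value) for a
#' marker-gene set against recurrence. Undefined rates (zero denominator)
#' are `NA`. Construct with [predictiveValues()].
#'
#' @slot counts named numeric: tp, fn, fp, tn.
#' @slot rates named numeric rate panel (exact fractions, NA if undefined).
#' @exportClass PredictivePerformance
setClass("PredictivePerformance", slots = c(
  counts = "numeric",
  rates = "numeric"
))

setValidity("PredictivePerformance", function(object) {
  if (!setequal(names(object@counts), c("tp", "fn", "fp", "tn")) ||
      any(object@counts < 0))
    return("counts must be non-negative tp, fn, fp, tn")
  ok <- !is.na(object@rates)
  if (any(object@rates[ok] < -1e-12 | object@rates[ok] > 1 + 1e-12))
    return("rates must lie in [0, 1]")
  TRUE
})
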