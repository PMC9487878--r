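#' @name recurseq-accessors
#' @title Accessors for recurseq S4 containers
#' @description Slot accessors: `kept()` / `discarded()` for
#'   [FilterReport-class], `lrrPoints()` for [LrrTrack-class], `patients()` /
#'   `cohortTruth()` / `cohortConfig()` for [SyntheticCohort-class],
#'   `perfCounts()` / `perfRates()` for [PredictivePerformance-class].
#' @param x the object.
#' @param rounded for `perfRates()`, return the panel rounded half-up to 3
#'   decimals (the convention of printed clinical tables).
#' @return The slot contents (data.frame, list, or named numeric).
NULL

#' @rdname recurseq-accessors
#' @export
setGeneric("kept", function(x) standardGeneric("kept"))

#' @rdname recurseq-accessors
#' @export
setGeneric("discarded", function(x) standardGeneric("discarded"))

#' @rdname recurseq-accessors
#' @export
setGeneric("lrrPoints", function(x) standardGeneric("lrrPoints"))

#' @rdname recurseq-accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname recurseq-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname recurseq-accessors
#' @export
setGeneric("cohortConfig", function(x) standardGeneric("cohortConfig"))

#' @rdname recurseq-accessors
#' @export
setGeneric("perfCounts", function(x) standardGeneric("perfCounts"))

#' @rdname recurseq-accessors
#' @export
setGeneric("perfRates", function(x, rounded = FALSE)
  standardGeneric("perfRates"))

#' @rdname recurseq-accessors
#' @export
setMethod("kept", "FilterReport", function(x) x@kept)

#' @rdname recurseq-accessors
#' @export
setMethod("discarded", "FilterReport", function(x) x@discarded)

#' @rdname recurseq-accessors
#' @export
setMethod("lrrPoints", "LrrTrack", function(x) x@points)

#' @rdname recurseq-accessors
#' @export
setMethod("patients", "SyntheticCohort", function(x) x@patients)

#' @rdname recurseq-accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname recurseq-accessors
#' @export
setMethod("cohortConfig", "SyntheticCohort", function(x) x@config)

#' @rdname recurseq-accessors
#' @export
setMethod("perfCounts", "PredictivePerformance", function(x) x@counts)

#' @rdname recurseq-accessors
#' @export
setMethod("perfRates", "PredictivePerformance",
          function(x, rounded = FALSE) {
            if (rounded) roundHalfUp(x@rates, 3) else x@rates
          })

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPatients, "patients, purity",
      object@purity, ", mean depth", object@meanDepth, "\n")
  cat("  marker rates:",
      paste(names(object@markerRates), signif(object@markerRates, 3),
            sep = "=", collapse = " "), "\n")
  cat("  hazard ratios:",
      paste(names(object@hazardRatios), signif(object@hazardRatios, 3),
            sep = "=", collapse = " "), "\n")
  cat("  segments:", nrow(object@segments), "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@patients), "patients,",
      sum(object@patients$recurrent), "recurrent\n")
  cat("  truth records:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", nrow(object@kept), "kept,",
      nrow(object@discarded), "discarded\n")
  if (nrow(object@discarded)) {
    tab <- sort(table(unlist(strsplit(object@discarded$triggered_rules, ","))),
                decreasing = TRUE)
    cat("  rule hits:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "LrrTrack", function(object) {
  cat("LrrTrack for", object@tumorId, ":", nrow(object@points), "points on",
      length(unique(object@points$chrom)), "chromosome(s)\n")
})

setMethod("show", "SurvivalCurve", function(object) {
  cat("SurvivalCurve:", object@n, "subjects,", object@nEvents, "events,",
      length(object@time), "time points\n")
})

setMethod("show", "PredictivePerformance", function(object) {
  cat("PredictivePerformance (tp fn fp tn):",
      paste(object@counts[c("tp", "fn", "fp", "tn")], collapse = " "), "\n")
  r <- roundHalfUp(object@rates, 3)
  cat(" ", paste(names(r), format(r, nsmall = 3), sep = "=",
                 collapse = " "), "\n")
})
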