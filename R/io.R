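# plain-text readers/writers for the pipeline's tables

#' Read and write pipeline tables as TSV
#'
#' `readSnpSites()` / `writeSnpSites()` handle the SNP-site schema (chrom,
#' pos, gc_frac, normal_depth, tumor_depth, germline_vaf, tumor_baf);
#' `readSomaticCalls()` / `writeSomaticCalls()` the VCF-like somatic call
#' schema; `readClinicalTable()` / `writeClinicalTable()` the per-patient
#' clinical table. Positions are 0-based in all internal tables.
#'
#' @param path file path.
#' @param x table to write.
#' @return the table (readers), invisibly the path (writers).
#' @name recurseq-io
NULL

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname recurseq-io
#' @export
readSnpSites <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(x, c("chrom", "pos", "gc_frac", "normal_depth",
                      "tumor_depth", "germline_vaf"), "SNP site file")
  x
}

#' @rdname recurseq-io
#' @export
writeSnpSites <- function(x, path) writeTsv(x, path)

#' @rdname recurseq-io
#' @export
readSomaticCalls <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(x, c("chrom", "pos", "ref", "alt", "total_reads",
                      "tumor_alt_reads", "germline_alt_reads",
                      "alt_fwd_reads", "alt_rev_reads",
                      "in_population_db"), "somatic call file")
  x
}

#' @rdname recurseq-io
#' @export
writeSomaticCalls <- function(x, path) writeTsv(x, path)

#' @rdname recurseq-io
#' @export
readClinicalTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(x, c("patient_id", "stage", "recurrent", "rfs_days",
                      "rfs_event"), "clinical file")
  x
}

#' @rdname recurseq-io
#' @export
writeClinicalTable <- function(x, path) writeTsv(x, path)

#' Write an LRR track as bedGraph-style TSV
#'
#' One line per point: chrom, start (0-based), end, smoothed LRR.
#'
#' @param track an [LrrTrack-class] or a point table.
#' @param path output path.
#' @export
writeLrrBedGraph <- function(track, path) {
  if (is(track, "LrrTrack")) track <- lrrPoints(track)
  out <- data.frame(chrom = track$chrom, start = track$pos,
                    end = track$pos + 1, value = track$smoothed_lrr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gain/loss segment calls as BED
#'
#' BED5: chrom, start (0-based), end, name = GAIN/LOSS,
#' score = -10 log10(q).
#'
#' @param segments GRanges from [callGainLoss()].
#' @param path output path.
#' @export
writeSegmentsBed <- function(segments, path) {
  md <- as.data.frame(S4Vectors::mcols(segments))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(segments)),
                    start = GenomicRanges::start(segments) - 1,
                    end = GenomicRanges::end(segments),
                    name = md$direction,
                    score = round(-10 * log10(pmax(md$q_value, 1e-300)), 1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes clinical.tsv, truth_markers.tsv, and (when present) one
#' calls_<tumor>.tsv per tumor plus truth.json with the segment model.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeTsv(patients(cohort), file.path(dir, "clinical.tsv"))
  truth <- cohortTruth(cohort)
  writeTsv(truth$markerStatus, file.path(dir, "truth_markers.tsv"))
  jsonlite::write_json(list(segments = truth$segments),
                       file.path(dir, "truth.json"), digits = NA)
  if (!is.null(truth$somaticCalls))
    for (tid in names(truth$somaticCalls))
      writeTsv(truth$somaticCalls[[tid]],
               file.path(dir, paste0("calls_", tid, ".tsv")))
  invisible(dir)
}
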