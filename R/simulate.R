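#' Default copy-number segment model
#'
#' A compact diploid two-chromosome genome (chr1 0-100 Mb, chr2 0-80 Mb),
#' copy-neutral throughout. Replace or extend rows to inject gains, losses
#' or copy-neutral LOH; regions must not overlap within a chromosome.
#'
#' @return data.frame with columns chrom, start, end (0-based half-open),
#'   total_copies, minor_copies.
#' @export
defaultSegmentModel <- function() {
  data.frame(chrom = c("chr1", "chr2"),
             start = c(0, 0),
             end = c(100e6, 80e6),
             total_copies = c(2, 2),
             minor_copies = c(1, 1))
}

#' Construct a simulation configuration
#'
#' Defaults describe a stage II/III colorectal resection cohort: 109
#' patients (the size of the predictive-value analysis set), stage II/III
#' split 0.56/0.44, marker-gene mutation rates taken from whole-exome
#' frequencies (APC 0.64, TP53 0.59, KRAS 0.35, ZFP36L2 0.10, BRAF 0.05),
#' an elevated recurrence hazard for ZFP36L2-mutant patients, five-year
#' administrative censoring with random loss to follow-up, tumor purity
#' 0.7, mean depth 100 with negative-binomial overdispersion, and a
#' unimodal quadratic coverage-GC bias centered at GC 0.45.
#'
#' @param nPatients cohort size.
#' @param stageFractions named fractions over stages II and III, summing to 1.
#' @param markerRates named per-gene probability of a non-synonymous marker
#'   mutation in the primary tumor.
#' @param hazardRatios named per-gene multiplicative recurrence hazard ratio.
#' @param purity tumor cell fraction in (0, 1].
#' @param meanDepth mean sequencing depth.
#' @param gcBiasAmplitude amplitude of the quadratic depth-GC bias (0 = no
#'   bias).
#' @param snpSpacing germline SNP spacing in bp.
#' @param segments copy-number segment model, see [defaultSegmentModel()].
#' @param artifactRates named expected counts per tumor of artifact calls,
#'   one per filter rule (LOW_DEPTH, LOW_VAF, GERMLINE_EVIDENCE,
#'   SINGLE_STRAND, POPULATION_VARIANT).
#' @param dispersion negative-binomial size for depth noise (larger = closer
#'   to Poisson).
#' @param baselineHazard baseline recurrence hazard per day for
#'   marker-negative patients.
#' @param followupDays administrative censoring horizon (days).
#' @param lossToFollowupRate per-day exponential rate of loss to follow-up.
#' @param mutationsPerTumor expected number of true somatic mutations per
#'   tumor.
#' @param seed integer global seed; per-tumor substreams are derived from it.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nPatients = 20L, seed = 7L)
#' cfg
#' @export
SimulationConfig <- function(nPatients = 109L,
                             stageFractions = c(II = 0.56, III = 0.44),
                             markerRates = c(ZFP36L2 = 0.10, KRAS = 0.35,
                                             BRAF = 0.05, APC = 0.64,
                                             TP53 = 0.59),
                             hazardRatios = c(ZFP36L2 = 2.5, KRAS = 1,
                                              BRAF = 1, APC = 1, TP53 = 1),
                             purity = 0.7,
                             meanDepth = 100,
                             gcBiasAmplitude = 0.3,
                             snpSpacing = 10000,
                             segments = defaultSegmentModel(),
                             artifactRates = c(LOW_DEPTH = 5, LOW_VAF = 5,
                                               GERMLINE_EVIDENCE = 5,
                                               SINGLE_STRAND = 5,
                                               POPULATION_VARIANT = 5),
                             dispersion = 50,
                             baselineHazard = log(2) / 1500,
                             followupDays = 1825,
                             lossToFollowupRate = 1 / 5000,
                             mutationsPerTumor = 40,
                             seed = 1L) {
  new("SimulationConfig",
      nPatients = as.integer(nPatients),
      stageFractions = stageFractions,
      markerRates = markerRates,
      hazardRatios = hazardRatios[names(markerRates)],
      purity = purity,
      meanDepth = meanDepth,
      gcBiasAmplitude = gcBiasAmplitude,
      snpSpacing = snpSpacing,
      segments = segments,
      artifactRates = artifactRates,
      dispersion = dispersion,
      baselineHazard = baselineHazard,
      followupDays = followupDays,
      lossToFollowupRate = lossToFollowupRate,
      mutationsPerTumor = mutationsPerTumor,
      seed = as.integer(seed))
}

# classical coverage-GC curve: unimodal quadratic peaking at GC = 0.45
gcDepthFactor <- function(gc, amplitude) {
  pmax(0.05, 1 + amplitude * (1 - ((gc - 0.45) / 0.25)^2))
}

assertNonOverlapping <- function(segments) {
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("segments overlap on ", ch, call. = FALSE)
  }
  invisible(segments)
}

#' Simulate germline SNP depth data for one tumor/normal pair
#'
#' Emits one row per germline SNP: flanking GC fraction, normal and tumor
#' read depths, germline VAF (homozygous near 0/1 or heterozygous near 0.5)
#' and tumor B-allele frequency. Tumor depth at a site is proportional to
#' the purity-weighted total copy number of its segment; both samples share
#' the same smooth multiplicative GC bias; counts are overdispersed
#' negative-binomial.
#'
#' @param config a [SimulationConfig-class].
#' @param tumorId sample identifier (selects the RNG substream).
#' @return data.frame with columns chrom, pos (0-based), gc_frac,
#'   normal_depth, tumor_depth, germline_vaf, tumor_baf.
#' @examples
#' sites <- simulateSnpDepths(SimulationConfig(seed = 3L), "T0001")
#' head(sites)
#' @export
simulateSnpDepths <- function(config, tumorId) {
  validObject(config)
  seg <- config@segments
  assertNonOverlapping(seg)
  set.seed(substreamSeed(config@seed, paste0("depth:", tumorId)))
  p <- config@purity
  chunks <- lapply(seq_len(nrow(seg)), function(k) {
    s <- seg[k, ]
    pos <- seq(s$start + floor(config@snpSpacing / 2), s$end - 1,
               by = config@snpSpacing)
    n <- length(pos)
    if (!n) return(NULL)
    # flanking GC centered near the genome-wide 0.40, left of the coverage
    # peak, so the coverage-GC relationship is predominantly monotone
    gc <- rbeta(n, 16, 24)
    f <- gcDepthFactor(gc, config@gcBiasAmplitude)
    tumorCopies <- p * s$total_copies + 2 * (1 - p)
    normalDepth <- rnbinom(n, mu = config@meanDepth * f,
                           size = config@dispersion)
    tumorDepth <- rnbinom(n, mu = config@meanDepth * f * tumorCopies / 2,
                          size = config@dispersion)
    zyg <- sample(c("HOM0", "HOM1", "HET"), n, replace = TRUE,
                  prob = c(0.3, 0.3, 0.4))
    vaf <- numeric(n)
    vaf[zyg == "HOM0"] <- rbeta(sum(zyg == "HOM0"), 1, 60)
    vaf[zyg == "HOM1"] <- 1 - rbeta(sum(zyg == "HOM1"), 1, 60)
    vaf[zyg == "HET"] <- pmin(pmax(rnorm(sum(zyg == "HET"), 0.5, 0.03), 0), 1)
    # which parental allele carries the B allele is a fair coin at HET sites
    bCopies <- ifelse(runif(n) < 0.5, s$minor_copies,
                      s$total_copies - s$minor_copies)
    hetFrac <- (p * bCopies + (1 - p)) / pmax(tumorCopies, 1e-9)
    bafP <- pmin(pmax(ifelse(zyg == "HET", hetFrac, vaf), 0), 1)
    baf <- ifelse(tumorDepth > 0,
                  rbinom(n, tumorDepth, bafP) / pmax(tumorDepth, 1), NA_real_)
    data.frame(chrom = s$chrom, pos = pos, gc_frac = gc,
               normal_depth = normalDepth, tumor_depth = tumorDepth,
               germline_vaf = vaf, tumor_baf = baf)
  })
  out <- do.call(rbind, chunks)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

somaticEffects <- function()
  c("synonymous", "missense", "frameshift", "nonsense", "splice", "other")

# clean calls pass every rule of the discard cascade by construction:
# depth >= 20, VAF >= 0.05, <= 2 germline alt reads, both strands covered,
# not in the population database
makeCleanCalls <- function(n, config, genes = character(0)) {
  if (n == 0) return(emptyCallTable())
  seg <- config@segments
  segIdx <- sample(seq_len(nrow(seg)), n, replace = TRUE,
                   prob = seg$end - seg$start)
  pos <- floor(seg$start[segIdx] +
                 runif(n) * (seg$end[segIdx] - seg$start[segIdx]))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  depth <- 20 + rnbinom(n, mu = max(config@meanDepth - 20, 10),
                        size = config@dispersion)
  altReads <- rbinom(n, depth, runif(n, 0.10, 0.50))
  altReads <- pmin(pmax(altReads, pmax(2, ceiling(0.05 * depth))), depth)
  fwd <- pmin(pmax(rbinom(n, altReads, 0.5), 1), altReads - 1)
  eff <- if (length(genes)) {
    sample(c("frameshift", "nonsense", "missense"), n, replace = TRUE,
           prob = c(0.5, 0.3, 0.2))
  } else {
    sample(somaticEffects(), n, replace = TRUE,
           prob = c(0.30, 0.45, 0.10, 0.08, 0.05, 0.02))
  }
  data.frame(chrom = seg$chrom[segIdx], pos = pos, ref = ref, alt = alt,
             total_reads = depth, tumor_alt_reads = altReads,
             tumor_vaf = altReads / depth,
             germline_alt_reads = sample(0:2, n, replace = TRUE,
                                         prob = c(0.85, 0.10, 0.05)),
             alt_fwd_reads = fwd, alt_rev_reads = altReads - fwd,
             in_population_db = FALSE,
             gene = if (length(genes)) genes else "",
             effect = eff,
             is_nonsynonymous = eff != "synonymous",
             truth = "TRUE_SOMATIC")
}

emptyCallTable <- function() {
  data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), total_reads = numeric(0),
             tumor_alt_reads = numeric(0), tumor_vaf = numeric(0),
             germline_alt_reads = numeric(0), alt_fwd_reads = numeric(0),
             alt_rev_reads = numeric(0), in_population_db = logical(0),
             gene = character(0), effect = character(0),
             is_nonsynonymous = logical(0), truth = character(0))
}

# each artifact violates exactly its designated rule and no other
makeArtifactCalls <- function(rule, n, config) {
  calls <- makeCleanCalls(n, config)
  if (!n) return(calls)
  if (rule == "LOW_DEPTH") {
    depth <- sample(5:19, n, replace = TRUE)
    alt <- pmax(2, ceiling(0.05 * depth))
    calls$total_reads <- depth
    calls$tumor_alt_reads <- alt
    calls$alt_fwd_reads <- 1
    calls$alt_rev_reads <- alt - 1
  } else if (rule == "LOW_VAF") {
    depth <- sample(60:150, n, replace = TRUE)
    calls$total_reads <- depth
    calls$tumor_alt_reads <- 2
    calls$alt_fwd_reads <- 1
    calls$alt_rev_reads <- 1
  } else if (rule == "GERMLINE_EVIDENCE") {
    calls$germline_alt_reads <- sample(3:8, n, replace = TRUE)
  } else if (rule == "SINGLE_STRAND") {
    calls$alt_fwd_reads <- calls$tumor_alt_reads
    calls$alt_rev_reads <- 0
  } else if (rule == "POPULATION_VARIANT") {
    calls$in_population_db <- TRUE
  } else stop("unknown artifact rule: ", rule)
  calls$tumor_vaf <- calls$tumor_alt_reads / calls$total_reads
  calls$truth <- rule
  calls
}

#' Simulate candidate somatic calls for one tumor
#'
#' Emits a mixture of true somatic calls (constructed to pass every rule of
#' the discard cascade) and artifact calls, each artifact violating exactly
#' one configured rule; the `truth` column labels each row with
#' `"TRUE_SOMATIC"` or the name of the violated rule. When `markerStatus`
#' is given, one disruptive non-synonymous call is planted per positive
#' marker gene.
#'
#' @param config a [SimulationConfig-class].
#' @param tumorId sample identifier (selects the RNG substream).
#' @param markerStatus optional named logical over marker genes.
#' @return data.frame of candidate calls (see [applyFilterCascade()] for the
#'   column contract) plus the `truth` label column.
#' @examples
#' calls <- simulateSomaticCalls(SimulationConfig(seed = 3L), "T0001",
#'                               markerStatus = c(ZFP36L2 = TRUE))
#' table(calls$truth)
#' @export
simulateSomaticCalls <- function(config, tumorId, markerStatus = NULL) {
  validObject(config)
  set.seed(substreamSeed(config@seed, paste0("calls:", tumorId)))
  nTrue <- rpois(1, config@mutationsPerTumor)
  parts <- list(makeCleanCalls(nTrue, config))
  if (!is.null(markerStatus)) {
    posGenes <- names(markerStatus)[as.logical(markerStatus)]
    if (length(posGenes))
      parts <- c(parts, list(makeCleanCalls(length(posGenes), config,
                                            genes = posGenes)))
  }
  for (rule in names(config@artifactRates)) {
    nArt <- rpois(1, config@artifactRates[[rule]])
    parts <- c(parts, list(makeArtifactCalls(rule, nArt, config)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic tumor/normal cohort with ground truth
#'
#' Draws per-patient stage and per-gene marker status, recurrence times from
#' exponential hazards multiplied by the per-gene hazard ratios of mutated
#' markers, and applies administrative censoring at the follow-up horizon
#' plus random loss to follow-up. Post-recurrence survival gives overall
#' survival times consistent with recurrence-free survival. Optionally
#' simulates per-tumor somatic call tables (with planted marker-gene calls
#' and filter artifacts).
#'
#' @param config a [SimulationConfig-class].
#' @param includeCalls simulate per-tumor somatic call tables (slower); the
#'   clinical table and truth marker status are generated either way.
#' @return A [SyntheticCohort-class]; `patients()` gives the clinical table
#'   (patient_id, tumor_id, stage, per-gene logical marker columns,
#'   recurrent, rfs_days, rfs_event, os_days, os_event), `cohortTruth()`
#'   the truth records.
#' @examples
#' coh <- generateCohort(SimulationConfig(nPatients = 30L, seed = 11L),
#'                       includeCalls = FALSE)
#' head(patients(coh))
#' @export
generateCohort <- function(config, includeCalls = TRUE) {
  validObject(config)
  set.seed(substreamSeed(config@seed, "cohort"))
  n <- config@nPatients
  genes <- names(config@markerRates)
  patientId <- sprintf("P%04d", seq_len(n))
  tumorId <- sprintf("T%04d", seq_len(n))
  stage <- sample(names(config@stageFractions), n, replace = TRUE,
                  prob = config@stageFractions)
  marker <- vapply(genes,
                   function(g) runif(n) < config@markerRates[[g]],
                   logical(n))
  marker <- matrix(marker, nrow = n,
                   dimnames = list(NULL, genes))
  hr <- exp(marker %*% log(config@hazardRatios[genes]))[, 1]
  tRec <- rexp(n, rate = config@baselineHazard * hr)
  cens <- pmin(config@followupDays,
               if (config@lossToFollowupRate > 0)
                 rexp(n, config@lossToFollowupRate) else Inf)
  rfsDays <- pmax(1, round(pmin(tRec, cens)))
  rfsEvent <- tRec <= cens
  # post-recurrence survival; non-recurrent patients die only rarely in
  # follow-up, so OS is censored with RFS for them
  tDeath <- ifelse(rfsEvent, tRec + rexp(n, log(2) / 900), Inf)
  osDays <- pmax(rfsDays, round(pmin(tDeath, cens)))
  osEvent <- tDeath <= cens
  clinical <- data.frame(patient_id = patientId, tumor_id = tumorId,
                         stage = stage, as.data.frame(marker),
                         recurrent = rfsEvent,
                         rfs_days = rfsDays, rfs_event = rfsEvent,
                         os_days = osDays, os_event = osEvent)
  truth <- list(
    markerStatus = data.frame(patient_id = patientId, tumor_id = tumorId,
                              as.data.frame(marker)),
    segments = config@segments
  )
  if (includeCalls) {
    truth$somaticCalls <- lapply(seq_len(n), function(i)
      simulateSomaticCalls(config, tumorId[i],
                           markerStatus = marker[i, ]))
    names(truth$somaticCalls) <- tumorId
  }
  new("SyntheticCohort", patients = clinical, truth = truth, config = config)
}

#' Simulate tumor pairs with known clonal origin
#'
#' Builds synchronous/metachronous tumor pairs: same-origin pairs share a
#' clonal trunk of mutations on top of private ones, independent pairs share
#' none. Clinical labels are the true origin flipped at `clinicalFlipRate`
#' (emulating imperfect clinical assessment).
#'
#' @param config a [SimulationConfig-class].
#' @param nPairs number of tumor pairs.
#' @param trunkMutations shared trunk size for same-origin pairs.
#' @param privateMutations private mutations per tumor.
#' @param sameOriginFraction fraction of pairs that truly share an origin.
#' @param clinicalFlipRate probability that a clinical label contradicts the
#'   true origin.
#' @return list with `pairs` (tumor_a, tumor_b, true_origin, clinical_label)
#'   and `calls`, a named list of per-tumor call tables.
#' @export
simulateTumorPairs <- function(config, nPairs = 10, trunkMutations = 6,
                               privateMutations = 12,
                               sameOriginFraction = 0.5,
                               clinicalFlipRate = 0) {
  validObject(config)
  set.seed(substreamSeed(config@seed, "pairs"))
  pairs <- vector("list", nPairs)
  calls <- list()
  for (k in seq_len(nPairs)) {
    a <- sprintf("PA%03da", k)
    b <- sprintf("PA%03db", k)
    same <- runif(1) < sameOriginFraction
    trunk <- if (same) makeCleanCalls(trunkMutations, config)
             else emptyCallTable()
    callsA <- rbind(trunk, makeCleanCalls(privateMutations, config))
    callsB <- rbind(trunk, makeCleanCalls(privateMutations, config))
    trueLab <- if (same) "RECURRENCE" else "DOUBLE_CANCER"
    clinLab <- if (runif(1) < clinicalFlipRate)
      setdiff(c("RECURRENCE", "DOUBLE_CANCER"), trueLab) else trueLab
    pairs[[k]] <- data.frame(tumor_a = a, tumor_b = b,
                             true_origin = if (same) "SAME_ORIGIN"
                                           else "INDEPENDENT",
                             clinical_label = clinLab)
    calls[[a]] <- callsA
    calls[[b]] <- callsB
  }
  list(pairs = do.call(rbind, pairs), calls = calls)
}
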