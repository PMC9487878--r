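# shared fixtures built in code

# a clean somatic call that passes every filter rule
cleanCall <- function(...) {
  base <- data.frame(chrom = "chr1", pos = 1000, ref = "A", alt = "T",
                     total_reads = 100, tumor_alt_reads = 20,
                     germline_alt_reads = 0, alt_fwd_reads = 10,
                     alt_rev_reads = 10, in_population_db = FALSE,
                     gene = "", effect = "missense",
                     is_nonsynonymous = TRUE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# printed marker-gene contingency counts (stage II/III, n = 109):
# KRAS+BRAF, ZFP36L2 alone, and the combined panel
table2Counts <- list(
  kras_braf = c(tp = 23, fn = 34, fp = 15, tn = 37),
  zfp36l2 = c(tp = 12, fn = 45, fp = 2, tn = 50),
  combined = c(tp = 27, fn = 30, fp = 15, tn = 37)
)

smallConfig <- function(seed = 1L, ...) {
  SimulationConfig(nPatients = 20L, snpSpacing = 1e5, seed = seed, ...)
}

# independent O(n^2) oracle for the moving-window median
bruteForceWindowMedian <- function(pos, values, windowBp) {
  half <- windowBp / 2
  vapply(seq_along(pos), function(i)
    median(values[abs(pos - pos[i]) <= half]), numeric(1))
}
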