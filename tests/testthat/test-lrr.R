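test_that("zygosity selection applies the stated VAF intervals", {
  vaf <- c(0.03, 0.05, 0.07, 0.20, 0.40, 0.50, 0.60, 0.61, 0.95, 0.99)
  z <- selectSnps(data.frame(germline_vaf = vaf))$zygosity
  expect_equal(z, c("HOM", "HOM", "EXCLUDED", "EXCLUDED", "HET", "HET",
                    "HET", "EXCLUDED", "HOM", "HOM"))
})

test_that("raw LRR matches the closed form with pseudo-count 0.5", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                      normal_depth = c(100, 100, 100),
                      tumor_depth = c(100, 200, 0))
  lrr <- computeLrr(sites)$raw_lrr
  expect_equal(lrr[1], 0)
  expect_equal(lrr[2], log2(200.5 / 100.5))
  expect_equal(lrr[3], log2(0.5 / 100.5))
  # equal depth vectors give identically zero LRR
  set.seed(3)
  d <- rpois(50, 80)
  eq <- computeLrr(data.frame(chrom = "chr1", pos = seq_len(50) * 100,
                              normal_depth = d, tumor_depth = d))
  expect_true(all(eq$raw_lrr == 0))
})

test_that("double-zero sites are dropped and EXCLUDED zygosity is honored", {
  sites <- data.frame(chrom = "chr1", pos = c(1, 2, 3),
                      normal_depth = c(0, 10, 10),
                      tumor_depth = c(0, 10, 10),
                      zygosity = c("HET", "HET", "EXCLUDED"))
  expect_equal(computeLrr(sites)$pos, 2)
})

test_that("moving-window median equals the brute-force oracle", {
  # degenerate windows
  single <- smoothLrr(data.frame(chrom = "chr9", pos = 5e6, raw_lrr = 0.7))
  expect_equal(single$smoothed_lrr, 0.7)
  const <- smoothLrr(data.frame(chrom = "chr1", pos = seq(1e5, 5e6, 1e5),
                                raw_lrr = 0.3))
  expect_true(all(const$smoothed_lrr == 0.3))
  # randomized property vs O(n^2) oracle, several window widths
  set.seed(77)
  for (rep in 1:5) {
    n <- 1000
    pts <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      pos = sample.int(3e7, n),
                      raw_lrr = rnorm(n))
    pts <- pts[order(pts$chrom, pts$pos), ]
    w <- sample(c(5e5, 1e6, 2e6), 1)
    sm <- smoothLrr(pts, windowBp = w)
    for (ch in unique(pts$chrom)) {
      i <- pts$chrom == ch
      expect_identical(sm$smoothed_lrr[i],
                       bruteForceWindowMedian(pts$pos[i], pts$raw_lrr[i], w))
    }
  }
})

test_that("windows never cross chromosome boundaries", {
  pts <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                    pos = c(1e6, 1.2e6, 1e6, 1.2e6),
                    raw_lrr = c(1, 1, -1, -1))
  sm <- smoothLrr(pts, windowBp = 1e6)
  expect_equal(sm$smoothed_lrr, c(1, 1, -1, -1))
})

test_that("GC adjustment is a near-identity on unbiased data", {
  cfg <- SimulationConfig(seed = 21L, gcBiasAmplitude = 0, snpSpacing = 2e4)
  sites <- simulateSnpDepths(cfg, "T0001")
  adj <- suppressMessages(gcAdjustDepths(sites))
  relDiff <- abs(adj$normal_depth - adj$normal_depth_raw) /
    pmax(adj$normal_depth_raw, 1)
  expect_lt(median(relDiff), 0.05)
})

test_that("GC adjustment removes an injected quadratic bias", {
  cfg <- SimulationConfig(seed = 22L, gcBiasAmplitude = 0.4,
                          snpSpacing = 1e4)
  sites <- simulateSnpDepths(cfg, "T0001")
  rawRho <- cor(sites$normal_depth, sites$gc_frac, method = "spearman")
  expect_gt(abs(rawRho), 0.1)
  adj <- suppressMessages(gcAdjustDepths(sites))
  for (col in c("normal_depth", "tumor_depth"))
    expect_lt(abs(cor(adj[[col]], adj$gc_frac, method = "spearman")), 0.05)
  # genome-wide median depth is preserved
  expect_equal(median(adj$normal_depth), median(adj$normal_depth_raw),
               tolerance = 0.05)
  # zero depths remain zero
  z <- adj[adj$normal_depth_raw == 0, ]
  if (nrow(z)) expect_true(all(z$normal_depth == 0))
})

test_that("a shared bias curve leaves the tumor/normal ratio unchanged", {
  cfg <- SimulationConfig(seed = 23L, gcBiasAmplitude = 0.4, purity = 1,
                          snpSpacing = 1e4, dispersion = 1e4)
  sites <- simulateSnpDepths(cfg, "T0001")
  adj <- suppressMessages(gcAdjustDepths(sites))
  ok <- adj$normal_depth_raw > 0 & adj$normal_depth > 0
  before <- adj$tumor_depth_raw[ok] / adj$normal_depth_raw[ok]
  after <- adj$tumor_depth[ok] / adj$normal_depth[ok]
  expect_equal(median(after), median(before), tolerance = 0.03)
  expect_equal(sd(log(after)), sd(log(before)), tolerance = 0.05)
})

test_that("empty input to the GC adjuster errors", {
  expect_error(gcAdjustDepths(data.frame(gc_frac = numeric(0),
                                         normal_depth = numeric(0),
                                         tumor_depth = numeric(0))),
               "empty")
})

test_that("allele-specific split recovers closed-form copy ratios", {
  mkPoints <- function(lrr, baf, n = 25) {
    pos <- seq(1e5, by = 1e4, length.out = n)
    list(points = data.frame(chrom = "chr1", pos = pos, raw_lrr = lrr,
                             smoothed_lrr = lrr),
         het = data.frame(chrom = "chr1", pos = pos, tumor_baf = baf))
  }
  # balanced diploid region: major = minor = 0
  bal <- mkPoints(0, 0.5)
  out <- alleleSpecificLrr(bal$points, bal$het)
  expect_true(all(out$major_lrr == 0))
  expect_true(all(out$minor_lrr == 0))
  # pure LOH (2 copies, minor 0, purity 1): BAF 1, minor floored, major 1
  loh <- mkPoints(0, 1)
  out <- alleleSpecificLrr(loh$points, loh$het)
  expect_true(all(out$major_lrr == 1))
  expect_true(all(out$minor_lrr == -8))
  # 3:1 gain at purity 1: total 4 copies, LRR log2(2) = 1, BAF 0.75
  # major = 1 + log2(1.5) = log2(3); minor = 1 + log2(0.5) = 0
  gain <- mkPoints(1, 0.75)
  out <- alleleSpecificLrr(gain$points, gain$het)
  expect_equal(out$major_lrr, rep(log2(3), 25))
  expect_equal(out$minor_lrr, rep(0, 25))
  expect_true(all(out$major_lrr >= out$minor_lrr))
})

test_that("mirrored BAF makes the split invariant to allele labeling", {
  pos <- seq(1e5, by = 1e4, length.out = 10)
  pts <- data.frame(chrom = "chr1", pos = pos, raw_lrr = 0.5,
                    smoothed_lrr = 0.5)
  a <- alleleSpecificLrr(pts, data.frame(chrom = "chr1", pos = pos,
                                         tumor_baf = 0.8))
  b <- alleleSpecificLrr(pts, data.frame(chrom = "chr1", pos = pos,
                                         tumor_baf = 0.2))
  expect_equal(a$major_lrr, b$major_lrr)
  expect_equal(a$minor_lrr, b$minor_lrr)
})

test_that("the pipeline recovers segment copy state at moderate purity", {
  seg <- data.frame(chrom = "chr1", start = c(0, 60e6), end = c(60e6, 80e6),
                    total_copies = c(2, 4), minor_copies = c(1, 1))
  cfg <- SimulationConfig(seed = 31L, purity = 0.6, meanDepth = 120,
                          segments = seg, snpSpacing = 2e4)
  trk <- suppressMessages(buildLrrTrack(simulateSnpDepths(cfg, "T1"), "T1"))
  pts <- lrrPoints(trk)
  expected <- log2((0.6 * 4 + 2 * 0.4) / 2)
  inGain <- pts$pos >= 61e6 & pts$pos < 79e6
  expect_equal(mean(pts$smoothed_lrr[inGain]), expected, tolerance = 0.1)
  expect_equal(mean(pts$smoothed_lrr[pts$pos < 59e6]), 0, tolerance = 0.1)
})
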