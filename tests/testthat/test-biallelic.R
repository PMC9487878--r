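sv <- function(genes = "APC", disrupts = TRUE, causesLoh = FALSE,
               allele = NA) {
  data.frame(sv_type = "DELETION", chrom1 = "chr5", pos1 = 1e6,
             chrom2 = "chr5", pos2 = 2e6, affected_genes = genes,
             disrupts_exon = disrupts, causes_loh = causesLoh,
             allele = allele)
}
mut <- function(effects, damaging = FALSE, gene = "APC") {
  data.frame(gene = rep(gene, length.out = length(effects)),
             effect = effects,
             damaging = rep(damaging, length.out = length(effects)))
}

test_that("two-hit categories follow the stated precedence", {
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        mut(c("frameshift", "frameshift")),
                                        loh = FALSE)$category,
               "BIALLELIC_POINT")
  expect_equal(classifyGeneInactivation("T1", "APC", mut("nonsense"),
                                        loh = TRUE)$category,
               "POINT_PLUS_LOH")
  # two point mutations WITH LOH resolve to point-plus-LOH
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        mut(c("nonsense", "splice")),
                                        loh = TRUE)$category,
               "POINT_PLUS_LOH")
  # LOH-causing deletion on one allele plus exonic SVs on the other
  svs <- rbind(sv(causesLoh = TRUE), sv())
  st <- classifyGeneInactivation("T1003", "APC", loh = TRUE, svs = svs)
  expect_equal(st$category, "SV_MEDIATED_BIALLELIC")
  expect_equal(st$n_disruptive_svs_distinct_alleles, 2L)
  expect_equal(classifyGeneInactivation("T1", "APC")$category, "WILDTYPE")
})

test_that("single hits of any kind are monoallelic", {
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        mut("frameshift"))$category,
               "MONOALLELIC")
  expect_equal(classifyGeneInactivation("T1", "APC", loh = TRUE)$category,
               "MONOALLELIC")
  expect_equal(classifyGeneInactivation("T1", "APC", svs = sv())$category,
               "MONOALLELIC")
  # two unphased SVs without LOH stay conservative (could hit one allele)
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        svs = rbind(sv(), sv()))$category,
               "MONOALLELIC")
  # ... but known distinct phase upgrades them
  svs <- rbind(sv(allele = 1), sv(allele = 2))
  expect_equal(classifyGeneInactivation("T1", "APC", svs = svs)$category,
               "SV_MEDIATED_BIALLELIC")
})

test_that("only disruptive effects count as hits", {
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        mut(c("missense", "synonymous")),
                                        loh = FALSE)$category,
               "WILDTYPE")
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        mut(c("missense", "missense"),
                                            damaging = TRUE),
                                        loh = FALSE)$category,
               "BIALLELIC_POINT")
  # SVs outside the gene or not exon-disrupting do not count
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        svs = sv(genes = "TP53"))$category,
               "WILDTYPE")
  expect_equal(classifyGeneInactivation("T1", "APC",
                                        svs = sv(disrupts = FALSE))$category,
               "WILDTYPE")
})

test_that("classification is order-independent and hit-monotone", {
  biallelicCats <- c("BIALLELIC_POINT", "POINT_PLUS_LOH",
                     "SV_MEDIATED_BIALLELIC")
  rank <- function(cat) cat %in% biallelicCats
  set.seed(55)
  effects <- c("nonsense", "frameshift", "splice", "missense", "synonymous")
  for (i in 1:50) {
    m <- mut(sample(effects, sample(0:3, 1), replace = TRUE))
    loh <- runif(1) < 0.4
    s <- if (runif(1) < 0.4) sv() else NULL
    base <- classifyGeneInactivation("T1", "APC", m, loh, s)
    shuffled <- classifyGeneInactivation("T1", "APC",
                                         m[sample(nrow(m)), , drop = FALSE],
                                         loh, s)
    expect_equal(base$category, shuffled$category)
    more <- classifyGeneInactivation("T1", "APC",
                                     rbind(m, mut("nonsense")), loh, s)
    expect_gte(rank(more$category), rank(base$category))
  }
})

test_that("conflicting LOH evidence warns and the LOH input wins", {
  expect_warning(
    st <- classifyGeneInactivation("T1", "APC", mut("nonsense"), loh = TRUE,
                                   minorAlleleRetained = TRUE),
    "minor allele")
  expect_equal(st$category, "POINT_PLUS_LOH")
})

test_that("cohort summary reproduces the of-which fraction arithmetic", {
  statuses <- rbind(
    do.call(rbind, replicate(37, classifyGeneInactivation(
      "x", "APC", mut(c("nonsense", "frameshift"))), simplify = FALSE)),
    do.call(rbind, replicate(43, classifyGeneInactivation(
      "x", "APC", mut("nonsense"), loh = TRUE), simplify = FALSE)),
    classifyGeneInactivation("x", "APC", loh = TRUE,
                             svs = rbind(sv(causesLoh = TRUE), sv())),
    do.call(rbind, replicate(86, classifyGeneInactivation("x", "APC"),
                             simplify = FALSE)))
  statuses$tumor_id <- sprintf("T%03d", seq_len(nrow(statuses)))
  s <- summarizeInactivation(statuses, "APC")
  expect_equal(s$n_total, 167)
  expect_equal(s$n_biallelic, 81)
  expect_equal(round(100 * s$fraction_biallelic, 1), 48.5)
  expect_equal(round(100 * s$fraction_of_biallelic[["BIALLELIC_POINT"]], 1),
               45.7)
  expect_equal(round(100 * s$fraction_of_biallelic[["POINT_PLUS_LOH"]], 1),
               53.1)
})

test_that("summary rejects duplicates and empty cohorts", {
  st <- rbind(classifyGeneInactivation("T1", "APC"),
              classifyGeneInactivation("T1", "APC"))
  expect_error(summarizeInactivation(st, "APC"), "duplicate")
  expect_error(summarizeInactivation(st[0, ], "APC"), "no status")
})

test_that("planted category mixtures are recovered exactly", {
  set.seed(66)
  planted <- sample(c("BIALLELIC_POINT", "POINT_PLUS_LOH",
                      "SV_MEDIATED_BIALLELIC", "MONOALLELIC", "WILDTYPE"),
                    120, replace = TRUE)
  statuses <- do.call(rbind, lapply(seq_along(planted), function(i) {
    args <- switch(planted[i],
      BIALLELIC_POINT = list(mutations = mut(c("nonsense", "nonsense"),
                                             gene = "TP53")),
      POINT_PLUS_LOH = list(mutations = mut("frameshift", gene = "TP53"),
                            loh = TRUE),
      SV_MEDIATED_BIALLELIC = list(
        svs = rbind(sv(genes = "TP53", causesLoh = TRUE),
                    sv(genes = "TP53")),
        loh = TRUE),
      MONOALLELIC = list(mutations = mut("splice", gene = "TP53")),
      WILDTYPE = list())
    do.call(classifyGeneInactivation,
            c(list(tumorId = sprintf("T%03d", i), gene = "TP53"), args))
  }))
  expect_equal(statuses$category, planted)
  s <- summarizeInactivation(statuses, "TP53")
  expect_equal(unname(s$counts[unique(planted)]),
               as.integer(table(planted)[unique(planted)]))
})
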