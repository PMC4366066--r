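# The synthetic-data generator: configuration validation, deterministic
# quota composition, structural invariants, determinism, substream
# stability, the codon-pair simulator's limiting behavior, and the
# closed-form chromosome copy accounting.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(propX = 1.2), "propX")
  expect_error(simulationConfig(biasProps = c(MBG = .5, FBG = .4, NBG = .2)),
               "biasProps")
  expect_error(simulationConfig(kappa = -1), "kappa")
  expect_error(simulationConfig(xMbgInflation = -0.1), "xMbgInflation")
  expect_error(simulationConfig(tauConcentration =
                                  c(MBG = 0, FBG = .4, NBG = .8)),
               "tauConcentration")
})

test_that("class composition is exact by quota rounding", {
  cfg <- simulationConfig(nGenes = 100L, propX = 0.2, makeSequences = FALSE,
                          seed = 7L)
  gt <- geneTable(generateDataset(cfg))
  expect_equal(nrow(gt), 100L)
  expect_equal(sum(gt$chrom == "X"), 20L)
  expect_equal(as.integer(table(gt$bias_class)[c("MBG", "FBG", "NBG")]),
               c(20L, 20L, 60L))
})

test_that("dataset invariants hold and regeneration is bit-identical", {
  cfg <- simulationConfig(nGenes = 150L, seed = 3L,
                          nCodonsDist = list(meanlog = log(60), sdlog = 0.3,
                                             min = 20))
  ds <- generateDataset(cfg)
  gt <- geneTable(ds)
  # degree equals incident edge count (validity also enforces this)
  ed <- interactionEdges(ds)
  inc <- table(factor(c(ed$from, ed$to), levels = gt$gene_id))
  expect_equal(gt$degree, as.integer(inc))
  # tissue matrix nonnegative with at least one positive value per gene
  tm <- tissueMatrix(ds)
  expect_true(all(tm >= 0))
  expect_true(all(apply(tm, 1, max) > 0))
  # every gene once in the table; codon pairs keyed by gene IDs
  expect_false(anyDuplicated(gt$gene_id) > 0)
  expect_true(all(names(codonPairs(ds)) %in% gt$gene_id))
  # determinism
  expect_identical(ds, generateDataset(cfg))
  # expression measurements reconstruct the generative quantities exactly
  es <- expressionSummaryTable(expressionMeasurements(ds), tissueMatrix(ds))
  i <- match(gt$gene_id, es$gene_id)
  expect_equal(es$divergence[i], gt$expression_divergence, tolerance = 1e-12)
  expect_equal(es$polymorphism[i], gt$expression_polymorphism,
               tolerance = 1e-12)
  expect_equal(es$tau[i], gt$tau, tolerance = 1e-12)
})

test_that("adding genes does not perturb existing genes' substream draws", {
  base <- simulationConfig(nGenes = 60L, makeSequences = FALSE, seed = 41L)
  more <- simulationConfig(nGenes = 90L, makeSequences = FALSE, seed = 41L)
  g1 <- geneTable(generateDataset(base))
  g2 <- geneTable(generateDataset(more))
  # class labels change with n (quota), so compare genes with equal labels;
  # the per-gene draws (level, tau) must be identical for shared IDs with
  # the same bias class.  Degree and divergence depend on class/graph.
  shared <- intersect(g1$gene_id, g2$gene_id)
  same <- shared[g1$bias_class[match(shared, g1$gene_id)] ==
                   g2$bias_class[match(shared, g2$gene_id)]]
  expect_gt(length(same), 0)
  expect_equal(g1$level[match(same, g1$gene_id)],
               g2$level[match(same, g2$gene_id)])
  expect_equal(g1$tau[match(same, g1$gene_id)],
               g2$tau[match(same, g2$gene_id)])
})

test_that("x_mbg_inflation scales X-linked MBG divergence multiplicatively", {
  ratios <- vapply(1:30, function(s) {
    cfg <- simulationConfig(nGenes = 5000L, makeSequences = FALSE,
                            xMbgInflation = 1.5, seed = 2000L + s)
    gt <- geneTable(generateDataset(cfg))
    m <- gt[gt$bias_class == "MBG", ]
    mean(m$expression_divergence[m$chrom == "X"]) /
      mean(m$expression_divergence[m$chrom == "A"])
  }, numeric(1))
  expect_equal(mean(ratios), 1.5, tolerance = 0.05)
})

test_that("codon pair simulation honours its limiting cases", {
  # t = 0: identical sequences
  p <- simulateCodonPair(0.5, 2, 0, nCodons = 200, seed = 1)
  expect_identical(p@seqA, p@seqB)
  # omega = 0: identical amino acid sequences, possibly different codons
  p <- simulateCodonPair(0, 2, 0.5, nCodons = 300, seed = 2)
  aa <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_identical(aa(p@seqA), aa(p@seqB))
  expect_false(identical(p@seqA, p@seqB))
  # no stops, no gaps ever
  expect_false(any(fasterX:::.isStopCodon(fasterX:::splitCodons(p@seqA))))
  expect_false(any(fasterX:::.isStopCodon(fasterX:::splitCodons(p@seqB))))
  # invalid frequency vectors rejected
  expect_error(simulateCodonPair(1, 2, .1, codonFreqs = rep(1 / 64, 64),
                                 nCodons = 10), "length")
  f <- rep(1 / 61, 61)
  names(f) <- senseCodons()
  names(f)[1] <- "TAA"
  expect_error(simulateCodonPair(1, 2, .1, codonFreqs = f, nCodons = 10),
               "stop")
  expect_error(simulateCodonPair(1, 2, .1, codonFreqs = rep(1 / 61, 61) * 1.1,
                                 nCodons = 10), "sum")
})

test_that("substitution counts scale linearly with t at small t", {
  countDiffs <- function(t, seeds) {
    mean(vapply(seeds, function(s) {
      p <- simulateCodonPair(1, 2, t, nCodons = 500, seed = s)
      sum(fasterX:::splitCodons(p@seqA) != fasterX:::splitCodons(p@seqB))
    }, numeric(1)))
  }
  d1 <- countDiffs(0.01, 1:40)
  d2 <- countDiffs(0.02, 41:80)
  d4 <- countDiffs(0.04, 81:120)
  # doubling t doubles the expected count within Monte-Carlo error
  expect_equal(d2 / d1, 2, tolerance = 0.25)
  expect_equal(d4 / d2, 2, tolerance = 0.25)
})

test_that("chromosome copy accounting matches the closed forms", {
  eq <- chromosomeCopyAccounting("X", 500, 500)
  expect_identical(eq$copyRatioVsAutosome, 0.75)
  expect_identical(eq$fractionInFemales, 2 / 3)
  a <- chromosomeCopyAccounting("autosome", 123, 456)
  expect_identical(a$copyRatioVsAutosome, 1)
  expect_equal(a$fractionInFemales, 123 / (123 + 456))
  # general sex ratio: X copies 2F + M over autosomal 2(F + M)
  g <- chromosomeCopyAccounting("X", 300, 100)
  expect_equal(g$copyRatioVsAutosome, (600 + 100) / 800)
  expect_equal(g$fractionInFemales, 600 / 700)
  expect_error(chromosomeCopyAccounting("X", 0, 10), ">= 1")
})
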