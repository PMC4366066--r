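# Expression properties: tau closed forms and invariances, the
# level/divergence/polymorphism summary, and sex-bias classification.

test_that("tau closed-form cases and domain errors", {
  expect_identical(tissueSpecificity(c(5, 5, 5, 5)), 0)
  expect_identical(tissueSpecificity(c(7, 0, 0, 0)), 1)
  expect_identical(tissueSpecificity(c(2, 1, 1)), 0.5)
  expect_error(tissueSpecificity(c(0, 0, 0)), "positive")
  expect_error(tissueSpecificity(c(1, -1, 2)), "nonnegative")
  expect_error(tissueSpecificity(5), "2 tissues")
})

test_that("tau is scale-invariant and bounded", {
  set.seed(99)
  for (k in 1:200) {
    x <- rgamma(sample(2:30, 1), shape = 0.5)
    tau <- tissueSpecificity(x)
    expect_gte(tau, 0)
    expect_lte(tau, 1)
    c <- runif(1, 1e-6, 1e6)
    expect_equal(tissueSpecificity(c * x), tau, tolerance = 1e-12)
  }
})

test_that("tau is weakly monotone under mass transfer to the maximal tissue", {
  set.seed(7)
  for (k in 1:100) {
    x <- rgamma(sample(3:20, 1), shape = 1)
    tau0 <- tissueSpecificity(x)
    i <- which.max(x)
    j <- sample(setdiff(seq_along(x), i), 1)
    delta <- runif(1, 0, x[j])
    y <- x
    y[i] <- y[i] + delta
    y[j] <- y[j] - delta
    expect_gte(tissueSpecificity(y), tau0 - 1e-12)
  }
})

test_that("expression summary computes level, divergence and pooled SD", {
  m <- data.frame(gene_id = "g",
                  species = rep(c("s1", "s2"), each = 2),
                  replicate = c(1, 2, 1, 2),
                  log2_signal = c(1, 3, 2, 4))
  s <- summarizeExpression(m, "g")
  expect_equal(s$level, 2.5)
  expect_equal(s$divergence, 1)
  expect_equal(s$polymorphism, sqrt(2))

  # species means 4 and 6
  m2 <- data.frame(gene_id = "g", species = c("s1", "s2"),
                   replicate = c(1, 1), log2_signal = c(4, 6))
  s2 <- summarizeExpression(m2, "g")
  expect_equal(s2$level, 5)
  expect_equal(s2$divergence, 2)
  expect_true(is.na(s2$polymorphism))   # < 2 replicates: undefined, not 0

  # identical replicate vectors: zero divergence and polymorphism
  m3 <- data.frame(gene_id = "g", species = rep(c("s1", "s2"), each = 3),
                   replicate = rep(1:3, 2), log2_signal = rep(c(2, 3, 4), 2))
  s3 <- summarizeExpression(m3, "g")
  expect_equal(s3$divergence, 0)
  expect_equal(s3$polymorphism, 1)      # pooled SD of (2,3,4) twice

  # symmetric in species labels
  m4 <- m
  m4$species <- rep(c("s2", "s1"), each = 2)
  s4 <- summarizeExpression(m4, "g")
  expect_equal(s4$level, s$level)
  expect_equal(s4$divergence, s$divergence)

  # missing species named in the error
  m5 <- m[m$species == "s1", ]
  m5 <- rbind(m5, data.frame(gene_id = "h", species = "s2", replicate = 1,
                             log2_signal = 5))
  expect_error(summarizeExpression(m5, "g"), "s2")
})

test_that("sex-bias classification partitions and is antisymmetric", {
  expect_identical(classifySexBias(8, 6), "MBG")
  expect_identical(classifySexBias(5, 5), "NBG")
  expect_identical(classifySexBias(3, 4.5), "FBG")
  expect_error(classifySexBias(Inf, 1), "finite")
  expect_error(classifySexBias(1, 2, log2Threshold = 0), "positive")
  set.seed(12)
  male <- rnorm(200, 6, 2)
  female <- rnorm(200, 6, 2)
  cls <- classifySexBias(male, female)
  expect_true(all(cls %in% c("MBG", "FBG", "NBG")))
  swapped <- classifySexBias(female, male)
  expect_identical(swapped[cls == "MBG"], rep("FBG", sum(cls == "MBG")))
  expect_identical(swapped[cls == "FBG"], rep("MBG", sum(cls == "FBG")))
  expect_identical(swapped[cls == "NBG"], rep("NBG", sum(cls == "NBG")))
})

test_that("summary table carries NA tau for genes absent from the tissue matrix", {
  m <- data.frame(gene_id = rep(c("a", "b"), each = 4),
                  species = rep(rep(c("s1", "s2"), each = 2), 2),
                  replicate = rep(1:2, 4),
                  log2_signal = rnorm(8, 5))
  tm <- matrix(runif(3), 1, 3, dimnames = list("a", NULL))
  es <- expressionSummaryTable(m, tm)
  expect_false(is.na(es$tau[es$gene_id == "a"]))
  expect_true(is.na(es$tau[es$gene_id == "b"]))
})
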