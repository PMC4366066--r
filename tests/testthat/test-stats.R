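# The statistical battery: exact branches against enumeration oracles,
# approximation branches against permutation oracles, regression contracts,
# and the stratified matched comparison's structural properties.

test_that("Mann-Whitney U: frozen exact cases", {
  t1 <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(t1$statistic), 0)
  expect_equal(t1$p.value, 0.1)          # 2 * 1/20 over all C(6,3) splits
  # identical samples: no separation
  t2 <- mannWhitneyU(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_gte(t2$p.value, 0.99)
})

test_that("Mann-Whitney exact branch equals the enumeration oracle across sizes", {
  set.seed(31)
  for (k in 1:25) {
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    x <- sample(seq_len(200), n1 + n2)   # distinct values: tie-free
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    for (sided in c("two", "greater", "less")) {
      got <- mannWhitneyU(a, b, sided = sided)
      expect_equal(got$p.value, oracleMannWhitneyP(a, b, sided),
                   tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney approximation with ties matches a permutation oracle", {
  set.seed(77)
  a <- sample(1:6, 30, replace = TRUE)
  b <- sample(2:7, 40, replace = TRUE)
  got <- mannWhitneyU(a, b)
  expect_match(got$note, "approximation")
  pPerm <- oraclePermutationMWP(a, b, nPerm = 20000)
  expect_lt(abs(got$p.value - pPerm), 0.02)
})

test_that("signed-rank: frozen exact cases and conventions", {
  t1 <- wilcoxonSignedRank(c(1, 2, 3))
  expect_equal(unname(t1$statistic), 0)
  expect_equal(t1$p.value, 0.25)                     # two-sided, 2/8
  expect_equal(wilcoxonSignedRank(c(1, 2, 3), sided = "greater")$p.value,
               0.125)
  # perfect antisymmetry: p = 1 up to the approximation convention
  t2 <- wilcoxonSignedRank(c(-2, -1, 1, 2))
  expect_gte(t2$p.value, 0.99)
  # zeros dropped before ranking
  t3 <- wilcoxonSignedRank(c(0, 0, 1, 2, 3))
  expect_equal(unname(t3$n), 3L)
  # all-zero differences: undefined with a note
  t4 <- wilcoxonSignedRank(c(0, 0, 0))
  expect_true(is.na(t4$p.value))
  expect_match(t4$note, "zero")
})

test_that("signed-rank exact branch equals the sign-flip enumeration oracle", {
  set.seed(13)
  for (k in 1:25) {
    n <- sample(1:8, 1)
    d <- sample(seq_len(100), n) * sample(c(-1, 1), n, replace = TRUE)
    for (sided in c("two", "greater", "less")) {
      got <- wilcoxonSignedRank(d, sided = sided)
      expect_equal(got$p.value, oracleSignedRankP(d, sided),
                   tolerance = 1e-12)
    }
  }
})

test_that("signed-rank approximation with ties matches a sign-flip oracle", {
  set.seed(5)
  d <- sample(c(-3, -2, -1, 1, 2, 3, 4), 40, replace = TRUE)
  got <- wilcoxonSignedRank(d)
  expect_match(got$note, "approximation")
  expect_lt(abs(got$p.value - oracleSignFlipP(d, 20000)), 0.02)
})

test_that("Spearman rho equals Pearson on midranks, with monotone limits", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(unname(spearmanRho(x, 2 * x + 1)$statistic), 1)
  expect_equal(unname(spearmanRho(x, -x^3)$statistic), -1)
  set.seed(8)
  xt <- sample(1:5, 30, replace = TRUE)
  yt <- xt + sample(1:4, 30, replace = TRUE)
  expect_equal(unname(spearmanRho(xt, yt)$statistic),
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_true(is.na(spearmanRho(rep(1, 10), rnorm(10))$statistic))
})

test_that("standardized OLS satisfies its algebraic contracts", {
  # exact linear response: R = 1, zero residuals
  set.seed(21)
  x1 <- rnorm(50)
  x2 <- rnorm(50)
  fit <- suppressWarnings(
    fitStandardizedOls(2 * x1 - 3 * x2 + 5, list(a = x1, b = x2)))
  expect_equal(fit$R, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  # 8-point toy against the closed-form normal-equations solution
  X <- cbind(a = c(1, 2, 3, 4, 5, 6, 7, 8.5),
             b = c(2, 1, 4, 3, 6, 5, 8, 7),
             c = c(1, 4, 2, 2, 5, 7, 3, 6))
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  fit <- fitStandardizedOls(y, as.data.frame(X))
  Z <- scale(X)
  zy <- as.numeric(scale(y))
  bHand <- solve(crossprod(Z), crossprod(Z, zy))   # intercept drops: centred
  expect_equal(unname(fit$bstar), as.numeric(bHand), tolerance = 1e-10)
  # residuals orthogonal to every covariate, summing to zero
  expect_lt(max(abs(crossprod(Z, fit$residuals))), 1e-8)
  expect_lt(abs(sum(fit$residuals)), 1e-9)

  # null behavior at large n
  set.seed(99)
  xb <- matrix(rnorm(3 * 4000), ncol = 3,
               dimnames = list(NULL, c("u", "v", "w")))
  fit0 <- fitStandardizedOls(rnorm(4000), as.data.frame(xb))
  expect_lt(max(abs(fit0$bstar)), 0.06)
  expect_lt(fit0$R, 0.06)

  # collinearity error names the offending pair
  expect_error(fitStandardizedOls(rnorm(20),
                                  list(p = 1:20, q = (1:20) * 2 + 1e-13)),
               "collinear")
})

test_that("residual group test equals calling Mann-Whitney on the split residuals", {
  set.seed(3)
  x <- rnorm(100)
  y <- x + rnorm(100)
  fit <- fitStandardizedOls(y, list(x = x))
  lab <- rep(c("X", "A"), 50)
  got <- residualGroupTest(fit, lab)
  want <- mannWhitneyU(fit$residuals[lab == "X"], fit$residuals[lab == "A"])
  expect_equal(got$p.value, want$p.value)
  expect_equal(got$statistic, want$statistic)
  expect_error(residualGroupTest(fit, rep("X", 100)), "nonempty")
})

test_that("rank bins are exactly equal-size with remainder to lower bins", {
  set.seed(4)
  b <- quantileBins(rnorm(100), 10)
  expect_equal(as.integer(table(b)), rep(10L, 10))
  b2 <- quantileBins(rnorm(103), 10)
  expect_equal(as.integer(table(b2)), c(11L, 11L, 11L, rep(10L, 7)))
  # rank-based: strictly monotone transforms leave bins unchanged
  x <- rgamma(77, 2)
  expect_identical(quantileBins(x, 5), quantileBins(log(x), 5))
  expect_identical(quantileBins(x, 5), quantileBins(rank(x), 5))
})

test_that("stratified comparison keeps only co-occupied categories and is rank-invariant", {
  set.seed(10)
  n <- 400
  lev <- rnorm(n)
  tau <- runif(n)
  deg <- rpois(n, 20)
  chrom <- rep(c("X", "A"), c(80, 320))
  resp <- rlnorm(n)
  sc <- stratifiedXAComparison(resp, lev, tau, deg, chrom, nBins = 4,
                               ids = sprintf("g%03d", 1:n))
  # every retained category has both classes
  expect_true(all(sc$categories$nX >= 1 & sc$categories$nA >= 1))
  # each gene maps to exactly one category triple
  expect_equal(nrow(sc$bins), n)
  # monotone transform of a covariate leaves the comparison unchanged
  sc2 <- stratifiedXAComparison(resp, exp(lev), tau^3, deg, chrom, nBins = 4,
                                ids = sprintf("g%03d", 1:n))
  expect_equal(sc$categories, sc2$categories)
  expect_equal(sc$test$p.value, sc2$test$p.value)
  # categories lacking one class contribute no pair: construct a covariate
  # value block holding only A genes
  lev2 <- lev
  aIdx <- which(chrom == "A")[1:100]
  lev2[aIdx] <- 100 + seq_len(100)                  # top bin (size 100) pure A
  sc3 <- stratifiedXAComparison(resp, lev2, tau, deg, chrom, nBins = 4,
                                ids = sprintf("g%03d", 1:n))
  topbin <- max(sc3$bins[, "level"])
  topcats <- startsWith(sc3$categories$category, paste0(topbin, "."))
  inTop <- sc3$bins[, "level"] == topbin
  expect_true(all(chrom[inTop] == "A"))
  expect_false(any(topcats))
  # insufficient overlap is an error
  expect_error(
    stratifiedXAComparison(resp[1:40], lev[1:40], tau[1:40], deg[1:40],
                           rep(c("X", "A"), c(1, 39))[sample(40)], nBins = 2),
    "insufficient overlap|fewer observations")
})
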