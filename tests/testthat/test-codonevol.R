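# NG86 counting against the independent enumeration oracle, and the ML
# estimator's structural guarantees (generator algebra, optimality,
# reversibility, agreement with counting at low divergence).

test_that("NG86 counting equals the exhaustive per-codon enumeration oracle", {
  set.seed(101)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    rp <- randomCleanPair(n, nMut = sample(0:(2 * n), 1))
    pair <- codonPair("t", rp$a, rp$b)
    got <- ng86(pair)
    want <- oracleNG86(rp$a, rp$b)
    expect_equal(got$syn_sites, want$S, tolerance = 1e-12)
    expect_equal(got$nonsyn_sites, want$N, tolerance = 1e-12)
    expect_equal(got$n_syn_diffs, want$Sd, tolerance = 1e-12)
    expect_equal(got$n_nonsyn_diffs, want$Nd, tolerance = 1e-12)
    expect_equal(got$dS, want$dS, tolerance = 1e-12)
    expect_equal(got$dN, want$dN, tolerance = 1e-12)
  }
})

test_that("NG86 limiting cases behave as defined", {
  p <- codonPair("id", "ATGAAACCC", "ATGAAACCC")
  e <- ng86(p)
  expect_equal(e$dN, 0)
  expect_equal(e$dS, 0)
  expect_true(is.na(e$omega))

  # single synonymous third-position change among many identical codons
  a <- paste(rep("CTG", 100), collapse = "")
  b <- paste(c(rep("CTG", 99), "CTA"), collapse = "")
  e <- ng86(codonPair("id", a, b))
  expect_equal(e$dN, 0)
  expect_gt(e$dS, 0)
  expect_equal(e$omega, 0)

  # codons with N or - excluded pairwise
  e <- ng86(codonPair("id", "ATGA-NAAA", "ATGAAAAAG"))
  expect_equal(e$n_codons_used, 2L)
})

test_that("rate matrix has zero row sums, the F3x4 stationary distribution, and unit scaling", {
  pair <- codonPair("x", "ATGAAACCCGGGTTTACG", "ATGAAGCCGGGATTCACG")
  pi <- codonFreqsF3x4(pair)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  Q <- gy94RateMatrix(kappa = 3.1, omega = 0.4, pi = pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_lt(max(abs(pi %*% Q)), 1e-10)          # stationarity
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance of the reversible generator
  F <- pi * Q
  expect_lt(max(abs(F - t(F))), 1e-14)
})

test_that("transition probabilities are a stochastic matrix with correct limits", {
  pi <- rep(1 / 61, 61)
  Q <- gy94RateMatrix(2, 0.5, pi)
  P <- fasterX:::.probMatrix(Q, 0.3, pi)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0))
  P0 <- fasterX:::.probMatrix(Q, 1e-12, pi)
  expect_lt(max(abs(P0 - diag(61))), 1e-9)
})

test_that("dN/dS decomposition reproduces omega and splits t", {
  pi <- rep(1 / 61, 61)
  d <- fasterX:::.decomposeDnDs(t = 0.3, kappa = 2, omega = 0.25, pi = pi)
  expect_equal(d$dN / d$dS, 0.25, tolerance = 1e-10)
  expect_equal(d$synSitesPerCodon + d$nonsynSitesPerCodon, 3, tolerance = 1e-12)
})

test_that("ML fit on an identical pair sits at the t lower bound with zero divergence", {
  seqs <- simulateCodonPair(0.5, 2, 0, nCodons = 500, seed = 7)
  fit <- gy94ML(seqs)
  expect_equal(fit$t, 1e-6, tolerance = 1e-9)
  expect_equal(fit$dN, 0)
  expect_equal(fit$dS, 0)
})

test_that("ML fit is invariant to swapping the two sequences", {
  p <- simulateCodonPair(0.4, 2.5, 0.25, nCodons = 400, seed = 11)
  f1 <- gy94ML(p)
  f2 <- gy94ML(codonPair(p@geneId, p@seqB, p@seqA))
  expect_equal(f1$logL, f2$logL, tolerance = 1e-5)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-3)
  expect_equal(f1$t, f2$t, tolerance = 1e-4)
})

test_that("ML optimum dominates a 10x10x10 grid over the parameter box", {
  p <- simulateCodonPair(0.3, 2, 0.2, nCodons = 300, seed = 5)
  fit <- gy94ML(p)
  pi <- codonFreqsF3x4(p)
  tab <- fasterX:::.codonTables()
  ia <- fasterX:::.senseIndex(fasterX:::splitCodons(p@seqA))
  ib <- fasterX:::.senseIndex(fasterX:::splitCodons(p@seqB))
  counts <- tabulate((ib - 1L) * 61L + ia, nbins = 61L * 61L)
  nz <- which(counts > 0)
  ll <- function(t, k, w) {
    P <- fasterX:::.probMatrix(gy94RateMatrix(k, w, pi), t, pi)
    ri <- ((nz - 1L) %% 61L) + 1L
    sum(counts[nz] * (log(pi[ri]) + log(pmax(P[nz], 1e-300))))
  }
  grid <- expand.grid(t = exp(seq(log(1e-6), log(10), length.out = 10)),
                      k = exp(seq(log(0.01), log(100), length.out = 10)),
                      w = exp(seq(log(1e-4), log(99), length.out = 10)))
  gmax <- max(mapply(ll, grid$t, grid$k, grid$w))
  expect_gte(fit$logL, gmax - 1e-6)
})

test_that("ML and NG86 agree on omega at low divergence", {
  set.seed(42)
  for (w in c(0.2, 0.8)) {
    p <- simulateCodonPair(w, 2, 0.05, nCodons = 800,
                           seed = sample.int(1e6, 1))
    fml <- gy94ML(p)
    fng <- ng86(p)
    expect_false(is.na(fng$omega))
    expect_lt(abs(fml$omega - fng$omega) / fng$omega, 0.35)
  }
})

test_that("ML recovers simulation parameters on average (small replicate set)", {
  ests <- vapply(1:12, function(k) {
    p <- simulateCodonPair(0.5, 2, 0.2, nCodons = 500, seed = 9000 + k)
    gy94ML(p)$omega
  }, numeric(1))
  expect_gt(mean(ests), 0.35)
  expect_lt(mean(ests), 0.65)
})
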