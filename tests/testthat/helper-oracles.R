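# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: the NG86 oracle works on codon strings
# with its own recursive pathway enumeration, and the exact-test oracles
# enumerate the full null distributions.

GENCODE <- Biostrings::GENETIC_CODE
STOPS <- names(GENCODE)[GENCODE == "*"]

oracleSplitCodons <- function(s) {
  s <- toupper(s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

## Per-codon NG86 site counts: fraction of the three single-nucleotide
## changes at each position that are synonymous / nonsynonymous, changes to
## stop codons excluded from both classes.
oracleSiteCounts <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  nonsyn <- 0
  for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch
    mut[p] <- alt
    mc <- paste(mut, collapse = "")
    if (mc %in% STOPS) next
    if (GENCODE[[mc]] == GENCODE[[codon]]) syn <- syn + 1 / 3
    else nonsyn <- nonsyn + 1 / 3
  }
  c(syn = syn, nonsyn = nonsyn)
}

## All minimal mutational pathways between two codons, as lists of codon
## steps; recursive construction.
oraclePathways <- function(from, to) {
  if (from == to) return(list(character(0)))
  fa <- strsplit(from, "")[[1]]
  ta <- strsplit(to, "")[[1]]
  out <- list()
  for (p in which(fa != ta)) {
    step <- fa
    step[p] <- ta[p]
    mid <- paste(step, collapse = "")
    for (rest in oraclePathways(mid, to))
      out <- c(out, list(c(mid, rest)))
  }
  out
}

## Pathway-averaged synonymous/nonsynonymous differences for a codon pair,
## excluding pathways through stop codons (fall back to all pathways with
## stop steps counted nonsynonymous when every pathway is blocked).
oracleDiffCounts <- function(from, to) {
  paths <- oraclePathways(from, to)
  if (length(paths) == 1 && length(paths[[1]]) == 0)
    return(c(syn = 0, nonsyn = 0))
  classify <- function(path, allowStops) {
    states <- c(from, path)
    if (!allowStops && any(states[-length(states)][-1] %in% STOPS))
      return(NULL)
    syn <- 0
    nonsyn <- 0
    for (k in seq_len(length(states) - 1)) {
      a <- states[k]
      b <- states[k + 1]
      if (a %in% STOPS || b %in% STOPS) nonsyn <- nonsyn + 1
      else if (GENCODE[[a]] == GENCODE[[b]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(paths, classify, allowStops = FALSE))
  if (length(res) == 0) res <- lapply(paths, classify, allowStops = TRUE)
  colMeans(do.call(rbind, res))
}

## Full NG86 estimate on two codon-aligned strings (no ambiguity handling;
## callers supply clean sequences).
oracleNG86 <- function(seqA, seqB) {
  ca <- oracleSplitCodons(seqA)
  cb <- oracleSplitCodons(seqB)
  sA <- colSums(do.call(rbind, lapply(ca, oracleSiteCounts)))
  sB <- colSums(do.call(rbind, lapply(cb, oracleSiteCounts)))
  S <- (sA[["syn"]] + sB[["syn"]]) / 2
  N <- (sA[["nonsyn"]] + sB[["nonsyn"]]) / 2
  d <- rowSums(mapply(oracleDiffCounts, ca, cb))
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  list(S = S, N = N, Sd = unname(d["syn"]), Nd = unname(d["nonsyn"]),
       dS = jc(d[["syn"]] / S), dN = jc(d[["nonsyn"]] / N))
}

## Random clean (stop-free) codon-aligned pair for oracle comparisons.
randomCleanPair <- function(nCodons, nMut = nCodons) {
  sense <- names(GENCODE)[GENCODE != "*"]
  a <- sample(sense, nCodons, replace = TRUE)
  b <- a
  for (k in seq_len(nMut)) {
    i <- sample(nCodons, 1)
    cand <- strsplit(b[i], "")[[1]]
    cand[sample(3, 1)] <- sample(c("A", "C", "G", "T"), 1)
    cand <- paste(cand, collapse = "")
    if (!(cand %in% STOPS)) b[i] <- cand
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

## Exact two-sided/one-sided Mann-Whitney p by complete enumeration of all
## choose(n1+n2, n1) group assignments (no ties assumed).
oracleMannWhitneyP <- function(a, b, sided = "two") {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  pLess <- mean(us <= uObs)
  pGreater <- mean(us >= uObs)
  switch(sided,
         two = min(1, 2 * min(pLess, pGreater)),
         greater = pGreater,
         less = pLess)
}

## Exact signed-rank p by enumeration of all 2^n sign assignments
## (zeros removed by caller; no ties in |d| assumed).
oracleSignedRankP <- function(d, sided = "two") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  pLess <- mean(vs <= vObs)
  pGreater <- mean(vs >= vObs)
  switch(sided,
         two = min(1, 2 * min(pLess, pGreater)),
         greater = pGreater,
         less = pLess)
}

## Monte-Carlo permutation p for Mann-Whitney with ties.
oraclePermutationMWP <- function(a, b, nPerm = 20000) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (length(b)) / 2
  us <- replicate(nPerm, {
    ii <- sample(length(pooled), n1)
    sum(r[ii]) - n1 * (n1 + 1) / 2
  })
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

## Monte-Carlo sign-flip p for the signed-rank test with ties.
oracleSignFlipP <- function(d, nFlip = 20000) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  vs <- replicate(nFlip, sum(r[runif(n) < 0.5]))
  mean(abs(vs - mu) >= abs(vObs - mu) - 1e-9)
}
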