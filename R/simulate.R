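# Codon-sequence simulation under the single-ratio codon model, and the
# closed-form chromosome copy-number accounting behind the 3/4 effective
# population size argument.

#' Simulate a codon-aligned orthologous pair
#'
#' Draws an ancestral sequence from `codonFreqs` and evolves it along a
#' single lineage of total length `t` (expected substitutions per codon)
#' under the single-ratio codon model ([gy94RateMatrix()]), by exact
#' Gillespie event sampling over the whole sequence.  Under reversibility
#' this is equivalent in distribution to evolving two branches of length
#' `t/2` from a stationary ancestor, so the returned `(seqA, seqB)` pair is
#' a valid pairwise sample at divergence `t`.  Stop codons are unreachable
#' by construction, and the pair contains no gaps.
#'
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param t total pairwise divergence, expected substitutions per codon
#'   (>= 0).
#' @param codonFreqs length-61 probability vector over the sense codons
#'   (must exclude stop codons and sum to 1 within 1e-9); default uniform.
#'   A length-64 vector is rejected.
#' @param nCodons number of codons to simulate.
#' @param seed integer seed (optional; caller RNG restored afterwards).
#' @param geneId identifier for the returned pair.
#' @return A [CodonPair-class] with `seqA` the ancestral and `seqB` the
#'   evolved sequence.
#' @export
simulateCodonPair <- function(omega, kappa, t, codonFreqs = NULL,
                              nCodons, seed = NULL, geneId = "sim") {
  tab <- .codonTables()
  stopifnot(omega >= 0, kappa > 0, t >= 0, nCodons >= 1)
  if (is.null(codonFreqs)) codonFreqs <- rep(1 / tab$N, tab$N)
  if (!is.null(names(codonFreqs))) {
    if (any(.isStopCodon(names(codonFreqs))))
      .stopf("codonFreqs must not contain stop codons")
    codonFreqs <- codonFreqs[tab$CODONS]
    if (anyNA(codonFreqs)) .stopf("codonFreqs names must be the sense codons")
  }
  if (length(codonFreqs) != tab$N)
    .stopf("codonFreqs must have length %d (sense codons)", tab$N)
  if (any(codonFreqs < 0) || abs(sum(codonFreqs) - 1) > 1e-9)
    .stopf("codonFreqs must be nonnegative and sum to 1 within 1e-9")
  pi <- as.numeric(codonFreqs)

  withSeed(seed, {
    state <- sample.int(tab$N, nCodons, replace = TRUE, prob = pi)
    anc <- state
    if (t > 0 && any(pi > 0)) {
      Q <- gy94RateMatrix(kappa, omega, pi)
      rates <- -diag(Q)
      Pjump <- Q
      diag(Pjump) <- 0
      ## whole-sequence Gillespie: total rate is the sum of per-codon exit
      ## rates; each event picks a codon proportional to its rate, then a
      ## destination from the embedded jump chain.
      total <- sum(rates[state])
      time <- 0
      repeat {
        if (total <= 0) break
        time <- time + rexp(1L, total)
        if (time > t) break
        cod <- sample.int(nCodons, 1L, prob = rates[state])
        s <- state[cod]
        new <- sample.int(tab$N, 1L, prob = Pjump[s, ])
        total <- total + rates[new] - rates[s]
        state[cod] <- new
      }
    }
    codonPair(geneId,
              paste(tab$CODONS[anc], collapse = ""),
              paste(tab$CODONS[state], collapse = ""))
  })
}

#' Chromosome copy accounting
#'
#' Closed-form accounting of chromosome copies carried by a population of
#' `nFemales` XX females and `nMales` XY males.  For the X chromosome the
#' population carries `2*nFemales + nMales` copies against
#' `2*(nFemales + nMales)` copies of any autosome, so at an equal sex ratio
#' the copy ratio is 3/4 -- the classic expectation that the effective
#' population size of the X is 3/4 that of the autosomes -- and 2/3 of X
#' copies reside in females (the X "spends 2/3 of its time in females").
#'
#' @param chromosomeClass `"X"` or `"autosome"` (also accepts `"A"`).
#' @param nFemales,nMales positive breeding counts.
#' @return list with `copyRatioVsAutosome` and `fractionInFemales`.
#' @examples
#' chromosomeCopyAccounting("X", 100, 100)   # 0.75 and 2/3
#' @export
chromosomeCopyAccounting <- function(chromosomeClass, nFemales, nMales) {
  chromosomeClass <- match.arg(chromosomeClass, c("X", "autosome", "A"))
  if (!(nFemales >= 1 && nMales >= 1))
    .stopf("nFemales and nMales must be >= 1")
  f <- as.numeric(nFemales)
  m <- as.numeric(nMales)
  if (chromosomeClass == "X") {
    xcopies <- 2 * f + m
    list(copyRatioVsAutosome = xcopies / (2 * (f + m)),
         fractionInFemales = 2 * f / xcopies)
  } else {
    list(copyRatioVsAutosome = 1,
         fractionInFemales = 2 * f / (2 * (f + m)))
  }
}
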