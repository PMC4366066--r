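# The single-ratio (one omega for all sites and lineages) codon substitution
# model with F3x4 equilibrium frequencies: rate-matrix construction,
# transition probabilities via eigendecomposition of the symmetrized
# reversible generator, and the decomposition of evolutionary distance t into
# dN and dS through the model's equilibrium synonymous/nonsynonymous flux.

#' F3x4 equilibrium codon frequencies from a codon pair
#'
#' Estimates position-specific nucleotide frequencies from both sequences of
#' a pair (codons containing ambiguity or gaps are excluded pairwise) and
#' forms sense-codon frequencies as the product over the three positions,
#' renormalized over the 61 sense codons.  With
#' `thirdPositionOnly = TRUE` the third-position nucleotide frequencies are
#' used at all three positions (a sensitivity variant; the standard F3x4
#' definition is the default).
#'
#' @param pair a [CodonPair-class].
#' @param thirdPositionOnly logical, see above.
#' @param floor lower bound applied to each nucleotide frequency before the
#'   product, guarding against structurally unreachable codons in short
#'   alignments.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
codonFreqsF3x4 <- function(pair, thirdPositionOnly = FALSE, floor = 1e-6) {
  tab <- .codonTables()
  ca <- splitCodons(pair@seqA)
  cb <- splitCodons(pair@seqB)
  ia <- .senseIndex(ca)
  ib <- .senseIndex(cb)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) .stopf("no usable codons in pair '%s'", pair@geneId)
  m <- rbind(tab$CMAT[ia[keep], , drop = FALSE],
             tab$CMAT[ib[keep], , drop = FALSE])
  f <- vapply(1:3, function(p)
    tabulate(match(m[, p], tab$NT), 4L), numeric(4L))    # 4 x 3, nt x pos
  f <- sweep(f, 2L, colSums(f), "/")
  f <- pmax(f, floor)
  f <- sweep(f, 2L, colSums(f), "/")
  if (thirdPositionOnly) f[, 1L] <- f[, 2L] <- f[, 3L]
  i1 <- match(tab$CMAT[, 1L], tab$NT)
  i2 <- match(tab$CMAT[, 2L], tab$NT)
  i3 <- match(tab$CMAT[, 3L], tab$NT)
  pi <- f[i1, 1L] * f[i2, 2L] * f[i3, 3L]
  pi <- pi / sum(pi)
  names(pi) <- tab$CODONS
  pi
}

#' Codon substitution rate matrix (single-ratio model)
#'
#' Builds the 61 x 61 reversible generator: single-nucleotide codon changes
#' occur at rate `pi_j * kappa^[transition] * omega^[nonsynonymous]`, all
#' other exchanges at rate 0; rows sum to zero.  The matrix is scaled so that
#' the expected number of substitutions per codon per unit time at
#' stationarity is 1, i.e. branch lengths are in expected substitutions per
#' codon.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi length-61 equilibrium codon frequencies (sense codons, summing
#'   to 1), e.g. from [codonFreqsF3x4()].
#' @param scale logical; scale to one expected substitution per codon per
#'   unit time (default) or leave unscaled.
#' @return 61 x 61 rate matrix with `pi` as stationary distribution.
#' @export
gy94RateMatrix <- function(kappa, omega, pi, scale = TRUE) {
  tab <- .codonTables()
  stopifnot(kappa > 0, omega >= 0, length(pi) == tab$N)
  pi <- pi / sum(pi)
  Q <- tab$ONEDIFF * rep(pi, each = tab$N)   # q_ij propto pi_j
  Q[tab$TS] <- Q[tab$TS] * kappa
  ns <- tab$NONSYN & tab$ONEDIFF
  Q[ns] <- Q[ns] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  dimnames(Q) <- list(tab$CODONS, tab$CODONS)
  Q
}

## Transition probability matrix exp(Q t) for the reversible generator,
## via eigendecomposition of the symmetrized matrix
## S = diag(sqrt(pi)) Q diag(1/sqrt(pi)); falls back to scaling-and-squaring
## if the decomposition degrades.
.probMatrix <- function(Q, t, pi) {
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- outer(1 / sp, sp) *
    (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  if (!all(is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-6)
    P <- .expmSS(Q * t)
  P[P < 0] <- 0
  P
}

## Matrix exponential by scaling and squaring with a Taylor/Pade-free
## series; used only as a fallback for ill-conditioned decompositions.
.expmSS <- function(A) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, max(abs(A))))) + 4L)
  A <- A / 2^s
  P <- diag(n) + A
  term <- A
  for (k in 2:16) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

## Equilibrium proportion of synonymous flux under the generator with the
## given parameters (unscaled proportions are scale-invariant).
.synFluxProportion <- function(kappa, omega, pi) {
  tab <- .codonTables()
  Q <- gy94RateMatrix(kappa, omega, pi, scale = FALSE)
  flux <- pi * Q
  syn <- tab$ONEDIFF & !tab$NONSYN
  ns <- tab$ONEDIFF & tab$NONSYN
  fs <- sum(flux[syn])
  fn <- sum(flux[ns])
  fs / (fs + fn)
}

## Decompose scaled divergence t (subs/codon) into dN and dS.  Site
## proportions come from the neutral (omega = 1) flux -- the mutational
## opportunity definition -- so S = 3 * rhoS1 and N = 3 * rhoN1 sites per
## codon; realized flux proportions use the fitted omega.
.decomposeDnDs <- function(t, kappa, omega, pi) {
  rhoS1 <- .synFluxProportion(kappa, 1, pi)
  fS <- .synFluxProportion(kappa, omega, pi)
  dS <- t * fS / (3 * rhoS1)
  dN <- t * (1 - fS) / (3 * (1 - rhoS1))
  list(dN = dN, dS = dS, synSitesPerCodon = 3 * rhoS1,
       nonsynSitesPerCodon = 3 * (1 - rhoS1))
}
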