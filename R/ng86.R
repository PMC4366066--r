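# Nei-Gojobori (1986) counting of synonymous and nonsynonymous sites and
# differences, with Jukes-Cantor multiple-hit correction.  Serves both as a
# stand-alone estimator and as the counting backend for the gene filters
# ("zero synonymous changes") and the ML starting values.

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences (single-nucleotide changes to stop codons are excluded from
#' both site classes).  Differences at codons differing at more than one
#' position are averaged over all minimal mutational pathways, excluding
#' pathways that pass through a stop codon.  Proportions are corrected by
#' the single-parameter Jukes-Cantor formula; a corrected proportion >= 3/4
#' yields `NA` for that distance.  `dS` is exactly 0 when zero synonymous
#' differences are observed.
#'
#' Codons containing `N` or `-` in either sequence are excluded pairwise.
#'
#' @param pair a [CodonPair-class]; should pass [validateCds()].
#' @return One-row data.frame with columns `gene_id`, `method` ("NG86"),
#'   `dN`, `dS`, `omega`, `kappa` (`NA`), `t` (substitutions per codon
#'   implied by the corrected distances), `logL` (`NA`),
#'   `n_codons_used`, `n_syn_diffs`, `n_nonsyn_diffs`, `syn_sites`,
#'   `nonsyn_sites`, `converged`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86 <- function(pair) {
  stopifnot(is(pair, "CodonPair"))
  tab <- .codonTables()
  ia <- .senseIndex(splitCodons(pair@seqA))
  ib <- .senseIndex(splitCodons(pair@seqB))
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]
  ib <- ib[keep]
  n <- length(ia)
  if (n == 0L) .stopf("no usable codons in pair '%s'", pair@geneId)
  S <- (sum(tab$SYN_SITES[ia]) + sum(tab$SYN_SITES[ib])) / 2
  N <- (sum(tab$NONSYN_SITES[ia]) + sum(tab$NONSYN_SITES[ib])) / 2
  Sd <- sum(tab$NG_SD[cbind(ia, ib)])
  Nd <- sum(tab$NG_ND[cbind(ia, ib)])
  jc <- function(p) {
    if (is.nan(p)) return(NA_real_)
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(Sd / S)
  dN <- jc(Nd / N)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  t <- if (!is.na(dN) && !is.na(dS)) (N * dN + S * dS) / n else NA_real_
  data.frame(gene_id = pair@geneId, method = "NG86", dN = dN, dS = dS,
             omega = omega, kappa = NA_real_, t = t, logL = NA_real_,
             n_codons_used = n, n_syn_diffs = Sd, n_nonsyn_diffs = Nd,
             syn_sites = S, nonsyn_sites = N, converged = TRUE,
             stringsAsFactors = FALSE)
}
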