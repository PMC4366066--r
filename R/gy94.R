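# Pairwise maximum-likelihood estimation of (t, kappa, omega) under the
# single-ratio codon model with F3x4 frequencies, and the vectorized
# divergence front-end used by the pipeline.

.ML_BOUNDS <- list(t = c(1e-6, 10), kappa = c(0.01, 100), omega = c(1e-4, 99))

#' Pairwise ML dN/dS under the single-ratio codon model (F3x4)
#'
#' Maximizes the pairwise likelihood over divergence `t` (expected
#' substitutions per codon), transition/transversion ratio `kappa` and
#' `omega` = dN/dS, with equilibrium codon frequencies estimated from the
#' pair by [codonFreqsF3x4()].  One sequence is taken at stationarity and
#' the other related by `exp(Q t)`; by reversibility the fit is invariant to
#' swapping the sequences.  Optimization is bounded multi-start local search
#' in log-parameter space (starts: NG86-informed, neutral `omega = 1`, and
#' `omega = 0.1`), bounds `t` in [1e-6, 10], `kappa` in [0.01, 100], `omega`
#' in [1e-4, 99], convergence tolerance 1e-8 on the log-likelihood.  `dN`
#' and `dS` are decomposed from `t` via the model's equilibrium
#' synonymous/nonsynonymous flux with mutational-opportunity (neutral-flux)
#' site counts.
#'
#' Codons containing `N` or `-` in either sequence are excluded pairwise
#' before frequency estimation and likelihood evaluation.  An identical
#' pair returns `t` at the lower bound with `dN = dS = 0`.
#'
#' @param pair a [CodonPair-class]; should pass [validateCds()].
#' @param init optional named list overriding the first start, any of
#'   `t`, `kappa`, `omega`.
#' @param thirdPositionOnly passed to [codonFreqsF3x4()].
#' @return One-row data.frame with the same columns as [ng86()] (`method`
#'   is "ML_M0"; `n_syn_diffs`/`n_nonsyn_diffs` carry the NG86 observed
#'   counts so downstream filters can use them; `converged` flags optimizer
#'   success).
#' @references Goldman N, Yang Z (1994) Mol Biol Evol 11:725-736; Yang Z
#'   (2007) Mol Biol Evol 24:1586-1591.
#' @export
gy94ML <- function(pair, init = NULL, thirdPositionOnly = FALSE) {
  stopifnot(is(pair, "CodonPair"))
  tab <- .codonTables()
  ia <- .senseIndex(splitCodons(pair@seqA))
  ib <- .senseIndex(splitCodons(pair@seqB))
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]
  ib <- ib[keep]
  n <- length(ia)
  if (n == 0L) .stopf("no usable codons in pair '%s'", pair@geneId)

  ng <- ng86(pair)
  pi <- codonFreqsF3x4(pair, thirdPositionOnly = thirdPositionOnly)

  counts <- tabulate((ib - 1L) * tab$N + ia, nbins = tab$N * tab$N)
  nz <- which(counts > 0L)
  cnt <- counts[nz]
  ri <- ((nz - 1L) %% tab$N) + 1L        # row (sequence A) index
  logpi <- log(pi[ri])

  if (all(ia == ib)) {                   # no differences: boundary fit
    t0 <- .ML_BOUNDS$t[1]
    P <- .probMatrix(gy94RateMatrix(2, 1, pi), t0, pi)
    ll <- sum(cnt * (logpi + log(pmax(P[nz], 1e-300))))
    return(.mlResult(pair, NA_real_, NA_real_, NA_real_, t0, 2, ll, n, ng,
                     TRUE))
  }

  negll <- function(par) {
    t <- exp(par[1L]); kappa <- exp(par[2L]); omega <- exp(par[3L])
    Q <- gy94RateMatrix(kappa, omega, pi)
    P <- .probMatrix(Q, t, pi)
    -sum(cnt * (logpi + log(pmax(P[nz], 1e-300))))
  }

  tNG <- ng$t
  if (!is.finite(tNG) || tNG <= 0) tNG <- 0.1
  omNG <- ng$omega
  if (!is.finite(omNG) || omNG <= 0) omNG <- 0.5
  start1 <- c(t = tNG, kappa = 2, omega = omNG)
  if (!is.null(init)) start1[names(init)] <- unlist(init)
  starts <- list(start1,
                 c(t = max(tNG, 0.05), kappa = 2, omega = 1),
                 c(t = max(tNG, 0.05), kappa = 2, omega = 0.1))

  lower <- log(vapply(.ML_BOUNDS, `[`, numeric(1L), 1L))
  upper <- log(vapply(.ML_BOUNDS, `[`, numeric(1L), 2L))
  best <- NULL
  anyConv <- FALSE
  for (s in starts) {
    p0 <- pmin(pmax(log(s), lower), upper)
    fit <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e-8 / .Machine$double.eps,
                                  maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    anyConv <- anyConv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) .stopf("optimizer failed for pair '%s'", pair@geneId)

  t <- exp(best$par[[1L]]); kappa <- exp(best$par[[2L]])
  omega <- exp(best$par[[3L]])
  dec <- .decomposeDnDs(t, kappa, omega, pi)
  .mlResult(pair, dec$dN, dec$dS, omega, t, kappa, -best$value, n, ng,
            anyConv)
}

.mlResult <- function(pair, dN, dS, omega, t, kappa, logL, n, ng, converged) {
  if (is.na(dN) && t <= .ML_BOUNDS$t[1]) { dN <- 0; dS <- 0 }
  data.frame(gene_id = pair@geneId, method = "ML_M0", dN = dN, dS = dS,
             omega = omega, kappa = kappa, t = t, logL = logL,
             n_codons_used = n, n_syn_diffs = ng$n_syn_diffs,
             n_nonsyn_diffs = ng$n_nonsyn_diffs, syn_sites = ng$syn_sites,
             nonsyn_sites = ng$nonsyn_sites, converged = converged,
             stringsAsFactors = FALSE)
}

#' Estimate divergence for a collection of codon pairs
#'
#' Runs [validateCds()] on each pair (trimming terminal stops), then applies
#' the requested estimator(s) to pairs passing QC; pairs failing QC get an
#' all-`NA` estimate row so the filter stage can record the exclusion.
#'
#' @param pairs list of [CodonPair-class] objects (or a single pair).
#' @param method "ng86", "ml" or "both".
#' @param thirdPositionOnly passed to [gy94ML()].
#' @return list with `estimates` (data.frame, one row per gene x method) and
#'   `qc` (data.frame of [validateCds()] reports, one row per gene).
#' @export
estimateDivergence <- function(pairs, method = c("ng86", "ml", "both"),
                               thirdPositionOnly = FALSE) {
  method <- match.arg(method)
  if (is(pairs, "CodonPair")) pairs <- list(pairs)
  qcs <- vector("list", length(pairs))
  est <- list()
  for (i in seq_along(pairs)) {
    v <- validateCds(pairs[[i]])
    qcs[[i]] <- v$report
    if (!v$report$ok) {
      est[[length(est) + 1L]] <- data.frame(
        gene_id = v$report$gene_id,
        method = if (method == "ml") "ML_M0" else "NG86",
        dN = NA_real_, dS = NA_real_, omega = NA_real_, kappa = NA_real_,
        t = NA_real_, logL = NA_real_, n_codons_used = NA_integer_,
        n_syn_diffs = NA_real_, n_nonsyn_diffs = NA_real_,
        syn_sites = NA_real_, nonsyn_sites = NA_real_, converged = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    p <- v$pair
    if (method %in% c("ng86", "both"))
      est[[length(est) + 1L]] <- ng86(p)
    if (method %in% c("ml", "both"))
      est[[length(est) + 1L]] <-
        gy94ML(p, thirdPositionOnly = thirdPositionOnly)
  }
  list(estimates = do.call(rbind, est), qc = do.call(rbind, qcs))
}
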