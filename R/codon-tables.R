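# Lookup tables over the 61 sense codons of the standard genetic code,
# built once at load time and shared by the simulator, the NG86 counter and
# the ML estimator.  All pairwise structure (single-nucleotide neighbourhood,
# transition vs transversion, synonymous vs nonsynonymous) is precomputed as
# 61 x 61 matrices so per-gene work is pure indexing.

.codon <- new.env(parent = emptyenv())

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

## NG86 pathway-averaged synonymous/nonsynonymous difference counts for one
## ordered codon pair, on integer nucleotide codes (1..4) with a 64-entry
## amino-acid/stop lookup.  Minimal mutational pathways are permutations of
## the differing positions; pathways passing through a stop codon are
## excluded (if every pathway is blocked, all pathways are used and
## stop-crossing steps count as nonsynonymous).
.ngPairCounts <- function(pa, pb, aa64, stop64, perms123) {
  dif <- which(pa != pb)
  if (length(dif) == 0L) return(c(syn = 0, nonsyn = 0))
  idx <- function(v) 16L * (v[1L] - 1L) + 4L * (v[2L] - 1L) + v[3L]
  walk <- function(order, allowStops) {
    cur <- pa
    syn <- 0
    nonsyn <- 0
    pre <- idx(cur)
    for (p in order) {
      cur[p] <- pb[p]
      post <- idx(cur)
      if (stop64[post] && !allowStops) return(NULL)
      if (stop64[pre] || stop64[post]) nonsyn <- nonsyn + 1
      else if (aa64[pre] == aa64[post]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      pre <- post
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  perms <- perms123[[length(dif)]]
  res <- Filter(Negate(is.null),
                lapply(perms, function(o) walk(dif[o], allowStops = FALSE)))
  if (length(res) == 0L)
    res <- lapply(perms, function(o) walk(dif[o], allowStops = TRUE))
  colMeans(do.call(rbind, res))
}

.buildCodonTables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons64 <- names(gc)
  aa64 <- unname(gc)
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  n <- length(codons)               # 61
  cmat <- do.call(rbind, strsplit(codons, ""))
  purine <- cmat %in% c("A", "G")
  dim(purine) <- dim(cmat)

  ndiff <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    dp <- outer(cmat[, p], cmat[, p], "!=")
    ndiff <- ndiff + dp
    samePur <- outer(purine[, p], purine[, p], "==")
    ts <- ts | (dp & samePur)       # only meaningful where ndiff == 1
  }
  onediff <- ndiff == 1L
  ts <- ts & onediff
  nonsyn <- outer(aa, aa, "!=")

  ## NG86 per-codon site counts: at each position the three single-nucleotide
  ## changes are classified; changes creating a stop codon are dropped from
  ## both site classes, so synSites + nonsynSites <= 3 per codon.
  nt <- c("T", "C", "A", "G")
  synSites <- numeric(n)
  nonsynSites <- numeric(n)
  for (i in seq_len(n)) {
    ch <- cmat[i, ]
    for (p in 1:3) for (alt in setdiff(nt, ch[p])) {
      mut <- ch
      mut[p] <- alt
      mc <- paste(mut, collapse = "")
      if (.isStopCodon(mc)) next
      if (gc[[mc]] == aa[i]) synSites[i] <- synSites[i] + 1 / 3
      else nonsynSites[i] <- nonsynSites[i] + 1 / 3
    }
  }

  ## integer-coded structures for the pathway walk over all 61 x 61 pairs
  imat <- matrix(match(cmat, nt), n, 3L)
  all64 <- as.matrix(expand.grid(n3 = 1:4, n2 = 1:4, n1 = 1:4))[, 3:1]
  cod64 <- paste0(nt[all64[, 1L]], nt[all64[, 2L]], nt[all64[, 3L]])
  aa64i <- unname(gc[cod64])
  stop64 <- aa64i == "*"
  perms123 <- lapply(1:3, function(k) .permutations(seq_len(k)))

  ngSd <- matrix(0, n, n)
  ngNd <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (ndiff[i, j] == 0L) next
    cnt <- .ngPairCounts(imat[i, ], imat[j, ], aa64i, stop64, perms123)
    ngSd[i, j] <- cnt[["syn"]]
    ngNd[i, j] <- cnt[["nonsyn"]]
  }

  list(CODONS = codons, AA = aa, N = n, ONEDIFF = onediff, TS = ts,
       NONSYN = nonsyn, NDIFF = ndiff, SYN_SITES = synSites,
       NONSYN_SITES = nonsynSites, NG_SD = ngSd, NG_ND = ngNd,
       CMAT = cmat, NT = nt)
}

.codonTables <- function() {
  if (is.null(.codon$CODONS)) {
    tab <- .buildCodonTables()
    for (nm in names(tab)) assign(nm, tab[[nm]], envir = .codon)
  }
  .codon
}

.onLoad <- function(libname, pkgname) {
  .codonTables()
  invisible()
}

## Map codon strings to indices in the 61-codon sense alphabet; stop codons
## and codons containing N/gaps/ambiguity map to NA.
.senseIndex <- function(codons) {
  tab <- .codonTables()
  match(codons, tab$CODONS)
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons, in the order used by
#'   all codon-indexed structures in the package (the order of
#'   [Biostrings::GENETIC_CODE] with stop codons removed).
#' @export
senseCodons <- function() .codonTables()$CODONS
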