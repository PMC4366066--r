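# Sequence quality control: the consensus-site depth/quality filter, codon
# alignment validation (stop codons, ambiguous codons, length), and the
# ordered gene-level exclusion rules.

#' Consensus site filter by read depth and consensus quality
#'
#' Retains a site only when read depth is strictly greater than `minDepth`
#' AND the phred-scaled consensus (or variant) quality is strictly greater
#' than `minQuality`; all other sites are masked with `N`.  Defaults follow
#' the 7x / Q40 consensus rule (both inequalities strict, so depth 7 or
#' quality 40 are masked).
#'
#' @param depths integer vector of per-site read depths.
#' @param qualities numeric vector of phred-scaled consensus qualities.
#' @param bases character vector of called bases (single characters).
#' @param minDepth,minQuality strict lower thresholds.
#' @return list with `masked` (character vector, masked sites as `"N"`),
#'   `retained` (logical vector) and `fractionRetained`.
#' @export
consensusSiteFilter <- function(depths, qualities, bases,
                                minDepth = 7, minQuality = 40) {
  n <- length(bases)
  if (length(depths) != n || length(qualities) != n)
    .stopf("depths (%d), qualities (%d) and bases (%d) must have equal length",
           length(depths), length(qualities), n)
  keep <- depths > minDepth & qualities > minQuality
  keep[is.na(keep)] <- FALSE
  masked <- as.character(bases)
  masked[!keep] <- "N"
  list(masked = masked, retained = keep,
       fractionRetained = if (n) mean(keep) else NA_real_)
}

#' Validate a codon-aligned CDS pair
#'
#' Checks alignment length, flags internal stop codons in either sequence
#' (a terminal stop codon present in a sequence is permitted and trimmed
#' from both), and counts codons containing `N` or `-` in either sequence
#' (these are excluded pairwise by all downstream counting).  `ok` is true
#' when the length is divisible by 3 and neither sequence has an internal
#' stop.
#'
#' @param pair a [CodonPair-class] (or a list/character of length 2, plus
#'   `geneId`).
#' @return list with `report` (one-row data.frame: `gene_id`, `ok`,
#'   `internal_stop_a`, `internal_stop_b`, `length_error`,
#'   `ambiguous_codon_count`) and `pair` (the possibly terminal-trimmed
#'   [CodonPair-class], or `NULL` on a length error).
#' @export
validateCds <- function(pair) {
  stopifnot(is(pair, "CodonPair"))
  rep1 <- function(ok, sa, sb, lenerr, amb)
    data.frame(gene_id = pair@geneId, ok = ok, internal_stop_a = sa,
               internal_stop_b = sb, length_error = lenerr,
               ambiguous_codon_count = amb, stringsAsFactors = FALSE)
  if (nchar(pair@seqA) %% 3L != 0L || nchar(pair@seqA) != nchar(pair@seqB))
    return(list(report = rep1(FALSE, FALSE, FALSE, TRUE, NA_integer_),
                pair = NULL))
  ca <- splitCodons(pair@seqA)
  cb <- splitCodons(pair@seqB)
  nc <- length(ca)
  ## terminal stop codon permitted in either sequence; trim the last codon
  ## column from both when present
  if (nc > 0L && (.isStopCodon(ca[nc]) || .isStopCodon(cb[nc]))) {
    ca <- ca[-nc]
    cb <- cb[-nc]
    pair <- codonPair(pair@geneId, paste(ca, collapse = ""),
                      paste(cb, collapse = ""))
    nc <- nc - 1L
  }
  stopA <- any(.isStopCodon(ca))
  stopB <- any(.isStopCodon(cb))
  amb <- sum(grepl("[N-]", ca) | grepl("[N-]", cb))
  list(report = rep1(!stopA && !stopB, stopA, stopB, FALSE, as.integer(amb)),
       pair = pair)
}

#' Gene-level divergence exclusion filters
#'
#' Applies, in order, the exclusion rules for unreliable divergence
#' estimates: (i) internal stop codon in either sequence (or a length
#' error), (ii) zero observed synonymous changes, (iii) `omega >=
#' omegaCap` (inclusive).  Each excluded gene carries exactly one primary
#' reason -- the first rule it trips.
#'
#' @param estimates data.frame of divergence estimates (from [ng86()],
#'   [gy94ML()] or [estimateDivergence()]); must contain `gene_id`,
#'   `n_syn_diffs` and `omega`.  With multiple methods per gene, the first
#'   row per gene is used (observed counts are method-independent).
#' @param qc data.frame of QC reports from [validateCds()], one row per
#'   gene.
#' @param omegaCap inclusive upper bound on omega (default 9).
#' @return list with `kept` (character vector of gene IDs), `excluded`
#'   (data.frame `gene_id`, `reason`) and `table` (per-gene disposition).
#' @export
applyDivergenceFilters <- function(estimates, qc, omegaCap = 9) {
  if (is.null(estimates) || nrow(estimates) == 0L)
    return(list(kept = character(0),
                excluded = data.frame(gene_id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE),
                table = data.frame(gene_id = character(0),
                                   disposition = character(0),
                                   stringsAsFactors = FALSE)))
  first <- estimates[!duplicated(estimates$gene_id), , drop = FALSE]
  qc <- qc[match(first$gene_id, qc$gene_id), , drop = FALSE]
  reason <- rep(NA_character_, nrow(first))
  reason[is.na(reason) & qc$length_error] <- "length_error"
  reason[is.na(reason) & (qc$internal_stop_a | qc$internal_stop_b)] <-
    "internal_stop"
  reason[is.na(reason) & first$n_syn_diffs == 0] <- "zero_synonymous_changes"
  reason[is.na(reason) & !is.na(first$omega) & first$omega >= omegaCap] <-
    "omega_cap"
  kept <- first$gene_id[is.na(reason)]
  excl <- data.frame(gene_id = first$gene_id[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  tab <- data.frame(gene_id = first$gene_id,
                    disposition = ifelse(is.na(reason), "analyzed",
                                         paste0("excluded:", reason)),
                    stringsAsFactors = FALSE)
  list(kept = kept, excluded = excl, table = tab)
}
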