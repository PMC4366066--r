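# Per-gene expression properties: level, between-species divergence,
# within-species polymorphism, the tau tissue-specificity index, and the
# sex-bias classification.

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over the `N >= 2` tissues of a
#' nonnegative expression profile.  0 for a uniform profile, 1 for
#' expression confined to a single tissue, and invariant to positive
#' scaling.
#'
#' @param profile numeric vector of per-tissue expression values (length
#'   >= 2, nonnegative, at least one positive).
#' @return tau in `[0, 1]`.
#' @references Yanai I et al. (2005) Bioinformatics 21:650-659.
#' @examples
#' tissueSpecificity(c(5, 5, 5, 5))  # 0
#' tissueSpecificity(c(7, 0, 0, 0))  # 1
#' tissueSpecificity(c(2, 1, 1))     # 0.5
#' @export
tissueSpecificity <- function(profile) {
  profile <- as.numeric(profile)
  if (length(profile) < 2L) .stopf("profile needs at least 2 tissues")
  if (anyNA(profile) || any(profile < 0))
    .stopf("profile must be nonnegative with no missing values")
  mx <- max(profile)
  if (mx <= 0) .stopf("profile must have at least one positive value")
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Summarize per-gene expression level, divergence and polymorphism
#'
#' From replicate-level log2 measurements in two species: level is the
#' unweighted mean of the two species' mean log2 signals; divergence is the
#' absolute difference of the species means; polymorphism is the pooled
#' within-species standard deviation (per-species denominators n-1, pooled
#' by degrees of freedom).  With fewer than 2 replicates in either species
#' polymorphism is `NA` (undefined), never 0.
#'
#' @param measurements data.frame with columns `gene_id`, `species` (two
#'   levels), `replicate`, `log2_signal`.
#' @param gene gene ID to summarize.
#' @return list with `level`, `divergence`, `polymorphism`.
#' @examples
#' m <- data.frame(gene_id = "g", species = rep(c("a", "b"), each = 2),
#'                 replicate = c(1, 2, 1, 2), log2_signal = c(1, 3, 2, 4))
#' summarizeExpression(m, "g")  # level 2.5, divergence 1, polymorphism sqrt(2)
#' @export
summarizeExpression <- function(measurements, gene) {
  d <- measurements[measurements$gene_id == gene, , drop = FALSE]
  if (nrow(d) == 0L) .stopf("gene '%s' absent from measurements", gene)
  sp <- sort(unique(as.character(measurements$species)))
  if (length(sp) != 2L)
    .stopf("measurements must contain exactly 2 species, found %d", length(sp))
  for (s in sp) if (!any(d$species == s))
    .stopf("gene '%s' has no measurements in species '%s'", gene, s)
  x1 <- d$log2_signal[d$species == sp[1L]]
  x2 <- d$log2_signal[d$species == sp[2L]]
  m1 <- mean(x1)
  m2 <- mean(x2)
  pooled <- if (length(x1) >= 2L && length(x2) >= 2L) {
    sqrt(((length(x1) - 1L) * var(x1) + (length(x2) - 1L) * var(x2)) /
           (length(x1) + length(x2) - 2L))
  } else NA_real_
  list(level = (m1 + m2) / 2, divergence = abs(m1 - m2),
       polymorphism = pooled)
}

#' Classify sex bias from male and female expression levels
#'
#' MBG when `male - female >= log2Threshold`, FBG when
#' `female - male >= log2Threshold`, otherwise NBG.  The default threshold
#' of 1 on the log2 scale is a 2-fold change.  Vectorized.
#'
#' @param maleLevel,femaleLevel finite log2 expression levels.
#' @param log2Threshold positive log2 fold-change threshold.
#' @return character vector in `{MBG, FBG, NBG}`.
#' @export
classifySexBias <- function(maleLevel, femaleLevel, log2Threshold = 1) {
  if (length(log2Threshold) != 1L || !is.finite(log2Threshold) ||
      log2Threshold <= 0)
    .stopf("log2Threshold must be a positive finite scalar")
  if (anyNA(maleLevel) || anyNA(femaleLevel) ||
      any(!is.finite(maleLevel)) || any(!is.finite(femaleLevel)))
    .stopf("expression levels must be finite")
  diff <- maleLevel - femaleLevel
  ifelse(diff >= log2Threshold, "MBG",
         ifelse(-diff >= log2Threshold, "FBG", "NBG"))
}

#' Per-gene expression summary table
#'
#' Vectorized wrapper combining [summarizeExpression()] over all genes with
#' tau from a tissue matrix and an optional bias classification.  Genes
#' absent from the tissue matrix carry `tau = NA` and are dropped later
#' from property-adjusted analyses.
#'
#' @param measurements replicate-level table (see [summarizeExpression()]).
#' @param tissueMatrix optional genes x tissues matrix with gene IDs as row
#'   names.
#' @param biasClass optional named character vector of MBG/FBG/NBG labels.
#' @return data.frame with columns `gene_id`, `level`, `divergence`,
#'   `polymorphism`, `tau`, `bias_class`.
#' @export
expressionSummaryTable <- function(measurements, tissueMatrix = NULL,
                                   biasClass = NULL) {
  sp <- sort(unique(as.character(measurements$species)))
  if (length(sp) != 2L)
    .stopf("measurements must contain exactly 2 species, found %d", length(sp))
  byg <- function(values, f)
    tapply(values, measurements$gene_id, f)
  s1 <- measurements$species == sp[1L]
  agg <- function(sel, f) {
    r <- tapply(measurements$log2_signal[sel], measurements$gene_id[sel], f)
    r
  }
  ids <- sort(unique(measurements$gene_id))
  m1 <- agg(s1, mean)[ids]
  m2 <- agg(!s1, mean)[ids]
  n1 <- agg(s1, length)[ids]
  n2 <- agg(!s1, length)[ids]
  v1 <- agg(s1, var)[ids]
  v2 <- agg(!s1, var)[ids]
  pooled <- ifelse(n1 >= 2 & n2 >= 2,
                   sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)),
                   NA_real_)
  tau <- rep(NA_real_, length(ids))
  if (!is.null(tissueMatrix)) {
    hit <- match(ids, rownames(tissueMatrix))
    ok <- !is.na(hit)
    tau[ok] <- apply(tissueMatrix[hit[ok], , drop = FALSE], 1L,
                     tissueSpecificity)
  }
  bias <- rep(NA_character_, length(ids))
  if (!is.null(biasClass)) bias <- unname(biasClass[ids])
  data.frame(gene_id = ids, level = unname((m1 + m2) / 2),
             divergence = unname(abs(m1 - m2)), polymorphism = unname(pooled),
             tau = tau, bias_class = bias, stringsAsFactors = FALSE)
}
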