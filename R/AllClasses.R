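#' CodonPair: a codon-aligned pair of orthologous coding sequences
#'
#' Holds two codon-aligned nucleotide sequences sharing a gene ID.  The
#' alignment may contain `N` and `-` symbols; codons containing either are
#' excluded pairwise by all downstream counting and likelihood code.
#'
#' @slot geneId single gene identifier shared by the two sequences.
#' @slot seqA,seqB uppercase nucleotide strings over `{A,C,G,T,N,-}`, equal
#'   lengths divisible by 3.
#'
#' @seealso [codonPair()], [validateCds()], [ng86()], [gy94ML()]
#' @export
setClass("CodonPair",
  representation(geneId = "character", seqA = "character", seqB = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
    if (length(object@seqA) != 1L || length(object@seqB) != 1L)
      msg <- c(msg, "seqA and seqB must be single strings")
    else {
      if (nchar(object@seqA) != nchar(object@seqB))
        msg <- c(msg, "seqA and seqB must have equal length")
      ## length not divisible by 3 is permitted at construction so the QC
      ## stage can flag it ([validateCds()]); counting requires whole codons
      bad <- grepl("[^ACGTN-]", paste0(object@seqA, object@seqB))
      if (bad) msg <- c(msg, "sequences may only contain A, C, G, T, N, -")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CodonPair
#'
#' @param geneId gene identifier.
#' @param seqA,seqB codon-aligned nucleotide strings (case-insensitive).
#' @return A [CodonPair-class] object.
#' @examples
#' codonPair("g1", "ATGAAA", "ATGAAG")
#' @export
codonPair <- function(geneId, seqA, seqB) {
  new("CodonPair", geneId = as.character(geneId),
      seqA = toupper(as.character(seqA)), seqB = toupper(as.character(seqB)))
}

#' @describeIn CodonPair-class number of codon columns in the alignment.
#' @param x,object a `CodonPair`.
#' @export
setMethod("length", "CodonPair", function(x) nchar(x@seqA) %/% 3L)

setMethod("show", "CodonPair", function(object) {
  cat("CodonPair", object@geneId, "-", length(object), "codons\n")
  trim <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat("  A:", trim(object@seqA), "\n  B:", trim(object@seqB), "\n")
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Describes a synthetic genome-scale dataset: gene counts and chromosome /
#' sex-bias composition, the codon-evolution parameters used to simulate
#' orthologous CDS pairs, tissue-profile concentrations controlling tau, the
#' log-linear models generating expression divergence and polymorphism from
#' gene properties, and the multiplicative faster-X inflation applied to
#' X-linked male-biased genes (1 = null).  Use [simulationConfig()] to build
#' one; defaults encode the desk-scale study conditions documented in the
#' methods vignette.
#'
#' @slot nGenes number of genes.
#' @slot propX fraction of X-linked genes (quota-rounded, deterministic).
#' @slot biasProps named fractions for MBG/FBG/NBG, summing to 1.
#' @slot omegaDist list: per-class gamma means (`mean`, named MBG/FBG/NBG)
#'   and common `shape` for the true dN/dS ratio of each gene.
#' @slot kappa transition/transversion rate ratio of the codon model.
#' @slot tDist list(`mean`, `shape`): gamma distribution of pairwise
#'   divergence, in expected substitutions per codon.
#' @slot nCodonsDist list(`meanlog`, `sdlog`, `min`): lognormal CDS length
#'   (codons), rounded, floored at `min`.
#' @slot nTissues number of tissues in the expression atlas.
#' @slot tauConcentration named per-class symmetric Dirichlet concentration
#'   for tissue profiles; smaller values give more tissue-specific profiles
#'   (higher tau).
#' @slot levelDist list(`mean`, `sd`): normal log2 expression level.
#' @slot divergenceModel list of coefficients (`intercept`, `bLevel`, `bTau`,
#'   `bDegree`, `sigma`) of the log-linear expression-divergence model.
#' @slot xMbgInflation multiplicative inflation of expression divergence for
#'   genes that are both X-linked and male-biased; 1 defines the null.
#' @slot polymorphismModel analogous coefficients for within-species
#'   expression dispersion.
#' @slot degreeDist list: per-class negative-binomial means (`mean`, named)
#'   and `size` for interaction degree.
#' @slot nReplicates strains/replicates per species in the expression table.
#' @slot makeSequences logical; simulate codon pairs (set `FALSE` for
#'   expression-only studies where sequence simulation would be wasted).
#' @slot seed master seed; every random stream derives from it.
#'
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", propX = "numeric", biasProps = "numeric",
    omegaDist = "list", kappa = "numeric", tDist = "list",
    nCodonsDist = "list", nTissues = "integer", tauConcentration = "numeric",
    levelDist = "list", divergenceModel = "list", xMbgInflation = "numeric",
    polymorphismModel = "list", degreeDist = "list", nReplicates = "integer",
    makeSequences = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
    chk(length(object@nGenes) == 1L && object@nGenes >= 1L,
        "nGenes must be a positive integer")
    chk(length(object@propX) == 1L && object@propX >= 0 && object@propX <= 1,
        "propX must lie in [0, 1]")
    bp <- object@biasProps
    chk(length(bp) == 3L && setequal(names(bp), c("MBG", "FBG", "NBG")),
        "biasProps must be named MBG, FBG, NBG")
    chk(all(bp >= 0) && all(bp <= 1), "biasProps must lie in [0, 1]")
    chk(abs(sum(bp) - 1) <= 1e-12, "biasProps must sum to 1 (tol 1e-12)")
    chk(object@kappa > 0, "kappa must be strictly positive")
    chk(all(object@tauConcentration > 0),
        "tauConcentration must be strictly positive")
    chk(all(object@omegaDist$mean > 0) && object@omegaDist$shape > 0,
        "omegaDist parameters must be strictly positive")
    chk(object@tDist$mean > 0 && object@tDist$shape > 0,
        "tDist parameters must be strictly positive")
    chk(object@nCodonsDist$min >= 1, "nCodonsDist$min must be >= 1")
    chk(object@nTissues >= 2L, "nTissues must be >= 2")
    chk(object@xMbgInflation >= 0, "xMbgInflation must be >= 0")
    chk(all(object@degreeDist$mean >= 0) && object@degreeDist$size > 0,
        "degreeDist parameters must be positive")
    chk(object@nReplicates >= 1L, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,",
      sprintf("%.1f%% X-linked,", 100 * object@propX),
      sprintf("bias MBG/FBG/NBG = %.2f/%.2f/%.2f\n",
              object@biasProps[["MBG"]], object@biasProps[["FBG"]],
              object@biasProps[["NBG"]]))
  cat("  faster-X inflation (X MBG expression divergence):",
      object@xMbgInflation, if (object@xMbgInflation == 1) "(null)\n" else "\n")
  cat("  kappa =", object@kappa, "| mean t =", object@tDist$mean,
      "subs/codon | sequences:", object@makeSequences,
      "| seed =", object@seed, "\n")
})

#' SyntheticDataset: one realization of the generator
#'
#' Container for all synthetic inputs of the analysis: the per-gene table of
#' covariates and true generative quantities, per-species replicate-level
#' expression measurements, a gene-by-tissue expression matrix, an
#' interaction edge list, and (optionally) simulated codon-aligned CDS
#' pairs.  Access slots through [geneTable()], [expressionMeasurements()],
#' [tissueMatrix()], [interactionEdges()], [codonPairs()], [simConfig()].
#'
#' @slot geneTable data.frame, one row per gene: `gene_id`, `chrom` (X/A),
#'   `bias_class`, `level`, `tau`, `degree` (realized incident edge count),
#'   `expression_divergence`, `expression_polymorphism`, and when sequences
#'   are simulated `omega_true`, `t_true`, `n_codons`.
#' @slot expressionMeasurements data.frame: `gene_id`, `species`,
#'   `replicate`, `log2_signal`.
#' @slot tissueMatrix numeric matrix, genes x tissues, nonnegative.
#' @slot interactionEdges data.frame with columns `from`, `to` (gene IDs).
#' @slot codonPairs named list of [CodonPair-class] (possibly empty).
#' @slot config the generating [SimulationConfig-class] (echo).
#' @slot seedUsed the master seed actually used.
#'
#' @export
setClass("SyntheticDataset",
  representation(geneTable = "data.frame",
    expressionMeasurements = "data.frame", tissueMatrix = "matrix",
    interactionEdges = "data.frame", codonPairs = "list",
    config = "SimulationConfig", seedUsed = "integer"),
  validity = function(object) {
    msg <- character(0)
    gt <- object@geneTable
    ids <- gt$gene_id
    if (anyDuplicated(ids)) msg <- c(msg, "duplicated gene_id in geneTable")
    pid <- names(object@codonPairs)
    if (anyDuplicated(pid)) msg <- c(msg, "duplicated gene_id in codonPairs")
    if (length(pid) && !all(pid %in% ids))
      msg <- c(msg, "codonPairs contain IDs absent from geneTable")
    if (any(object@tissueMatrix < 0))
      msg <- c(msg, "tissueMatrix must be nonnegative")
    if (nrow(object@tissueMatrix) &&
        !all(apply(object@tissueMatrix, 1L, max) > 0))
      msg <- c(msg, "each gene needs at least one positive tissue value")
    ed <- object@interactionEdges
    inc <- table(factor(c(ed$from, ed$to), levels = ids))
    if (!all(gt$degree == as.integer(inc[ids])))
      msg <- c(msg, "geneTable degree must equal incident edge count")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SyntheticDataset", function(object) {
  gt <- object@geneTable
  cat("SyntheticDataset:", nrow(gt), "genes (",
      sum(gt$chrom == "X"), "X /", sum(gt$chrom == "A"), "A ),",
      length(object@codonPairs), "codon pairs,",
      nrow(object@interactionEdges), "interaction edges\n")
  print(table(chrom = gt$chrom, bias = gt$bias_class))
})

#' @describeIn SyntheticDataset-class per-gene covariate table.
#' @param object a `SyntheticDataset`.
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("geneTable", "SyntheticDataset", function(object) object@geneTable)

#' @describeIn SyntheticDataset-class replicate-level expression table.
#' @export
setGeneric("expressionMeasurements",
           function(object) standardGeneric("expressionMeasurements"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("expressionMeasurements", "SyntheticDataset",
          function(object) object@expressionMeasurements)

#' @describeIn SyntheticDataset-class gene-by-tissue matrix.
#' @export
setGeneric("tissueMatrix", function(object) standardGeneric("tissueMatrix"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("tissueMatrix", "SyntheticDataset",
          function(object) object@tissueMatrix)

#' @describeIn SyntheticDataset-class interaction edge list.
#' @export
setGeneric("interactionEdges",
           function(object) standardGeneric("interactionEdges"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("interactionEdges", "SyntheticDataset",
          function(object) object@interactionEdges)

#' @describeIn SyntheticDataset-class named list of simulated codon pairs.
#' @export
setGeneric("codonPairs", function(object) standardGeneric("codonPairs"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("codonPairs", "SyntheticDataset", function(object) object@codonPairs)

#' @describeIn SyntheticDataset-class the generating configuration.
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))
#' @rdname SyntheticDataset-class
#' @export
setMethod("simConfig", "SyntheticDataset", function(object) object@config)

#' FasterXReport: results of a full pipeline run
#'
#' @slot master gene-level master table: covariates, divergence estimates,
#'   QC flags and a `disposition` column (`analyzed` or `excluded:<reason>`).
#' @slot tests data.frame of rank-test results.
#' @slot regressions data.frame of standardized-regression parameters (one
#'   row per gene class x response, columns R, b* per covariate, with P).
#' @slot correlations data.frame of Spearman correlations of dN/dS/omega
#'   with level, tau and interaction degree.
#' @slot stratified list of stratified X-vs-A comparison results.
#' @slot meta run metadata (config echo, seed, package version, timestamps).
#' @export
setClass("FasterXReport",
  representation(master = "data.frame", tests = "data.frame",
    regressions = "data.frame", correlations = "data.frame",
    stratified = "list", meta = "list"))

setMethod("show", "FasterXReport", function(object) {
  disp <- table(sub(":.*$", "", object@master$disposition))
  cat("FasterXReport:", nrow(object@master), "genes (")
  cat(paste(names(disp), as.integer(disp), sep = " = ", collapse = ", "), ")\n")
  cat("  tests:", nrow(object@tests),
      "| regressions:", nrow(object@regressions),
      "| stratified comparisons:", length(object@stratified), "\n")
})
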