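# The synthetic-data generator: a genome-scale gene table with the
# correlation structure the faster-X analysis assumes (divergence falling
# with expression level and interaction degree, rising with tissue
# specificity), replicate-level expression measurements, a tissue atlas, a
# configuration-model interaction network, and codon pairs evolved under
# the same codon model the estimator fits.

#' Build a simulation configuration
#'
#' All arguments have defaults encoding the desk-scale study conditions
#' (documented with rationale in the methods vignette): 16% X-linked genes,
#' 20/20/60% MBG/FBG/NBG composition, a 25-tissue atlas, kappa = 2,
#' per-class true-omega means 0.15/0.10/0.07, and a log-linear expression
#' divergence model whose coefficients reproduce the canonical signs
#' (negative in level and interactions, positive in tau).
#' `xMbgInflation = 1` is the null; values above 1 inflate expression
#' divergence of X-linked male-biased genes multiplicatively.
#'
#' @param nGenes,propX,biasProps,omegaDist,kappa,tDist,nCodonsDist,nTissues
#'   see [SimulationConfig-class].
#' @param tauConcentration,levelDist,divergenceModel,xMbgInflation
#'   see [SimulationConfig-class].
#' @param polymorphismModel,degreeDist,nReplicates,makeSequences,seed
#'   see [SimulationConfig-class].
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 2000L, propX = 0.16,
    biasProps = c(MBG = 0.20, FBG = 0.20, NBG = 0.60),
    omegaDist = list(mean = c(MBG = 0.15, FBG = 0.10, NBG = 0.07), shape = 2),
    kappa = 2,
    tDist = list(mean = 0.06, shape = 4),
    nCodonsDist = list(meanlog = log(400), sdlog = 0.4, min = 50),
    nTissues = 25L,
    tauConcentration = c(MBG = 0.2, FBG = 0.4, NBG = 0.8),
    levelDist = list(mean = 8, sd = 2),
    divergenceModel = list(intercept = log(0.3), bLevel = -0.35, bTau = 0.3,
                           bDegree = -0.25, sigma = 0),
    xMbgInflation = 1,
    polymorphismModel = list(intercept = log(0.2), bLevel = -0.35,
                             bTau = 0.1, bDegree = -0.05, sigma = 0.5),
    degreeDist = list(mean = c(MBG = 40, FBG = 50, NBG = 80), size = 2),
    nReplicates = 4L, makeSequences = TRUE, seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes), propX = propX,
      biasProps = biasProps[c("MBG", "FBG", "NBG")], omegaDist = omegaDist,
      kappa = kappa, tDist = tDist, nCodonsDist = nCodonsDist,
      nTissues = as.integer(nTissues), tauConcentration = tauConcentration,
      levelDist = levelDist, divergenceModel = divergenceModel,
      xMbgInflation = xMbgInflation, polymorphismModel = polymorphismModel,
      degreeDist = degreeDist, nReplicates = as.integer(nReplicates),
      makeSequences = makeSequences, seed = as.integer(seed))
}

## Largest-remainder quota counts: exact class sizes at any n.
.quotaCounts <- function(n, props) {
  q <- n * props / sum(props)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## Configuration-model interaction network for a target degree sequence:
## igraph's stub-matching sampler with self-loops and multi-edges removed
## (in-package stub matching as fallback).  Returns the edge list and the
## realized degrees.
.interactionNetwork <- function(degTarget, ids) {
  deg <- as.integer(degTarget)
  if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
  g <- tryCatch(
    igraph::simplify(igraph::sample_degseq(deg, method = "configuration")),
    error = function(e) NULL)
  if (is.null(g)) {
    stubs <- sample(rep.int(seq_along(deg), deg))
    a <- stubs[seq(1L, length(stubs), 2L)]
    b <- stubs[seq(2L, length(stubs), 2L)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    keep <- lo != hi & !duplicated(lo * (length(deg) + 1) + hi)
    el <- cbind(lo[keep], hi[keep])
  } else {
    el <- igraph::as_edgelist(g, names = FALSE)
  }
  realized <- tabulate(c(el[, 1L], el[, 2L]), nbins = length(deg))
  list(edges = data.frame(from = ids[el[, 1L]], to = ids[el[, 2L]],
                          stringsAsFactors = FALSE),
       degree = as.integer(realized))
}

#' Generate a synthetic dataset
#'
#' Realizes a [SimulationConfig-class].  Chromosome and sex-bias labels are
#' assigned by deterministic largest-remainder quota (bias quotas applied
#' within each chromosome class), so configured proportions are exact at any
#' `nGenes`.  Each gene draws its tissue profile, expression level, target
#' interaction degree, true omega/divergence-time/length, and model noise
#' from its own RNG substream derived from the master seed, so enlarging a
#' dataset leaves existing genes' values unchanged; the interaction graph
#' and codon-pair simulations use further derived streams.  Expression
#' divergence is the log-linear `divergenceModel` applied to the gene's
#' covariates, multiplied by `xMbgInflation` for genes that are both
#' X-linked and male-biased; replicate-level measurements are constructed
#' so that species means and pooled within-species SD recover the
#' generative divergence and polymorphism exactly.  Identical configs give
#' bit-identical datasets.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SyntheticDataset-class].
#' @export
generateDataset <- function(config) {
  validObject(config)
  n <- config@nGenes
  master <- config@seed
  ids <- sprintf("g%05d", seq_len(n))

  nx <- .quotaCounts(n, c(config@propX, 1 - config@propX))[1L]
  chrom <- rep(c("X", "A"), c(nx, n - nx))
  bias <- character(n)
  for (cl in c("X", "A")) {
    idx <- which(chrom == cl)
    cnt <- .quotaCounts(length(idx), config@biasProps)
    bias[idx] <- rep(c("MBG", "FBG", "NBG"), cnt)
  }

  R <- config@nReplicates
  nt <- config@nTissues
  tissue <- matrix(0, n, nt, dimnames = list(ids, paste0("tissue", seq_len(nt))))
  level <- numeric(n)
  degT <- integer(n)
  omegaT <- numeric(n)
  tT <- numeric(n)
  nCod <- integer(n)
  epsD <- numeric(n)
  epsP <- numeric(n)
  zFold <- numeric(n)
  repE <- matrix(0, n, 2L * R)

  conc <- config@tauConcentration
  dmu <- config@degreeDist$mean
  for (i in seq_len(n)) {
    set.seed(.substreamSeed(master, i))
    b <- bias[i]
    tissue[i, ] <- rgamma(nt, shape = conc[[b]])
    if (max(tissue[i, ]) <= 0) tissue[i, 1L] <- 1e-8   # a.s. unreachable
    level[i] <- rnorm(1L, config@levelDist$mean, config@levelDist$sd)
    degT[i] <- rnbinom(1L, size = config@degreeDist$size, mu = dmu[[b]])
    omegaT[i] <- rgamma(1L, shape = config@omegaDist$shape,
                        rate = config@omegaDist$shape / config@omegaDist$mean[[b]])
    tT[i] <- rgamma(1L, shape = config@tDist$shape,
                    rate = config@tDist$shape / config@tDist$mean)
    nCod[i] <- max(config@nCodonsDist$min,
                   round(rlnorm(1L, config@nCodonsDist$meanlog,
                                config@nCodonsDist$sdlog)))
    epsD[i] <- rnorm(1L)
    epsP[i] <- rnorm(1L)
    zFold[i] <- rnorm(1L)
    repE[i, ] <- rnorm(2L * R)
  }

  tau <- apply(tissue, 1L, function(x) sum(1 - x / max(x)) / (nt - 1))

  ## fixed reference scalings (not sample z-scores) keep each gene's value
  ## a function of its own substream only; the tau reference matches the
  ## spread realized under the default 25-tissue concentrations
  zLev <- (level - config@levelDist$mean) / config@levelDist$sd
  zTau <- (tau - 0.82) / 0.07
  zDeg <- (log1p(degT) - log1p(dmu[bias])) / 0.7
  ## expression divergence arises as the absolute value of a centred normal
  ## between-species contrast (a folded normal, as an absolute difference of
  ## two log2 species means is), whose scale is the log-linear covariate
  ## model; `sigma` adds optional extra log-scale dispersion (default 0: the
  ## folded normal supplies the stochasticity, log|Z| having SD ~0.78)
  dm <- config@divergenceModel
  diverg <- exp(dm$intercept + dm$bLevel * zLev + dm$bTau * zTau +
                  dm$bDegree * zDeg + dm$sigma * epsD) *
    abs(zFold) / sqrt(2 / pi)
  infl <- chrom == "X" & bias == "MBG"
  diverg[infl] <- diverg[infl] * config@xMbgInflation
  pm <- config@polymorphismModel
  polym <- exp(pm$intercept + pm$bLevel * zLev + pm$bTau * zTau +
                 pm$bDegree * zDeg + pm$sigma * epsP)

  set.seed(.substreamSeed(master, 0L))
  net <- .interactionNetwork(degT, ids)

  gt <- data.frame(gene_id = ids, chrom = chrom, bias_class = bias,
                   level = level, tau = tau, degree = net$degree,
                   expression_divergence = diverg,
                   expression_polymorphism = polym,
                   stringsAsFactors = FALSE)

  ## replicate-level measurements: species means level +/- divergence/2,
  ## replicate noise centred and rescaled so the pooled within-species SD
  ## equals the generative polymorphism exactly
  shape <- function(e, s) {
    e <- e - mean(e)
    sde <- sd(e)
    if (R < 2L || !is.finite(sde) || sde == 0) return(rep(0, length(e)))
    e / sde * s
  }
  m1 <- level + diverg / 2
  m2 <- level - diverg / 2
  sig <- matrix(0, n, 2L * R)
  for (i in seq_len(n)) {
    sig[i, seq_len(R)] <- m1[i] + shape(repE[i, seq_len(R)], polym[i])
    sig[i, R + seq_len(R)] <- m2[i] + shape(repE[i, R + seq_len(R)], polym[i])
  }
  meas <- data.frame(
    gene_id = rep(ids, times = 2L * R),
    species = rep(rep(c("species1", "species2"), each = R), each = n),
    replicate = rep(rep(paste0("strain", seq_len(R)), 2L), each = n),
    log2_signal = c(sig),
    stringsAsFactors = FALSE)
  meas <- meas[order(match(meas$gene_id, ids), meas$species, meas$replicate), ]
  rownames(meas) <- NULL

  pairs <- list()
  if (config@makeSequences) {
    gt$omega_true <- omegaT
    gt$t_true <- tT
    gt$n_codons <- nCod
    pairs <- lapply(seq_len(n), function(i)
      simulateCodonPair(omega = omegaT[i], kappa = config@kappa, t = tT[i],
                        nCodons = nCod[i],
                        seed = .substreamSeed(master, n + i),
                        geneId = ids[i]))
    names(pairs) <- ids
  }

  new("SyntheticDataset", geneTable = gt, expressionMeasurements = meas,
      tissueMatrix = tissue, interactionEdges = net$edges,
      codonPairs = pairs, config = config, seedUsed = master)
}

#' Write a synthetic dataset to disk
#'
#' Writes `gene_table.tsv`, `expression.tsv`, `tissue_matrix.tsv`,
#' `interactions.tsv` and, when codon pairs are present, `species1.fa` /
#' `species2.fa` with identical ID sets.  All TSVs are tab-delimited with a
#' single header row.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wtsv(geneTable(dataset), "gene_table.tsv")
  wtsv(expressionMeasurements(dataset), "expression.tsv")
  tm <- data.frame(gene_id = rownames(tissueMatrix(dataset)),
                   tissueMatrix(dataset), check.names = FALSE,
                   stringsAsFactors = FALSE)
  wtsv(tm, "tissue_matrix.tsv")
  wtsv(interactionEdges(dataset), "interactions.tsv")
  files <- c("gene_table.tsv", "expression.tsv", "tissue_matrix.tsv",
             "interactions.tsv")
  cp <- codonPairs(dataset)
  if (length(cp)) {
    a <- Biostrings::DNAStringSet(vapply(cp, function(p) p@seqA, ""))
    b <- Biostrings::DNAStringSet(vapply(cp, function(p) p@seqB, ""))
    names(a) <- names(b) <- names(cp)
    Biostrings::writeXStringSet(a, file.path(dir, "species1.fa"))
    Biostrings::writeXStringSet(b, file.path(dir, "species2.fa"))
    files <- c(files, "species1.fa", "species2.fa")
  }
  invisible(file.path(dir, files))
}
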