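# End-to-end orchestration: input parsing (the only filesystem-facing
# module), the full analysis (expression summaries -> divergence QC /
# estimation / filters -> the statistical battery), and report writing.

#' Read a flat key = value analysis configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric.  Keys are documented in [runAnalysis()].
#'
#' @param path file path.
#' @return named list.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) .stopf("malformed config line: %s", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

.readTsvChecked <- function(path, what, requiredCols = NULL, idCol = "gene_id") {
  if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    .stopf("malformed row in %s (%s): line %d has %d fields, expected %d",
           what, path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L])
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  if (!is.null(requiredCols) && !all(requiredCols %in% names(d)))
    .stopf("%s (%s) must contain columns: %s", what, path,
           paste(setdiff(requiredCols, names(d)), collapse = ", "))
  if (!is.null(idCol) && idCol %in% names(d) && what != "expression" &&
      anyDuplicated(d[[idCol]])) {
    dup <- which(duplicated(d[[idCol]]))[1L]
    .stopf("duplicate gene ID '%s' in %s (%s), line %d",
           d[[idCol]][dup], what, path, dup + 1L)
  }
  d
}

#' Read and reconcile the analysis inputs
#'
#' Real-data mode: reads the annotation table (`gene_id`, `chrom`,
#' optionally `bias_class`), replicate-level expression TSV, gene-by-tissue
#' TSV, interaction edge list, and two codon-aligned FASTA files matched by
#' exact ID.  Genes missing from any required input are recorded with
#' disposition `excluded:missing_<input>`, never silently dropped; a FASTA
#' ID present in only one species is likewise recorded, not fatal.
#' Duplicate gene IDs within a file are an error naming the line.
#'
#' @param config named list with paths `annotation`, `expression`,
#'   `tissue`, `interactions`, `fasta_a`, `fasta_b` (any but `annotation`
#'   optional).
#' @return list: `annotation`, `measurements`, `tissueMatrix`, `edges`,
#'   `codonPairs` (named list of [CodonPair-class]), `missing` (data.frame
#'   `gene_id`, `reason`).
#' @export
readInputs <- function(config) {
  ann <- .readTsvChecked(config$annotation, "annotation",
                         c("gene_id", "chrom"))
  ids <- ann$gene_id
  missing <- data.frame(gene_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note <- function(gene, why)
    missing <<- rbind(missing, data.frame(gene_id = gene, reason = why,
                                          stringsAsFactors = FALSE))
  meas <- NULL
  if (!is.null(config$expression)) {
    meas <- .readTsvChecked(config$expression, "expression",
                            c("gene_id", "species", "replicate",
                              "log2_signal"), idCol = NULL)
    lost <- setdiff(ids, unique(meas$gene_id))
    if (length(lost)) note(lost, "missing_expression")
  }
  tiss <- NULL
  if (!is.null(config$tissue)) {
    td <- .readTsvChecked(config$tissue, "tissue matrix", "gene_id")
    tiss <- as.matrix(td[, setdiff(names(td), "gene_id"), drop = FALSE])
    rownames(tiss) <- td$gene_id
    lost <- setdiff(ids, td$gene_id)
    if (length(lost)) note(lost, "missing_tissue")
  }
  edges <- NULL
  if (!is.null(config$interactions))
    edges <- .readTsvChecked(config$interactions, "interactions",
                             c("from", "to"), idCol = NULL)
  pairs <- list()
  if (!is.null(config$fasta_a) && !is.null(config$fasta_b)) {
    fa <- Biostrings::readDNAStringSet(config$fasta_a)
    fb <- Biostrings::readDNAStringSet(config$fasta_b)
    if (anyDuplicated(names(fa)))
      .stopf("duplicate gene ID in %s", config$fasta_a)
    if (anyDuplicated(names(fb)))
      .stopf("duplicate gene ID in %s", config$fasta_b)
    shared <- intersect(names(fa), names(fb))
    only <- setdiff(union(names(fa), names(fb)), shared)
    if (length(only)) note(intersect(only, ids), "missing_ortholog")
    lost <- setdiff(ids, union(names(fa), names(fb)))
    if (length(lost)) note(lost, "missing_sequence")
    pairs <- lapply(shared, function(g)
      codonPair(g, as.character(fa[[g]]), as.character(fb[[g]])))
    names(pairs) <- shared
  }
  list(annotation = ann, measurements = meas, tissueMatrix = tiss,
       edges = edges, codonPairs = pairs, missing = missing)
}

## Statistical battery over a master table; returns the report tables.
.runStatsBattery <- function(master, nBins, sided = "two") {
  covNames <- c(Lev = "level", Spe = "tau", Int = "degree")
  responses <- c("expression_divergence", "expression_polymorphism",
                 "dN", "dS", "omega")
  responses <- intersect(responses, names(master))
  classes <- list(MBG = quote(bias_class == "MBG"),
                  NBG = quote(bias_class == "NBG"),
                  All = TRUE)
  covOK <- all(unname(covNames) %in% names(master))
  complete <- if (covOK)
    master[master$disposition == "analyzed" &
             complete.cases(master[, unname(covNames)]), ]
  else master[master$disposition == "analyzed", ]
  tests <- list()
  regs <- list()
  cors <- list()
  strat <- list()
  addTest <- function(label, cls, response, t)
    tests[[length(tests) + 1L]] <<- data.frame(
      analysis = label, gene_class = cls, response = response,
      statistic = names(t$statistic), value = unname(t$statistic),
      p_value = t$p.value, n = sum(t$n), sided = t$sided, note = t$note,
      stringsAsFactors = FALSE)

  for (resp in responses) {
    for (cl in names(classes)) {
      sel <- if (cl == "All") rep(TRUE, nrow(complete))
             else complete$bias_class == cl
      d <- complete[sel & !is.na(complete[[resp]]), ]
      if (nrow(d) < 10L || length(unique(d$chrom)) < 2L) next
      ## X vs A location contrast
      t1 <- mannWhitneyU(d[[resp]][d$chrom == "X"],
                         d[[resp]][d$chrom == "A"], sided = sided)
      addTest("xa_contrast", cl, resp, t1)
      if (!covOK) next   # property-adjusted analyses need all covariates
      ## Spearman correlations with the three properties
      for (cv in names(covNames))
        cors[[length(cors) + 1L]] <- local({
          ct <- spearmanRho(d[[resp]], d[[covNames[[cv]]]])
          data.frame(response = resp, gene_class = cl, property = cv,
                     rho = unname(ct$statistic), p_value = ct$p.value,
                     n = unname(ct$n), stringsAsFactors = FALSE)
        })
      ## standardized regression + residual X-vs-A contrast
      fit <- tryCatch(
        fitStandardizedOls(d[[resp]],
                           list(Lev = d$level, Spe = d$tau, Int = d$degree)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        regs[[length(regs) + 1L]] <- data.frame(
          response = resp, gene_class = cl, R = fit$R, R_P = fit$RP,
          b_Lev = fit$bstar[["Lev"]], b_Lev_P = fit$bstarP[["Lev"]],
          b_Spe = fit$bstar[["Spe"]], b_Spe_P = fit$bstarP[["Spe"]],
          b_Int = fit$bstar[["Int"]], b_Int_P = fit$bstarP[["Int"]],
          n = fit$n, stringsAsFactors = FALSE)
        rt <- tryCatch(residualGroupTest(fit, d$chrom, sided = sided),
                       error = function(e) NULL)
        if (!is.null(rt)) addTest("residual_contrast", cl, resp, rt)
      }
      ## 3D stratified matched comparison (distribution-free adjustment)
      if (cl %in% c("MBG", "All")) {
        sc <- tryCatch(
          stratifiedXAComparison(d[[resp]], d$level, d$tau, d$degree,
                                 d$chrom, nBins = nBins, ids = d$gene_id,
                                 sided = sided),
          error = function(e) NULL)
        if (!is.null(sc)) {
          strat[[paste(resp, cl, sep = ".")]] <- sc
          addTest("stratified_xa", cl, resp, sc$test)
        }
      }
    }
  }
  list(tests = do.call(rbind, tests) %||% data.frame(),
       regressions = do.call(rbind, regs) %||% data.frame(),
       correlations = do.call(rbind, cors) %||% data.frame(),
       stratified = strat)
}

#' Run the full faster-X analysis
#'
#' Orchestrates expression summaries, divergence QC/estimation/filtering
#' and the statistical battery.  `config` is a named list holding either a
#' [SimulationConfig-class] under `simulation`, or real-data paths
#' (`annotation`, `expression`, `tissue`, `interactions`, `fasta_a`,
#' `fasta_b`) -- never both.  Optional keys: `method` ("ng86", "ml",
#' "both"; default "ng86"), `omega_cap` (default 9), `n_bins` (default 10),
#' `sided` (default "two"), `seed`.
#'
#' The master table records every input gene exactly once with disposition
#' `analyzed` or `excluded:<reason>`, distinguishing the all-sequenced gene
#' set from the property-complete subset used by property-adjusted
#' analyses.
#'
#' @param config named list, see above.
#' @return A [FasterXReport-class].
#' @export
runAnalysis <- function(config) {
  isSim <- !is.null(config$simulation)
  paths <- c("annotation", "expression", "tissue", "interactions",
             "fasta_a", "fasta_b")
  if (isSim && any(paths %in% names(config)))
    .stopf("config must hold either a simulation config or data paths, not both")
  if (!isSim && is.null(config$annotation))
    .stopf("real-data mode requires an annotation path")
  method <- config$method %||% "ng86"
  omegaCap <- config$omega_cap %||% 9
  nBins <- as.integer(config$n_bins %||% 10)
  sided <- config$sided %||% "two"

  if (isSim) {
    simcfg <- config$simulation
    if (!is.null(config$seed)) simcfg@seed <- as.integer(config$seed)
    ds <- generateDataset(simcfg)
    ann <- geneTable(ds)[, c("gene_id", "chrom", "bias_class")]
    meas <- expressionMeasurements(ds)
    tiss <- tissueMatrix(ds)
    edges <- interactionEdges(ds)
    pairs <- codonPairs(ds)
    missing <- data.frame(gene_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  } else {
    inp <- readInputs(config)
    ann <- inp$annotation
    meas <- inp$measurements
    tiss <- inp$tissueMatrix
    edges <- inp$edges
    pairs <- inp$codonPairs
    missing <- inp$missing
  }

  ids <- ann$gene_id
  ## only identity columns seed the master table; covariates are rebuilt
  ## from the expression/tissue/network inputs so schemas cannot collide
  master <- ann[, intersect(c("gene_id", "chrom", "bias_class"), names(ann)),
                drop = FALSE]
  if (!"bias_class" %in% names(master)) master$bias_class <- NA_character_

  if (!is.null(meas)) {
    bias <- setNames(master$bias_class, master$gene_id)
    es <- expressionSummaryTable(meas, tiss, bias)
    master <- merge(master, es[, c("gene_id", "level", "divergence",
                                   "polymorphism", "tau")],
                    by = "gene_id", all.x = TRUE, sort = FALSE)
    names(master)[names(master) == "divergence"] <- "expression_divergence"
    names(master)[names(master) == "polymorphism"] <-
      "expression_polymorphism"
  }
  if (!is.null(edges)) {
    inc <- table(factor(c(edges$from, edges$to), levels = ids))
    master$degree <- as.integer(inc[master$gene_id])
  }

  ## divergence estimation + ordered exclusion taxonomy
  filt <- NULL
  if (length(pairs)) {
    est <- estimateDivergence(pairs[intersect(names(pairs), ids)],
                              method = method)
    filt <- applyDivergenceFilters(est$estimates, est$qc,
                                   omegaCap = omegaCap)
    keepMethod <- if (method == "both") "ML_M0" else unique(est$estimates$method)[1L]
    e1 <- est$estimates[est$estimates$method == keepMethod, ]
    master <- merge(master,
                    e1[, c("gene_id", "dN", "dS", "omega", "kappa", "t",
                           "logL", "n_codons_used", "n_syn_diffs")],
                    by = "gene_id", all.x = TRUE, sort = FALSE)
  }
  master <- master[match(ids, master$gene_id), ]
  rownames(master) <- NULL

  disposition <- rep("analyzed", nrow(master))
  if (nrow(missing)) {
    hit <- match(master$gene_id, missing$gene_id)
    disposition[!is.na(hit)] <-
      paste0("excluded:", missing$reason[hit[!is.na(hit)]])
  }
  if (length(pairs)) {
    noseq <- disposition == "analyzed" & !(master$gene_id %in% names(pairs))
    disposition[noseq] <- "excluded:missing_sequence"
    if (!is.null(filt)) {
      hit <- match(master$gene_id, filt$excluded$gene_id)
      sel <- !is.na(hit) & disposition == "analyzed"
      disposition[sel] <- paste0("excluded:", filt$excluded$reason[hit[sel]])
    }
  }
  master$disposition <- disposition
  propCols <- intersect(c("level", "tau", "degree"), names(master))
  master$property_complete <- length(propCols) == 3L &
    master$disposition == "analyzed" &
    complete.cases(master[, propCols, drop = FALSE])

  bat <- .runStatsBattery(master, nBins = nBins, sided = sided)

  meta <- list(mode = if (isSim) "simulation" else "real",
               method = method, omega_cap = omegaCap, n_bins = nBins,
               sided = sided,
               seed = if (isSim) simcfg@seed else config$seed %||% NA,
               n_genes = nrow(master),
               n_analyzed = sum(master$disposition == "analyzed"),
               n_property_complete = sum(master$property_complete),
               package_version = as.character(utils::packageVersion("fasterX")))

  new("FasterXReport", master = master, tests = bat$tests,
      regressions = bat$regressions, correlations = bat$correlations,
      stratified = bat$stratified, meta = meta)
}

.fmtP <- function(p) ifelse(is.na(p), "NA",
                            ifelse(p < 1e-4, sprintf("%.3e", p),
                                   sprintf("%.6g", p)))

#' Write a report bundle to disk
#'
#' Writes tab-delimited tables (`master.tsv`, `tests.tsv`,
#' `regressions.tsv`, `correlations.tsv`, `stratified.tsv`), a JSON
#' metadata file, and `manifest.tsv` listing every file with its MD5
#' checksum.  P-value columns use scientific notation below 1e-4.  Refuses
#' to overwrite existing report files unless `force = TRUE`.  Empty tables
#' are written with a header row only.
#'
#' @param bundle a [FasterXReport-class].
#' @param outdir output directory.
#' @param force overwrite existing files.
#' @return Invisibly, the manifest data.frame.
#' @export
writeReport <- function(bundle, outdir, force = FALSE) {
  stopifnot(is(bundle, "FasterXReport"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L) .stopf("outdir not writable: %s", outdir)
  files <- c("master.tsv", "tests.tsv", "regressions.tsv",
             "correlations.tsv", "stratified.tsv", "run_metadata.json")
  exists <- file.exists(file.path(outdir, files))
  if (any(exists) && !force)
    .stopf("report files already exist in %s (use force = TRUE): %s",
           outdir, paste(files[exists], collapse = ", "))
  fmt <- function(d) {
    for (cl in grep("^p_value$|_P$|^R_P$", names(d), value = TRUE))
      d[[cl]] <- .fmtP(d[[cl]])
    d
  }
  wtsv <- function(d, f) write.table(fmt(d), file.path(outdir, f),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  wtsv(bundle@master, "master.tsv")
  wtsv(bundle@tests %||% data.frame(), "tests.tsv")
  wtsv(bundle@regressions, "regressions.tsv")
  wtsv(bundle@correlations, "correlations.tsv")
  sdf <- if (length(bundle@stratified)) {
    do.call(rbind, lapply(names(bundle@stratified), function(nm) {
      s <- bundle@stratified[[nm]]
      cbind(comparison = nm, s$categories, stringsAsFactors = FALSE)
    }))
  } else data.frame(comparison = character(0), category = character(0),
                    nX = integer(0), nA = integer(0), meanX = numeric(0),
                    meanA = numeric(0), difference = numeric(0))
  wtsv(sdf, "stratified.tsv")
  jsonlite::write_json(bundle@meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- file.path(outdir, files)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
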