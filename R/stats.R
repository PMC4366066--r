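# The statistical battery: Mann-Whitney U, Spearman rank correlation,
# Wilcoxon signed-rank, standardized multiple regression with residual
# contrasts, and the 3-dimensional decile-stratified matched X-vs-autosome
# comparison.  P-values for the rank tests delegate to stats::wilcox.test /
# stats::cor.test; the statistics reported (U from midranks, T as the
# smaller rank sum, rho as midrank product-moment correlation) follow the
# conventions documented per function.

.fxTest <- function(statistic, p, n, sided, method, note = "") {
  structure(list(statistic = statistic, p.value = unname(p), n = n,
                 sided = sided, method = method, note = note),
            class = "fxTest")
}

#' @export
print.fxTest <- function(x, ...) {
  cat(x$method, paste0("(", x$sided, "-sided)"), "\n")
  cat(" ", names(x$statistic), "=", x$statistic,
      "| P =", format(x$p.value, digits = 4),
      "|", paste(names(x$n), x$n, sep = " = ", collapse = ", "), "\n")
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from joint midranks (U for `sampleA`:
#' `rankSumA - nA(nA+1)/2`).  The exact null distribution is used when
#' `min(nA, nB) <= 25` and the pooled data contain no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param sampleA,sampleB nonempty numeric vectors.
#' @param sided "two" (default), or "greater"/"less" for one-sided
#'   alternatives about `sampleA` relative to `sampleB`.
#' @return An `fxTest` result (statistic `U`, `p.value`, sample sizes,
#'   method note stating exact vs approximate).
#' @export
mannWhitneyU <- function(sampleA, sampleB, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  sampleA <- as.numeric(sampleA)
  sampleB <- as.numeric(sampleB)
  if (length(sampleA) == 0L || length(sampleB) == 0L)
    .stopf("both samples must be nonempty")
  n1 <- length(sampleA)
  n2 <- length(sampleB)
  pooled <- c(sampleA, sampleB)
  ties <- anyDuplicated(pooled) > 0L
  exact <- min(n1, n2) <= 25L && !ties
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  wt <- suppressWarnings(
    wilcox.test(sampleA, sampleB, alternative = alt, exact = exact,
                correct = TRUE))
  .fxTest(c(U = unname(U)), wt$p.value, c(nA = n1, nB = n2), sided,
          "Mann-Whitney U test",
          if (exact) "exact" else "normal approximation with tie and continuity correction")
}

#' Spearman rank correlation
#'
#' rho is the product-moment correlation of midranks; the P value uses the
#' t-distribution approximation.  Constant input yields `NA` rho.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param sided as in [mannWhitneyU()].
#' @return An `fxTest` result (statistic `rho`).
#' @export
spearmanRho <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) .stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(.fxTest(c(rho = NA_real_), NA_real_, c(n = length(x)), sided,
                   "Spearman rank correlation", "constant input"))
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE,
                                  alternative = alt))
  .fxTest(c(rho = unname(ct$estimate)), ct$p.value, c(n = length(x)), sided,
          "Spearman rank correlation", "t approximation")
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention).  T is the smaller of
#' the positive-rank and negative-rank sums over midranks of the absolute
#' differences.  Exact enumeration is used when the retained n <= 25 and the
#' absolute differences contain no ties; otherwise the normal approximation
#' with tie and continuity correction.  All-zero differences return an
#' `NA` result with an explanatory note.
#'
#' @param differences numeric vector of paired differences.
#' @param sided "two", or "greater"/"less" about the location of the
#'   differences.
#' @return An `fxTest` result (statistic `T`, `nPairs` = retained nonzero
#'   pairs).
#' @export
wilcoxonSignedRank <- function(differences, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  d <- as.numeric(differences)
  d <- d[!is.na(d)]
  if (length(d) == 0L) .stopf("need at least one difference")
  d <- d[d != 0]
  if (length(d) == 0L)
    return(.fxTest(c(T = NA_real_), NA_real_, c(nPairs = 0L), sided,
                   "Wilcoxon signed-rank test",
                   "all differences zero; statistic undefined"))
  n <- length(d)
  r <- rank(abs(d))
  vPlus <- sum(r[d > 0])
  Tstat <- min(vPlus, n * (n + 1) / 2 - vPlus)
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !ties
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  wt <- suppressWarnings(wilcox.test(d, alternative = alt, exact = exact,
                                     correct = TRUE))
  .fxTest(c(T = unname(Tstat)), wt$p.value, c(nPairs = n), sided,
          "Wilcoxon signed-rank test",
          if (exact) "exact" else "normal approximation with tie and continuity correction")
}

#' Standardized multiple regression (OLS on z-scores)
#'
#' Ordinary least squares with intercept after z-scoring the response and
#' every covariate; the slopes are the standardized coefficients b*, `R` is
#' the multiple correlation, and residuals are returned on the
#' standardized scale.  Per-coefficient P values are the usual t tests
#' (which coincide with partial-correlation tests for OLS); the P for `R`
#' is the overall F test.
#'
#' @param response numeric response.
#' @param covariates named list or data.frame of numeric covariates.
#' @return list of class `standardizedFit`: `bstar`, `bstarP`, `R`, `RP`,
#'   `residuals`, `n`, `covariateNames`.
#' @export
fitStandardizedOls <- function(response, covariates) {
  X <- as.data.frame(covariates)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    .stopf("covariates must be named")
  y <- as.numeric(response)
  if (nrow(X) != length(y)) .stopf("response and covariates lengths differ")
  if (anyNA(y) || anyNA(X))
    .stopf("missing values must be removed before regression")
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) .stopf("need n > number of covariates + 1")
  Z <- scale(as.matrix(X))
  if (any(attr(Z, "scaled:scale") == 0))
    .stopf("constant covariate: %s",
           names(X)[attr(Z, "scaled:scale") == 0][1L])
  cn <- kappa(cbind(1, Z), exact = FALSE)
  if (cn > 1e10) {
    cm <- abs(cor(Z))
    diag(cm) <- 0
    w <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    .stopf("collinear covariates: %s and %s (condition number %.3g)",
           names(X)[w[1L]], names(X)[w[2L]], cn)
  }
  zy <- as.numeric(scale(y))
  if (anyNA(zy)) .stopf("constant response")
  fit <- lm(zy ~ Z)
  sm <- summary(fit)
  co <- sm$coefficients
  bstar <- co[-1L, 1L]
  names(bstar) <- names(X)
  bstarP <- co[-1L, 4L]
  names(bstarP) <- names(X)
  R <- sqrt(max(0, sm$r.squared))
  f <- sm$fstatistic
  RP <- if (!is.null(f)) unname(pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
        else NA_real_
  structure(list(bstar = bstar, bstarP = bstarP, R = R, RP = RP,
                 residuals = unname(resid(fit)), n = n,
                 covariateNames = names(X)),
            class = "standardizedFit")
}

#' @export
print.standardizedFit <- function(x, ...) {
  cat("Standardized OLS fit: n =", x$n, "| R =", round(x$R, 3),
      "( P =", format(x$RP, digits = 3), ")\n")
  print(data.frame(bstar = round(x$bstar, 4),
                   P = signif(x$bstarP, 3)))
  invisible(x)
}

#' Mann-Whitney test on regression residuals split by group
#'
#' Equivalent to calling [mannWhitneyU()] on the residual vectors of the
#' two groups; used to contrast X-linked against autosomal genes after
#' removing the covariate structure.
#'
#' @param fit a `standardizedFit` from [fitStandardizedOls()].
#' @param groupLabels vector of `"X"`/`"A"` aligned with the fit's
#'   observations.
#' @param sided as in [mannWhitneyU()] (alternative about the X group).
#' @return An `fxTest` result.
#' @export
residualGroupTest <- function(fit, groupLabels,
                              sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(inherits(fit, "standardizedFit"))
  if (length(groupLabels) != length(fit$residuals))
    .stopf("groupLabels must align with fit residuals")
  gx <- fit$residuals[groupLabels == "X"]
  ga <- fit$residuals[groupLabels == "A"]
  if (length(gx) == 0L || length(ga) == 0L)
    .stopf("both groups must be nonempty")
  mannWhitneyU(gx, ga, sided = sided)
}

#' Equal-size rank bins
#'
#' Cuts a covariate into `nBins` equal-size bins by rank, with stable
#' tie-breaking by `ids` (then input order); remainder genes go to the
#' lower bins.  Bins depend only on ranks, so any strictly monotone
#' transform of the covariate yields identical bins.
#'
#' @param x numeric covariate.
#' @param nBins number of bins (>= 2).
#' @param ids optional tie-break keys.
#' @return integer bin index per observation, in `1:nBins`.
#' @export
quantileBins <- function(x, nBins = 10L, ids = NULL) {
  n <- length(x)
  if (nBins < 2L) .stopf("nBins must be >= 2")
  if (n < nBins) .stopf("fewer observations (%d) than bins (%d)", n, nBins)
  ord <- if (is.null(ids)) order(x) else order(x, ids)
  sizes <- rep(n %/% nBins, nBins)
  remainder <- n %% nBins
  if (remainder > 0) sizes[seq_len(remainder)] <- sizes[seq_len(remainder)] + 1L
  bin <- integer(n)
  bin[ord] <- rep.int(seq_len(nBins), sizes)
  bin
}

#' Decile-stratified matched X-vs-autosome comparison
#'
#' Expression level, tissue specificity and interaction degree are each cut
#' into `nBins` equal-size rank bins over the supplied gene set
#' ([quantileBins()]); each gene is assigned its combined 3-dimensional
#' category.  For every category containing at least one X-linked and one
#' autosomal gene, the mean response is computed for each class, and the
#' per-category differences (X mean - A mean) are tested with the Wilcoxon
#' signed-rank test ([wilcoxonSignedRank()]).  Categories lacking either
#' class contribute no pair.
#'
#' @param response per-gene numeric response (e.g. expression divergence or
#'   dN).
#' @param level,tau,degree per-gene covariates; all must be defined.
#' @param chrom per-gene `"X"`/`"A"` labels.
#' @param nBins bins per covariate (default 10 deciles).
#' @param ids optional gene IDs for stable tie-breaking.
#' @param sided passed to [wilcoxonSignedRank()].
#' @return list of class `stratifiedComparison`: `categories` (data.frame
#'   with category index, per-class n and means, difference), `nCategories`
#'   (retained), `bins` (n x 3 integer matrix), `test` (`fxTest`).
#' @export
stratifiedXAComparison <- function(response, level, tau, degree, chrom,
                                   nBins = 10L, ids = NULL,
                                   sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  n <- length(response)
  if (!all(lengths(list(level, tau, degree, chrom)) == n))
    .stopf("response, covariates and chrom must have equal length")
  if (anyNA(response) || anyNA(level) || anyNA(tau) || anyNA(degree))
    .stopf("all covariates must be defined for every gene supplied")
  if (!all(chrom %in% c("X", "A"))) .stopf("chrom labels must be 'X' or 'A'")
  b1 <- quantileBins(level, nBins, ids)
  b2 <- quantileBins(tau, nBins, ids)
  b3 <- quantileBins(degree, nBins, ids)
  cat3 <- paste(b1, b2, b3, sep = ".")
  isX <- chrom == "X"
  mx <- tapply(response[isX], cat3[isX], mean)
  ma <- tapply(response[!isX], cat3[!isX], mean)
  nx <- tapply(response[isX], cat3[isX], length)
  na <- tapply(response[!isX], cat3[!isX], length)
  common <- sort(intersect(names(mx), names(ma)))
  if (length(common) < 2L)
    .stopf("insufficient overlap: %d categories contain both X and A genes",
           length(common))
  categories <- data.frame(category = common,
                           nX = as.integer(nx[common]),
                           nA = as.integer(na[common]),
                           meanX = unname(mx[common]),
                           meanA = unname(ma[common]),
                           stringsAsFactors = FALSE)
  categories$difference <- categories$meanX - categories$meanA
  test <- wilcoxonSignedRank(categories$difference, sided = sided)
  structure(list(categories = categories, nCategories = nrow(categories),
                 bins = cbind(level = b1, tau = b2, degree = b3),
                 nBins = nBins, test = test),
            class = "stratifiedComparison")
}

#' @export
print.stratifiedComparison <- function(x, ...) {
  cat("Stratified X-vs-A comparison:", x$nCategories,
      "combined categories with both classes",
      paste0("(", x$nBins, " bins/covariate)"), "\n")
  cat("  mean difference (X - A):",
      format(mean(x$categories$difference), digits = 4), "\n")
  print(x$test)
  invisible(x)
}
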