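#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm rgamma rnbinom rlnorm rexp runif sd var cor
#'   wilcox.test cor.test lm pf coef resid quantile aggregate complete.cases
#'   setNames pnorm
#' @importFrom utils read.delim write.table head modifyList
NULL

## Derive a 32-bit substream seed for gene i from the master seed.  Genes own
## disjoint substreams so that enlarging a dataset leaves existing genes'
## draws untouched.
.substreamSeed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                as.numeric(i) * 2654435761) %% 2147483647)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's .Random.seed is restored afterwards.  seed = NULL runs as-is.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Split a nucleotide string into codon triplets (uppercase).
splitCodons <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (n == 0L) return(character(0))
  substring(x, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

.isStopCodon <- function(codons) codons %in% c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
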