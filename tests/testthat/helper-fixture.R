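# A deterministic 10-gene toy set constructed so that each gene-level
# exclusion rule (internal stop, zero synonymous changes, omega >= 9,
# length error) and the site-level depth/quality rule is exercised by
# exactly one gene, with known expected dispositions.

makeFilterFixture <- function() {
  rep30 <- function(cod) rep(cod, 30)
  seqOf <- function(cod) paste(cod, collapse = "")
  pairs <- list()
  add <- function(id, a, b) pairs[[id]] <<- codonPair(id, a, b)

  # g01 clean: 2 synonymous + 2 nonsynonymous changes
  a <- rep30("GGT"); b <- a
  b[1] <- "GGC"; b[2] <- "GGA"; b[3] <- "AGT"; b[4] <- "TGT"
  add("g01", seqOf(a), seqOf(b))

  # g02 internal stop codon in the second species
  b <- rep30("GGT"); b[5] <- "TAA"; b[1] <- "GGC"
  add("g02", seqOf(rep30("GGT")), seqOf(b))

  # g03 nonsynonymous-only differences: zero synonymous changes
  b <- rep30("AAA"); b[1:3] <- "CAA"
  add("g03", seqOf(rep30("AAA")), seqOf(b))

  # g04 identical sequences: zero changes at all, hence zero synonymous
  add("g04", seqOf(rep30("ATG")), seqOf(rep30("ATG")))

  # g05 one synonymous against 22 nonsynonymous changes: omega >= 9
  b <- rep30("GGT"); b[1] <- "GGC"; b[2:23] <- "TGT"
  add("g05", seqOf(rep30("GGT")), seqOf(b))

  # g06 clean pair whose second sequence passed the site filter with some
  # codons masked to N (depth 7 and quality 40 sites fail strictly)
  a <- rep30("GGT"); b <- a; b[1] <- "GGC"; b[2] <- "GGA"; b[3] <- "NNN"
  add("g06", seqOf(a), seqOf(b))

  # g07 terminal stop codon in both sequences: trimmed, kept
  a <- c(rep("GGT", 29), "TGA"); b <- a; b[1] <- "GGC"; b[2] <- "AGT"
  add("g07", seqOf(a), seqOf(b))

  # g08 length not divisible by 3
  add("g08", paste0(seqOf(rep30("GGT")), "GG"),
      paste0(seqOf(rep30("GGT")), "GG"))

  # g09 ambiguous codons excluded pairwise, gene kept
  a <- rep30("CTT"); b <- a; b[1] <- "CTC"; b[2] <- "A-T"; b[3] <- "ATT"
  add("g09", seqOf(a), seqOf(b))

  # g10 another clean gene with both kinds of change
  a <- rep30("ACT"); b <- a; b[1] <- "ACC"; b[2] <- "GCT"
  add("g10", seqOf(a), seqOf(b))

  expected <- c(g01 = "analyzed", g02 = "excluded:internal_stop",
                g03 = "excluded:zero_synonymous_changes",
                g04 = "excluded:zero_synonymous_changes",
                g05 = "excluded:omega_cap", g06 = "analyzed",
                g07 = "analyzed", g08 = "excluded:length_error",
                g09 = "analyzed", g10 = "analyzed")

  # pileup rows for the boundary site-filter cases: depth must exceed 7 and
  # quality must exceed 40, both strictly
  pileup <- data.frame(
    depth = c(8, 7, 200, 100, 6),
    quality = c(41, 100, 40, 45, 39),
    base = c("A", "C", "G", "T", "A"),
    expect_kept = c(TRUE, FALSE, FALSE, TRUE, FALSE))

  list(pairs = pairs, expected = expected, pileup = pileup)
}
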