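## Independent oracles used across the suite. These deliberately avoid the
## package's own scanning/intersection/summation code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN"
)

## IUPAC consensus -> plain character-class regex (degeneracies expanded)
iupac_regex <- function(consensus) {
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    set <- IUPAC_ORACLE[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, ""), collapse = "")
}

## all (possibly overlapping) 1-based match offsets via regex lookahead
regex_offsets <- function(sequence, consensus) {
  m <- gregexpr(paste0("(?=", iupac_regex(consensus), ")"),
                toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## brute-force both-strand IUPAC scan: (start, strand) pairs in input frame
regex_scan_oracle <- function(sequence, consensus) {
  L <- nchar(consensus)
  n <- nchar(sequence)
  rc <- paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan",
                                  sequence), "")[[1]]), collapse = "")
  fwd <- regex_offsets(sequence, consensus)
  revo <- regex_offsets(rc, consensus)
  rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+"),
    if (length(revo)) data.frame(start = n - (revo + L - 1L) + 1L,
                                 strand = "-")
  )
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## O(n^2) interval intersection oracle on GRanges (>=1 bp shared)
brute_overlap_oracle <- function(a, b) {
  out <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] == as.character(seqnames(b))[j] &&
        start(a)[i] <= end(b)[j] && start(b)[j] <= end(a)[i])
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(query = m[, 1], subject = m[, 2])
  df[order(df$query, df$subject), , drop = FALSE]
}

## brute-force pseudobulk summation oracle
brute_pseudobulk_oracle <- function(m, groups) {
  lv <- levels(factor(groups))
  out <- matrix(0, nrow(m), length(lv), dimnames = list(rownames(m), lv))
  for (p in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[p, as.character(groups[j])] <-
      out[p, as.character(groups[j])] + m[p, j]
  out
}

## brute-force median-of-ratios oracle (geomean-1 rescaled)
brute_mor_oracle <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  m <- m[keep, , drop = FALSE]
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  f <- numeric(ncol(m))
  for (g in seq_len(ncol(m))) f[g] <- median(m[, g] / geo)
  f / prod(f)^(1 / length(f))
}

## small simulation shared by several tests
tiny_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, nCellsPerSubset = 60L, nPromoterPeaks = 15L,
                   nCtcfPeaks = 8L, nDrePeaks = 30L, nCoaccessPairs = 3L,
                   nSnps = 10L, meanDepthPerCell = 1500)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}
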