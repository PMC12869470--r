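#' @include motifs.R io.R
NULL

.default_immune_keywords <- c(
  "immune", "lymphocyte", "monocyte", "neutrophil", "eosinophil",
  "basophil", "leukocyte", "white blood cell", "nk cell", "natural killer",
  "autoimmune", "lupus", "arthritis", "allerg", "asthma", "inflammat",
  "infection", "cd56", "thyroid disease", "surface marker")

.default_psych_keywords <- c(
  "depress", "anxiety", "schizophren", "addict", "bipolar", "psych",
  "neurotic", "autism", "adhd", "alcohol dependence", "cognitive")

#' Assign SNP traits to immune / psychological / other categories
#'
#' Case-insensitive substring matching against keyword lists; immune takes
#' precedence when a trait matches both lists; traits matching neither are
#' `other`.
#'
#' @param snps SNP `data.frame` with a `trait` column.
#' @param immuneKeywords,psychKeywords non-empty keyword vectors
#'   (defaults shipped with the package, fully overridable).
#' @return the input with a `category` column appended.
#' @export
categorizeTraits <- function(snps,
                             immuneKeywords = .default_immune_keywords,
                             psychKeywords = .default_psych_keywords) {
  if (!length(immuneKeywords) || !length(psychKeywords))
    stop("keyword lists must be non-empty")
  tr <- tolower(snps$trait)
  matchAny <- function(kw) {
    hit <- rep(FALSE, length(tr))
    for (k in tolower(kw)) hit <- hit | grepl(k, tr, fixed = TRUE)
    hit
  }
  imm <- matchAny(immuneKeywords)
  psy <- matchAny(psychKeywords)
  snps$category <- ifelse(imm, "immune",
                          ifelse(psy, "psychological", "other"))
  snps
}

#' Map SNPs to their containing peak
#'
#' A SNP at 1-based position p lies in a peak iff the peak range contains
#' p. When several peaks contain it, the smallest peak wins; ties go to
#' the leftmost.
#'
#' @param snps SNP `data.frame` (chrom, pos, rsid, ...).
#' @param peaks `GRanges` with an `id` mcol.
#' @return named character vector: peak id (or `NA`) per rsid.
#' @export
snpsInPeaks <- function(snps, peaks) {
  stopifnot(is(peaks, "GRanges"), !is.null(peaks$id))
  gr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L))
  ov <- findOverlaps(gr, peaks)
  out <- setNames(rep(NA_character_, nrow(snps)), snps$rsid)
  if (length(ov)) {
    df <- data.frame(q = queryHits(ov), s = subjectHits(ov))
    df$w <- width(peaks)[df$s]
    df$st <- start(peaks)[df$s]
    df <- df[order(df$q, df$w, df$st, df$s), ]
    df <- df[!duplicated(df$q), ]
    out[df$q] <- peaks$id[df$s]
  }
  out
}

#' Allele-specific motif creation and disruption at a SNP
#'
#' Extracts `windowBp` of sequence on each side of the SNP, substitutes
#' the alternate allele, scans both haplotypes with every motif on both
#' strands, and compares the number of hits whose footprint covers the SNP
#' position: more covering hits on the alternate allele means the motif is
#' \emph{gained}, fewer means \emph{lost}. Hits near the SNP that do not
#' cover it (e.g. an adjacent intact STAT3 site next to a created BLIMP1
#' site) are reported separately as context and never drive a
#' gained/lost call. The reference base at the SNP position is checked
#' against the genome; a mismatch signals a coordinate or genome-build
#' inconsistency and is an error naming the rsid.
#'
#' @param snp one-row SNP `data.frame` (chrom, pos, rsid, ref, alt) or a
#'   list with those fields.
#' @param genome `DNAStringSet` of contigs.
#' @param motifs list of [Motif-class] objects (default [defaultMotifs()]).
#' @param windowBp half-width of the extracted window; must be at least
#'   the longest motif length.
#' @return `data.frame`, one row per motif: `rsid`, `motif_id`, `status`
#'   (gained / lost / unchanged), `ref_hits`, `alt_hits`,
#'   `ref_context_hits`, `alt_context_hits`.
#' @export
alleleMotifDelta <- function(snp, genome, motifs = defaultMotifs(),
                             windowBp = 30L) {
  if (is.data.frame(snp)) {
    stopifnot(nrow(snp) == 1L)
    snp <- as.list(snp)
  }
  maxL <- max(vapply(motifs, motifLength, integer(1)))
  if (windowBp < maxL)
    stop("'windowBp' must be >= the longest motif length (", maxL, ")")
  chrom <- snp$chrom
  if (!chrom %in% names(genome)) stop("unknown contig for ", snp$rsid)
  contig <- genome[[chrom]]
  lo <- max(1L, snp$pos - windowBp)
  hi <- min(length(contig), snp$pos + windowBp)
  refWin <- as.character(Biostrings::subseq(contig, lo, hi))
  snpOff <- snp$pos - lo + 1L
  if (substring(refWin, snpOff, snpOff) != toupper(snp$ref))
    stop("reference base mismatch at ", snp$rsid, ": genome has '",
         substring(refWin, snpOff, snpOff), "', table says '", snp$ref, "'")
  altWin <- refWin
  substring(altWin, snpOff, snpOff) <- toupper(snp$alt)

  rows <- lapply(motifs, function(m) {
    hr <- scanMotif(refWin, m)
    ha <- scanMotif(altWin, m)
    covR <- sum(hr$start <= snpOff & hr$end >= snpOff)
    covA <- sum(ha$start <= snpOff & ha$end >= snpOff)
    data.frame(
      rsid = snp$rsid, motif_id = motifId(m),
      status = if (covA > covR) "gained"
               else if (covA < covR) "lost" else "unchanged",
      ref_hits = covR, alt_hits = covA,
      ref_context_hits = nrow(hr) - covR,
      alt_context_hits = nrow(ha) - covA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep the most significant SNP per linkage block
#'
#' GWAS variants inherited together are represented by the single SNP with
#' the smallest association p-value in each block (ties: first in input
#' order). Linkage computation itself is upstream; blocks arrive as a
#' column.
#'
#' @param snps `data.frame` with columns `block` and `p_value`.
#' @return the best row per block, in block order of first appearance.
#' @export
bestSnpPerBlock <- function(snps) {
  if (!all(c("block", "p_value") %in% names(snps)))
    stop("need 'block' and 'p_value' columns")
  keep <- unlist(lapply(split(seq_len(nrow(snps)), snps$block),
                        function(ix) ix[which.min(snps$p_value[ix])]))
  snps[sort(keep), , drop = FALSE]
}
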