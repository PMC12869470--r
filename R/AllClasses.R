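#' @include nkatac-package.R
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

#' DNA sequence motif
#'
#' A motif is either a degenerate IUPAC consensus (every position must match
#' its degeneracy set exactly; an \code{N} in the scanned sequence matches
#' nothing except a motif \code{N}) or a position weight matrix of per-base
#' log2-odds against a background, with a score threshold. Both kinds are
#' scanned on both strands by [scanMotif()].
#'
#' @slot id single identifier string.
#' @slot kind `"iupac"` or `"pwm"`.
#' @slot consensus IUPAC consensus string (iupac kind only).
#' @slot matrix 4 x L numeric matrix of log2-odds, rows A,C,G,T (pwm kind).
#' @slot threshold minimum score for a PWM hit.
#'
#' @seealso [iupacMotif()], [pwmMotif()], [pwmFromConsensus()],
#'   [defaultMotifs()]
#' @export
setClass("Motif",
  representation(
    id = "character",
    kind = "character",
    consensus = "character",
    matrix = "matrix",
    threshold = "numeric"
  ),
  prototype(consensus = NA_character_, matrix = matrix(0, 0, 0),
            threshold = NA_real_)
)

setValidity("Motif", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msgs <- c(msgs, "'id' must be a single non-empty string")
  if (length(object@kind) != 1L || !object@kind %in% c("iupac", "pwm"))
    msgs <- c(msgs, "'kind' must be \"iupac\" or \"pwm\"")
  if (identical(object@kind, "iupac")) {
    cs <- object@consensus
    if (length(cs) != 1L || is.na(cs) || nchar(cs) < 4L)
      msgs <- c(msgs, "iupac consensus must be a single string of length >= 4")
    else {
      bad <- setdiff(strsplit(toupper(cs), "")[[1]], names(IUPAC_SETS))
      if (length(bad))
        msgs <- c(msgs, paste0("invalid IUPAC character(s): ",
                               paste(unique(bad), collapse = ", ")))
    }
  }
  if (identical(object@kind, "pwm")) {
    m <- object@matrix
    if (nrow(m) != 4L || ncol(m) < 4L)
      msgs <- c(msgs, "pwm matrix must be 4 x L with L >= 4")
    else if (!all(is.finite(m)))
      msgs <- c(msgs, "pwm matrix must be finite")
    if (length(object@threshold) != 1L || is.na(object@threshold))
      msgs <- c(msgs, "pwm requires a single finite threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an IUPAC consensus motif
#'
#' @param id motif identifier.
#' @param consensus IUPAC consensus string (lower case accepted; \code{n}
#'   is treated as \code{N}).
#' @return A [Motif-class] of kind `"iupac"`.
#' @examples
#' m4 <- iupacMotif("M4", "ACTAYRNNNCCCR")
#' @export
iupacMotif <- function(id, consensus) {
  new("Motif", id = id, kind = "iupac", consensus = toupper(consensus))
}

#' Construct a PWM motif from a log-odds matrix
#'
#' @param id motif identifier.
#' @param matrix 4 x L numeric matrix of log2-odds, rows in order A, C, G, T.
#' @param threshold minimum summed log-odds for a hit.
#' @return A [Motif-class] of kind `"pwm"`.
#' @export
pwmMotif <- function(id, matrix, threshold) {
  rownames(matrix) <- c("A", "C", "G", "T")
  new("Motif", id = id, kind = "pwm", matrix = matrix, threshold = threshold)
}

#' @describeIn Motif-class motif identifier
#' @param object,x a `Motif`
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @export
setMethod("motifId", "Motif", function(x) x@id)

#' @describeIn Motif-class motif length in bp
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @export
setMethod("motifLength", "Motif", function(x) {
  if (x@kind == "iupac") nchar(x@consensus) else ncol(x@matrix)
})

setMethod("show", "Motif", function(object) {
  if (object@kind == "iupac") {
    cat("Motif ", object@id, " [iupac] ", object@consensus, "\n", sep = "")
  } else {
    cat("Motif ", object@id, " [pwm] L=", ncol(object@matrix),
        " threshold=", signif(object@threshold, 4),
        " (max ", signif(sum(apply(object@matrix, 2, max)), 4), ")\n",
        sep = "")
  }
})

#' Simulated genome with planted regulatory architecture
#'
#' Container for the synthetic contigs and annotations produced by
#' [simulateGenome()]: contig sequences, peaks carrying their true
#' compartment label, TSS positions (one per promoter peak), planted CTCF
#' sites, blacklist regions, and the designated motif-creating SNP locus.
#'
#' @slot genome `DNAStringSet` of synthetic contigs.
#' @slot peaks `GRanges` with mcols `id` and `class`
#'   (promoter / ctcf_distal / dre).
#' @slot tss `GRanges` of width-1 TSS positions with mcol `peak_id`.
#' @slot ctcfSites `GRanges` of planted CTCF motif instances.
#' @slot blacklist `GRanges` of artifact regions.
#' @slot designatedSnp list with `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `peak_id` describing the planted BLIMP1-creating SNP.
#' @export
setClass("SimulatedGenome",
  representation(
    genome = "DNAStringSet",
    peaks = "GRanges",
    tss = "GRanges",
    ctcfSites = "GRanges",
    blacklist = "GRanges",
    designatedSnp = "list"
  )
)

setValidity("SimulatedGenome", function(object) {
  msgs <- character()
  if (is.null(object@peaks$id) || is.null(object@peaks$class))
    msgs <- c(msgs, "peaks must carry 'id' and 'class' mcols")
  else if (!all(object@peaks$class %in% c("promoter", "ctcf_distal", "dre")))
    msgs <- c(msgs, "peak classes must be promoter/ctcf_distal/dre")
  if (!all(as.character(seqnames(object@peaks)) %in% names(object@genome)))
    msgs <- c(msgs, "peak seqnames must name contigs in 'genome'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulatedGenome", function(object) {
  cls <- table(object@peaks$class)
  cat("SimulatedGenome:", length(object@genome), "contig(s),",
      sum(Biostrings::width(object@genome)), "bp total\n")
  cat("  peaks:", length(object@peaks),
      paste0("(", paste(names(cls), cls, sep = "=", collapse = ", "), ")"),
      "\n")
  cat("  tss:", length(object@tss),
      " ctcf sites:", length(object@ctcfSites),
      " blacklist:", length(object@blacklist), "\n")
  cat("  designated SNP:", object@designatedSnp$rsid, "at",
      paste0(object@designatedSnp$chrom, ":", object@designatedSnp$pos),
      paste0(object@designatedSnp$ref, ">", object@designatedSnp$alt), "\n")
})

#' @describeIn SimulatedGenome-class contig sequences
#' @param x a `SimulatedGenome`
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @export
setMethod("genomeSequences", "SimulatedGenome", function(x) x@genome)

#' @describeIn SimulatedGenome-class peak ranges with true class labels
#' @export
setGeneric("simPeaks", function(x) standardGeneric("simPeaks"))
#' @export
setMethod("simPeaks", "SimulatedGenome", function(x) x@peaks)

#' @describeIn SimulatedGenome-class TSS positions
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))
#' @export
setMethod("tssSites", "SimulatedGenome", function(x) x@tss)

#' @describeIn SimulatedGenome-class planted CTCF site intervals
#' @export
setGeneric("ctcfSites", function(x) standardGeneric("ctcfSites"))
#' @export
setMethod("ctcfSites", "SimulatedGenome", function(x) x@ctcfSites)

#' @describeIn SimulatedGenome-class blacklist regions
#' @export
setGeneric("blacklistRegions",
           function(x) standardGeneric("blacklistRegions"))
#' @export
setMethod("blacklistRegions", "SimulatedGenome", function(x) x@blacklist)

#' @describeIn SimulatedGenome-class the designated motif-creating SNP
#' @export
setGeneric("designatedSnp", function(x) standardGeneric("designatedSnp"))
#' @export
setMethod("designatedSnp", "SimulatedGenome", function(x) x@designatedSnp)
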