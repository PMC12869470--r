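#' @include io.R
NULL

#' QC thresholds for snATAC cell filtering
#'
#' All comparisons are strict, matching the published filter wording:
#' cells pass with TSS enrichment > 2, nucleosome signal < 4, blacklist
#' ratio < 0.05 and more than 200 unique fragments.
#'
#' @param minTssEnrichment exclusive lower bound on TSS enrichment.
#' @param maxNucleosomeSignal exclusive upper bound on nucleosome signal.
#' @param maxBlacklistRatio exclusive upper bound on blacklist ratio.
#' @param minUniqueFragments exclusive lower bound on unique fragments.
#' @return list of class `qc_thresholds`.
#' @export
qcThresholds <- function(minTssEnrichment = 2,
                         maxNucleosomeSignal = 4,
                         maxBlacklistRatio = 0.05,
                         minUniqueFragments = 200) {
  th <- list(minTssEnrichment = minTssEnrichment,
             maxNucleosomeSignal = maxNucleosomeSignal,
             maxBlacklistRatio = maxBlacklistRatio,
             minUniqueFragments = minUniqueFragments)
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0")
  class(th) <- "qc_thresholds"
  th
}

#' Per-cell snATAC quality metrics
#'
#' Computes, per barcode after collapsing identical (chrom, start, end,
#' barcode) records to unique fragments:
#' \itemize{
#' \item \strong{n_unique_fragments}: unique fragment count.
#' \item \strong{tss_enrichment}: mean fragment-end (cut-site) coverage per
#'   position over TSS +/- `flankBp`, divided by the mean over the
#'   outermost `edgeBp` flank positions on each side. A flat genome-wide
#'   profile gives 1; zero flank coverage with central signal gives `Inf`;
#'   a cell with no cut sites near any TSS gives 0.
#' \item \strong{nucleosome_signal}: fragments of length 147-294 divided by
#'   fragments shorter than 147; 0 when there are no mono-nucleosomal
#'   fragments, `Inf` when there are mono-nucleosomal but no
#'   sub-nucleosomal fragments (sentinel; fails the filter).
#' \item \strong{blacklist_ratio}: fraction of the cell's unique fragments
#'   overlapping a blacklist interval by >= 1 bp.
#' }
#' Barcodes with zero fragments after collapsing are excluded.
#'
#' @param fragments `GRanges` with mcol `barcode` (as from
#'   [readFragments()] or [simulateFragments()]).
#' @param tss `GRanges` of TSS positions.
#' @param blacklist `GRanges` of artifact regions, or `NULL`.
#' @param flankBp half-width of the TSS window.
#' @param edgeBp width of each outermost flank used as the background.
#' @return `data.frame` with one row per barcode: `barcode`,
#'   `n_unique_fragments`, `tss_enrichment`, `nucleosome_signal`,
#'   `blacklist_ratio`.
#' @export
computeCellQC <- function(fragments, tss, blacklist = NULL,
                          flankBp = 1000L, edgeBp = 100L) {
  stopifnot(is(fragments, "GRanges"), !is.null(fragments$barcode))
  key <- paste(as.character(seqnames(fragments)), start(fragments),
               end(fragments), fragments$barcode)
  uniq <- fragments[!duplicated(key)]
  if (!length(uniq))
    return(data.frame(barcode = character(), n_unique_fragments = integer(),
                      tss_enrichment = numeric(),
                      nucleosome_signal = numeric(),
                      blacklist_ratio = numeric()))
  bc <- factor(uniq$barcode)
  nUniq <- as.integer(table(bc))

  len <- width(uniq)
  sub <- len < 147L
  mono <- len >= 147L & len <= 294L
  nSub <- tapply(sub, bc, sum)
  nMono <- tapply(mono, bc, sum)
  ns <- ifelse(nMono == 0, 0, ifelse(nSub == 0, Inf, nMono / nSub))

  blr <- if (is.null(blacklist) || !length(blacklist)) {
    rep(0, nlevels(bc))
  } else {
    inBl <- overlapsAny(uniq, blacklist)
    as.numeric(tapply(inBl, bc, mean))
  }

  ## cut sites: both fragment ends
  cuts <- GRanges(rep(seqnames(uniq), 2L),
                  IRanges(c(start(uniq), end(uniq)), width = 1L))
  cutBc <- rep(as.integer(bc), 2L)
  win <- suppressWarnings(resize(tss, 2L * flankBp + 1L, fix = "center"))
  ov <- findOverlaps(cuts, win)
  total <- rep(0, nlevels(bc)); flank <- rep(0, nlevels(bc))
  if (length(ov)) {
    rel <- abs(start(cuts)[queryHits(ov)] -
                 start(tss)[subjectHits(ov)])
    b <- cutBc[queryHits(ov)]
    tt <- tapply(rep(1, length(b)), factor(b, levels = seq_len(nlevels(bc))),
                 sum, default = 0)
    total <- as.numeric(tt)
    isFlank <- rel > (flankBp - edgeBp)
    ff <- tapply(as.numeric(isFlank),
                 factor(b, levels = seq_len(nlevels(bc))), sum, default = 0)
    flank <- as.numeric(ff)
  }
  nPos <- 2 * flankBp + 1
  tssE <- ifelse(total == 0, 0,
                 ifelse(flank == 0, Inf,
                        (total / nPos) / (flank / (2 * edgeBp))))

  data.frame(barcode = levels(bc),
             n_unique_fragments = nUniq,
             tss_enrichment = as.numeric(tssE),
             nucleosome_signal = as.numeric(ns),
             blacklist_ratio = blr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff it beats every threshold strictly: TSS enrichment
#' above the minimum, nucleosome signal and blacklist ratio below their
#' maxima, and strictly more unique fragments than the minimum (a cell with
#' exactly 200 unique fragments is removed under the default thresholds).
#' The removal report tallies failures per criterion non-exclusively.
#'
#' @param qc `data.frame` from [computeCellQC()].
#' @param thresholds a [qcThresholds()] object.
#' @return list with `qc` (input plus logical `passed`), `kept` (barcodes),
#'   and `report` (data.frame criterion / n_failed).
#' @export
filterCells <- function(qc, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  failTss <- !(qc$tss_enrichment > thresholds$minTssEnrichment)
  failNs <- !(qc$nucleosome_signal < thresholds$maxNucleosomeSignal)
  failBl <- !(qc$blacklist_ratio < thresholds$maxBlacklistRatio)
  failFr <- !(qc$n_unique_fragments > thresholds$minUniqueFragments)
  passed <- !(failTss | failNs | failBl | failFr)
  qc$passed <- passed
  list(
    qc = qc,
    kept = qc$barcode[passed],
    report = data.frame(
      criterion = c("tss_enrichment", "nucleosome_signal",
                    "blacklist_ratio", "n_unique_fragments"),
      n_failed = c(sum(failTss), sum(failNs), sum(failBl), sum(failFr))
    )
  )
}
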