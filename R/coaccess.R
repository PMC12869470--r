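#' @include AllClasses.R
NULL

#' Binarize a count matrix and pool cells into metacells
#'
#' Cells are partitioned into pools (random under `seed`, or by supplied
#' `labels`); each pooled entry is the fraction of the pool's cells with a
#' nonzero count — a simple sparsity remedy before correlating peaks.
#' With `poolSize = 1` the result is the 0/1 indicator of the input.
#' When the cell count is not a multiple of `poolSize`, the remainder
#' forms one final smaller pool.
#'
#' @param counts peaks-by-cells matrix or `SummarizedExperiment`.
#' @param poolSize cells per metacell (>= 1).
#' @param seed seed for the random partition (required when `poolSize > 1`
#'   and no labels are given).
#' @param labels optional explicit pool label per cell.
#' @return peaks-by-metacells numeric matrix with attribute `"pools"`
#'   (list of cell indices per metacell).
#' @export
binarizeAndPool <- function(counts, poolSize = 10L, seed = NULL,
                            labels = NULL) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  n <- ncol(counts)
  if (poolSize < 1L) stop("'poolSize' must be >= 1")
  if (poolSize > n) stop("'poolSize' exceeds the number of cells")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("'labels' must have one entry per cell")
    pools <- split(seq_len(n), factor(labels, levels = unique(labels)))
  } else if (poolSize == 1L) {
    pools <- as.list(seq_len(n))
  } else {
    if (is.null(seed))
      stop("random pooling needs a 'seed' for a reproducible partition")
    set.seed(seed)
    perm <- sample.int(n)
    pools <- split(perm, ceiling(seq_len(n) / poolSize))
  }
  bin <- (as.matrix(counts) > 0) * 1
  out <- vapply(pools, function(ix) rowMeans(bin[, ix, drop = FALSE]),
                numeric(nrow(counts)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(counts))
  rownames(out) <- rownames(counts)
  colnames(out) <- paste0("mc", seq_along(pools))
  attr(out, "pools") <- unname(pools)
  out
}

#' Distance-constrained co-accessibility scores
#'
#' For every same-chromosome peak pair whose midpoint distance is at most
#' `maxDistBp`, the score is the Pearson correlation of the two pooled
#' binary profiles across metacells. This deliberately replaces
#' graphical-model co-accessibility (cicero-style) with a transparent
#' statistic whose behaviour does not depend on arbitrary algorithm
#' settings; candidate links are meant to be validated orthogonally (loop
#' support, reporter assays). Zero-variance profiles score 0 and are
#' flagged rather than propagating NaN. Pairs are reported with `peak_a`
#' preceding `peak_b` in genome order.
#'
#' @param pooled peaks-by-metacells matrix from [binarizeAndPool()].
#' @param peaks `GRanges` with an `id` mcol, one range per pooled row (any
#'   order; matched by row name when available, else by position).
#' @param maxDistBp maximum midpoint distance.
#' @param cutoff score cutoff; `passes_cutoff` is score strictly greater.
#'   The published figure settings are 0.05 (locus browsing) and 0.25
#'   (stringent linking).
#' @return `data.frame`: `peak_a`, `peak_b`, `score`, `distance_bp`,
#'   `passes_cutoff`, `zero_variance`.
#' @export
coAccessibility <- function(pooled, peaks, maxDistBp = 500000L,
                            cutoff = 0.05) {
  stopifnot(is(peaks, "GRanges"))
  if (is.null(peaks$id)) peaks$id <- rownames(pooled)
  if (nrow(pooled) != length(peaks))
    stop("'pooled' rows and 'peaks' must correspond")
  if (!is.null(rownames(pooled))) {
    m <- match(peaks$id, rownames(pooled))
    if (anyNA(m)) stop("peak ids do not match pooled row names")
    pooled <- pooled[m, , drop = FALSE]
  }
  ord <- order(as.character(seqnames(peaks)), start(peaks), end(peaks))
  peaks <- peaks[ord]
  pooled <- pooled[ord, , drop = FALSE]
  mids <- floor((start(peaks) + end(peaks)) / 2)
  chrom <- as.character(seqnames(peaks))

  res <- list()
  for (chr in unique(chrom)) {
    ix <- which(chrom == chr)
    if (length(ix) < 2L) next
    sub <- pooled[ix, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    cc <- suppressWarnings(cor(t(sub)))
    pairIdx <- which(outer(mids[ix], mids[ix],
                           function(a, b) abs(a - b)) <= maxDistBp &
                       upper.tri(cc), arr.ind = TRUE)
    if (!nrow(pairIdx)) next
    i <- pairIdx[, 1]; j <- pairIdx[, 2]
    zv <- sds[i] == 0 | sds[j] == 0
    score <- cc[pairIdx]
    score[zv | is.na(score)] <- 0
    res[[chr]] <- data.frame(
      peak_a = peaks$id[ix[i]], peak_b = peaks$id[ix[j]],
      score = score,
      distance_bp = abs(mids[ix[j]] - mids[ix[i]]),
      passes_cutoff = score > cutoff,
      zero_variance = zv,
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(peak_a = character(), peak_b = character(),
                      score = numeric(), distance_bp = integer(),
                      passes_cutoff = logical(), zero_variance = logical()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate co-accessibility pairs with compartments and loop support
#'
#' A pair is a DRE-to-promoter link iff one peak is compartment `dre` and
#' the other `promoter`. It is loop supported iff a single loop's two
#' anchors lie within `anchorTolBp` of the two peaks (either orientation);
#' matching the anchors of two different loops does not count.
#'
#' @param pairs `data.frame` from [coAccessibility()].
#' @param classes named compartment per peak id.
#' @param loops `Pairs` of anchor `GRanges` (as from [readBedpe()]), or
#'   `NULL` for no loop evidence.
#' @param peaks `GRanges` with `id` mcols giving peak coordinates.
#' @param anchorTolBp anchor matching tolerance (Hi-C bin scale).
#' @return the input `pairs` with logical columns `dre_to_promoter` and
#'   `loop_supported` appended.
#' @export
annotateLinks <- function(pairs, classes, loops, peaks,
                          anchorTolBp = 10000L) {
  stopifnot(is(peaks, "GRanges"), !is.null(peaks$id))
  ca <- unname(classes[pairs$peak_a])
  cb <- unname(classes[pairs$peak_b])
  pairs$dre_to_promoter <- (ca == "dre" & cb == "promoter") |
    (ca == "promoter" & cb == "dre")
  pairs$loop_supported <- FALSE
  if (!is.null(loops) && length(loops)) {
    pa <- peaks[match(pairs$peak_a, peaks$id)]
    pb <- peaks[match(pairs$peak_b, peaks$id)]
    anchorA <- S4Vectors::first(loops)
    anchorB <- S4Vectors::second(loops)
    hitsA1 <- findOverlaps(pa, anchorA + anchorTolBp)
    hitsB2 <- findOverlaps(pb, anchorB + anchorTolBp)
    hitsA2 <- findOverlaps(pb, anchorA + anchorTolBp)
    hitsB1 <- findOverlaps(pa, anchorB + anchorTolBp)
    keyA1 <- paste(queryHits(hitsA1), subjectHits(hitsA1))
    keyB2 <- paste(queryHits(hitsB2), subjectHits(hitsB2))
    keyB1 <- paste(queryHits(hitsB1), subjectHits(hitsB1))
    keyA2 <- paste(queryHits(hitsA2), subjectHits(hitsA2))
    same <- intersect(keyA1, keyB2)          # a on anchorA, b on anchorB
    swapped <- intersect(keyB1, keyA2)       # a on anchorB, b on anchorA
    supp <- unique(as.integer(vapply(strsplit(c(same, swapped), " "),
                                     `[[`, "", 1L)))
    pairs$loop_supported[supp] <- TRUE
  }
  pairs
}
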