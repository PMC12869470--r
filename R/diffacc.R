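#' @include AllClasses.R
NULL

#' Sum single-cell counts into pseudobulk group columns
#'
#' @param counts peaks-by-cells matrix, or a `SummarizedExperiment` whose
#'   first assay holds the counts.
#' @param groups group label per cell (e.g. subset x donor); every cell
#'   must have one.
#' @return peaks-by-groups matrix of summed counts; total mass is
#'   conserved.
#' @export
pseudobulk <- function(counts, groups) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  if (length(groups) != ncol(counts))
    stop("'groups' must have one label per cell column")
  if (any(is.na(groups) | !nzchar(as.character(groups)))) {
    bad <- colnames(counts)[is.na(groups) | !nzchar(as.character(groups))]
    stop("cells with no group assignment: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  g <- factor(groups)
  out <- vapply(levels(g),
                function(l) rowSums(counts[, g == l, drop = FALSE]),
                numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Median-of-ratios size factors
#'
#' The classical centering normalization: for every peak nonzero in all
#' groups, take its counts divided by its across-group geometric mean;
#' each group's factor is the median of those ratios, rescaled so the
#' factors have geometric mean 1. Valid only under the assumption that
#' most features are unchanged — the assumption whose failure on globally
#' shifted DRE landscapes this package is built to expose.
#'
#' @param table peaks-by-groups count matrix (e.g. from [pseudobulk()]).
#' @return positive numeric vector of per-group size factors.
#' @export
medianOfRatiosFactors <- function(table) {
  pos <- rowSums(table > 0) == ncol(table)
  if (!any(pos))
    stop("no peak has nonzero counts in all groups")
  m <- table[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  f <- apply(m / geo, 2, median)
  f / exp(mean(log(f)))
}

.row_ttest <- function(ya, yb, varEqual = FALSE) {
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- apply(ya, 1, var); vb <- apply(yb, 1, var)
  fc <- mb - ma
  if (varEqual) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(fc))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- ifelse(se2 == 0, ifelse(fc == 0, 0, sign(fc) * Inf), fc / sqrt(se2))
  p <- ifelse(se2 == 0, ifelse(fc == 0, 1, 0),
              2 * pt(-abs(t), pmax(df, 1)))
  list(fc = fc, t = t, p = p)
}

#' Differential accessibility between two subsets, raw or centered
#'
#' Replicate-level (donor pseudobulk) values are `log2(count + pseudocount)`
#' — divided by median-of-ratios size factors first in `"centered"` mode,
#' left untouched in `"raw"` mode (the non-centered statistic appropriate
#' when fold changes are not believed to centre on zero). Per peak:
#' log2 fold change = mean(B) − mean(A) on the log scale, a two-sided
#' two-sample t-test across replicates (Welch by default; set
#' `varEqual = TRUE` for the pooled-variance Student's test), and BH
#' q-values over tested peaks. Peaks whose mean raw count is below
#' `minMean` in both subsets are excluded from testing.
#'
#' @param table peaks-by-replicates count matrix from [pseudobulk()].
#' @param subsets subset label of each replicate column.
#' @param subsetA,subsetB the two subsets to contrast (log2FC is B vs A).
#' @param mode `"raw"` or `"centered"`.
#' @param pseudocount added before log2 (must be > 0).
#' @param minMean expression filter on mean raw counts.
#' @param varEqual use the pooled-variance Student's t-test.
#' @param classes optional named compartment per peak id, recorded in the
#'   result.
#' @return `data.frame`: `peak_id`, `compartment` (NA when `classes` is
#'   NULL), `log2fc`, `t_stat`, `p_value`, `q_value`, `mode`.
#' @export
diffAccessibility <- function(table, subsets, subsetA, subsetB,
                              mode = c("raw", "centered"),
                              pseudocount = 1, minMean = 5,
                              varEqual = FALSE, classes = NULL) {
  mode <- match.arg(mode)
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  if (length(subsets) != ncol(table))
    stop("'subsets' must label every replicate column")
  ia <- which(subsets == subsetA); ib <- which(subsets == subsetB)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 replicate columns per subset")

  norm <- table
  if (mode == "centered") {
    sf <- medianOfRatiosFactors(table)
    norm <- sweep(table, 2, sf, "/")
  }
  y <- log2(norm + pseudocount)

  keep <- !(rowMeans(table[, ia, drop = FALSE]) < minMean &
              rowMeans(table[, ib, drop = FALSE]) < minMean)
  y <- y[keep, , drop = FALSE]
  tt <- .row_ttest(y[, ia, drop = FALSE], y[, ib, drop = FALSE],
                   varEqual = varEqual)
  ids <- rownames(table)[keep]
  res <- data.frame(
    peak_id = ids,
    compartment = if (is.null(classes)) NA_character_
                  else unname(classes[ids]),
    log2fc = unname(tt$fc),
    t_stat = unname(tt$t),
    p_value = unname(tt$p),
    q_value = p.adjust(tt$p, method = "BH"),
    mode = mode,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Summarize per-peak fold changes by compartment
#'
#' For each compartment: the mean and sd of the log2 fold changes, the
#' number of tested peaks, and a one-sample t-test of mean != 0. The raw
#' versus centered contrast of these summaries is the package's core
#' readout: under a real global DRE loss, centering attenuates the DRE
#' mean toward zero and pushes the promoter mean spuriously upward.
#'
#' @param results `data.frame` from [diffAccessibility()] (one mode, one
#'   contrast).
#' @param classes optional named compartment per peak id; used when the
#'   results carry no compartment column.
#' @return `data.frame`: `compartment`, `mean_log2fc`, `sd`, `n_peaks`,
#'   `one_sample_p`. Empty compartments are omitted with a message.
#' @export
compartmentShift <- function(results, classes = NULL) {
  comp <- results$compartment
  if (all(is.na(comp))) {
    if (is.null(classes))
      stop("results carry no compartment labels and no 'classes' given")
    comp <- unname(classes[results$peak_id])
  }
  lv <- intersect(c("promoter", "ctcf_distal", "dre", "unassigned"),
                  unique(comp[!is.na(comp)]))
  missing <- setdiff(c("promoter", "ctcf_distal", "dre"), lv)
  if (length(missing))
    message("empty compartment(s) omitted: ",
            paste(missing, collapse = ", "))
  out <- lapply(lv, function(cl) {
    fc <- results$log2fc[!is.na(comp) & comp == cl]
    p <- if (length(fc) >= 2L && sd(fc) > 0)
      t.test(fc, mu = 0)$p.value
    else if (length(fc) >= 1L && all(fc == 0)) 1 else NA_real_
    data.frame(compartment = cl, mean_log2fc = mean(fc),
               sd = sd(fc), n_peaks = length(fc), one_sample_p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
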