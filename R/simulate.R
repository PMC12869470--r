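#' @include AllClasses.R motifs.R io.R
NULL

#' Simulation parameters for the synthetic NK-cell dataset
#'
#' Bundles every knob of the generator with validation. The defaults encode
#' the study conditions the pipeline is built around: three NK subsets
#' (CD56-bright, CD56-dim CD57-, CD56-dim CD57+) from three donors, a
#' planted global DRE accessibility loss of one log2 unit affecting 70% of
#' DREs in the dim subsets together with a mild (+0.2 log2) promoter gain,
#' negative-binomial counts with dispersion 0.5, co-accessible peak pairs
#' with binarized correlation 0.6, and a 20% spiked-in fraction of
#' low-quality cells that fail the fragment-level QC thresholds.
#'
#' @param seed integer seed; every stochastic draw of every stage derives
#'   from it.
#' @param nCellsPerSubset cells simulated per subset (also the size of the
#'   fragment-level QC cell pool).
#' @param subsets ordered subset labels; the first is the reference
#'   (unshifted) subset.
#' @param nDonors replicate donors per subset.
#' @param nPromoterPeaks,nCtcfPeaks,nDrePeaks peak counts per compartment.
#' @param dreShiftLog2 planted log2 fold change of shifted DREs in non-
#'   reference subsets (negative = loss).
#' @param promoterShiftLog2 planted log2 fold change of promoters in non-
#'   reference subsets.
#' @param fracDreShifted fraction of DRE peaks carrying the shift.
#' @param meanDepthPerCell expected total counts per cell in the reference
#'   subset.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param nCoaccessPairs number of planted co-accessible DRE pairs.
#' @param coaccessRho target binarized cross-cell correlation of planted
#'   pairs (must be in (0, 1); the latent-activity construction cannot plant
#'   negative correlation).
#' @param fracLowqCells fraction of cells simulated as low quality.
#' @param nSnps number of SNPs emitted by [simulateSnps()].
#' @param fracSnpsInPeaks fraction of SNPs placed inside DRE peaks.
#' @param peakWidthBp peak width in bp.
#' @param peakSpacingBp distance between consecutive peak starts.
#' @param fragsPerGoodCell mean fragments per good cell.
#' @param fragsPerLowqCell upper bound on fragments per low-quality cell
#'   (kept below the 200-unique-fragment QC threshold).
#' @param tssFragFrac fraction of a good cell's fragments drawn around a
#'   TSS.
#' @return validated list of class `sim_config`.
#' @export
simConfig <- function(seed = 1L,
                      nCellsPerSubset = 500L,
                      subsets = c("bright", "dim57neg", "dim57pos"),
                      nDonors = 3L,
                      nPromoterPeaks = 300L,
                      nCtcfPeaks = 150L,
                      nDrePeaks = 600L,
                      dreShiftLog2 = -1,
                      promoterShiftLog2 = 0.2,
                      fracDreShifted = 0.7,
                      meanDepthPerCell = 5000,
                      dispersion = 0.5,
                      nCoaccessPairs = 20L,
                      coaccessRho = 0.6,
                      fracLowqCells = 0.2,
                      nSnps = 50L,
                      fracSnpsInPeaks = 0.5,
                      peakWidthBp = 400L,
                      peakSpacingBp = 3000L,
                      fragsPerGoodCell = 800,
                      fragsPerLowqCell = 150,
                      tssFragFrac = 0.5) {
  cfg <- list(seed = as.integer(seed), nCellsPerSubset = nCellsPerSubset,
              subsets = subsets, nDonors = nDonors,
              nPromoterPeaks = nPromoterPeaks, nCtcfPeaks = nCtcfPeaks,
              nDrePeaks = nDrePeaks, dreShiftLog2 = dreShiftLog2,
              promoterShiftLog2 = promoterShiftLog2,
              fracDreShifted = fracDreShifted,
              meanDepthPerCell = meanDepthPerCell, dispersion = dispersion,
              nCoaccessPairs = nCoaccessPairs, coaccessRho = coaccessRho,
              fracLowqCells = fracLowqCells, nSnps = nSnps,
              fracSnpsInPeaks = fracSnpsInPeaks, peakWidthBp = peakWidthBp,
              peakSpacingBp = peakSpacingBp,
              fragsPerGoodCell = fragsPerGoodCell,
              fragsPerLowqCell = fragsPerLowqCell,
              tssFragFrac = tssFragFrac)
  counts <- c("nCellsPerSubset", "nDonors", "nPromoterPeaks", "nCtcfPeaks",
              "nDrePeaks", "nCoaccessPairs", "nSnps", "peakWidthBp",
              "peakSpacingBp")
  for (f in counts)
    if (cfg[[f]] < 0) stop("'", f, "' must be >= 0")
  for (f in c("fracDreShifted", "fracLowqCells", "fracSnpsInPeaks"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  if (abs(cfg$coaccessRho) >= 1) stop("|coaccessRho| must be < 1")
  if (cfg$dispersion <= 0) stop("'dispersion' must be positive")
  if (cfg$meanDepthPerCell <= 0) stop("'meanDepthPerCell' must be positive")
  if (length(cfg$subsets) < 1L) stop("need at least one subset label")
  class(cfg) <- "sim_config"
  cfg
}

.random_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## Draw a concrete instantiation of an IUPAC consensus (N -> random base).
.instantiate_iupac <- function(consensus) {
  vapply(strsplit(consensus, "")[[1]], function(m) {
    set <- intersect(IUPAC_SETS[[m]], c("A", "C", "G", "T"))
    if (length(set) == 1L) set else sample(set, 1L)
  }, "")
}

.has_hit <- function(seqchars, motif) {
  nrow(scanMotif(paste(seqchars, collapse = ""), motif)) > 0L
}

.count_fixed <- function(s, pattern) {
  length(gregexpr(pattern, s, fixed = TRUE)[[1]]) -
    (gregexpr(pattern, s, fixed = TRUE)[[1]][1] == -1L)
}

#' Simulate a synthetic genome with planted regulatory architecture
#'
#' Lays promoter, CTCF-distal and DRE peaks along a few megabase-scale
#' contigs (uniform random background sequence), plants one exact M4
#' instantiation in every promoter peak and one CTCF core consensus in
#' every CTCF peak, and rejection-resamples DRE backgrounds until they are
#' free of both motifs. One designated DRE additionally carries a STAT3
#' motif instance adjacent to (not overlapping) a CCTTCT context whose
#' second base is the designated C-to-T SNP: the alternate allele creates
#' the BLIMP1 repressor site CTTTCT while leaving the STAT3 site intact.
#' A per-contig blacklist region is reserved beyond the peak array.
#'
#' @param config a [simConfig()] object.
#' @param maxAttempts rejection-sampling cap per peak; exceeding it signals
#'   a motif/background inconsistency and is an error.
#' @return A [SimulatedGenome-class].
#' @export
simulateGenome <- function(config, maxAttempts = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$peakWidthBp
  spacing <- config$peakSpacingBp
  nP <- config$nPromoterPeaks; nC <- config$nCtcfPeaks
  nD <- config$nDrePeaks
  n <- nP + nC + nD
  if (n < 1L) stop("need at least one peak")
  if (nD < 1L) stop("need at least one DRE peak (designated SNP carrier)")
  classes <- sample(rep(c("promoter", "ctcf_distal", "dre"),
                        times = c(nP, nC, nD)))

  perContig <- 500L
  nContigs <- ceiling(n / perContig)
  contigOf <- ceiling(seq_len(n) / perContig)
  slot <- seq_len(n) - (contigOf - 1L) * perContig
  startPos <- 10000L + (slot - 1L) * spacing + 1L
  contigNames <- paste0("ctg", seq_len(nContigs))
  contigPeakCount <- tabulate(contigOf, nContigs)
  contigLen <- 10000L + contigPeakCount * spacing + 40000L

  contigs <- lapply(contigLen, .random_chars)
  names(contigs) <- contigNames

  ctcfConsensus <- strsplit("TGGCCACCAGGGGGCGCTA", "")[[1]]
  ctcfPwm <- ctcfMotif()
  m4 <- m4Motif()
  ctcfStarts <- integer(0); ctcfChrom <- character(0)

  designatedIdx <- which(classes == "dre")[1]
  designated <- NULL

  for (i in seq_len(n)) {
    s <- startPos[i]
    ok <- FALSE
    for (attempt in seq_len(maxAttempts)) {
      seqc <- .random_chars(w)
      if (classes[i] == "promoter") {
        inst <- .instantiate_iupac(m4@consensus)
        o <- sample.int(w - length(inst) + 1L, 1L)
        seqc[o:(o + length(inst) - 1L)] <- inst
        ok <- TRUE
      } else if (classes[i] == "ctcf_distal") {
        o <- sample.int(w - length(ctcfConsensus) + 1L, 1L)
        seqc[o:(o + length(ctcfConsensus) - 1L)] <- ctcfConsensus
        if (!.has_hit(seqc, m4)) {
          ctcfStarts <- c(ctcfStarts, s + o - 1L)
          ctcfChrom <- c(ctcfChrom, contigNames[contigOf[i]])
          ok <- TRUE
        }
      } else if (i == designatedIdx) {
        o0 <- max(1L, floor(w / 2) - 20L)
        stat3 <- strsplit("TTCCAGGAA", "")[[1]]
        seqc[o0:(o0 + 8L)] <- stat3
        o1 <- o0 + 11L                       # 2-bp spacer after STAT3
        seqc[o1:(o1 + 5L)] <- strsplit("CCTTCT", "")[[1]]
        refs <- paste(seqc, collapse = "")
        altc <- seqc; altc[o1 + 1L] <- "T"
        alts <- paste(altc, collapse = "")
        if (!.has_hit(seqc, m4) &&
            nrow(scanMotif(refs, ctcfPwm)) == 0L &&
            .count_fixed(refs, "CTTTCT") == 0L &&
            .count_fixed(refs, "AGAAAG") == 0L &&
            .count_fixed(alts, "CTTTCT") == 1L &&
            .count_fixed(alts, "AGAAAG") == 0L) {
          designated <- list(rsid = "rs_synthetic_1",
                             chrom = contigNames[contigOf[i]],
                             pos = s + o1,     # second base of CCTTCT
                             ref = "C", alt = "T",
                             peak_id = sprintf("peak_%05d", i))
          ok <- TRUE
        }
      } else {
        if (!.has_hit(seqc, m4) &&
            nrow(scanMotif(paste(seqc, collapse = ""), ctcfPwm)) == 0L)
          ok <- TRUE
      }
      if (ok) break
    }
    if (!ok)
      stop("rejection sampling failed after ", maxAttempts,
           " attempts for peak ", i,
           " (motif/background inconsistency)")
    contigs[[contigOf[i]]][s:(s + w - 1L)] <- seqc
  }

  genome <- DNAStringSet(vapply(contigs, paste, "", collapse = ""))
  peaks <- GRanges(contigNames[contigOf], IRanges(startPos, width = w),
                   id = sprintf("peak_%05d", seq_len(n)), class = classes)
  promIdx <- which(classes == "promoter")
  tss <- GRanges(contigNames[contigOf[promIdx]],
                 IRanges(startPos[promIdx] + floor(w / 2), width = 1L),
                 peak_id = sprintf("peak_%05d", promIdx))
  ctcfSites <- GRanges(ctcfChrom,
                       IRanges(ctcfStarts, width = length(ctcfConsensus)))
  blacklist <- GRanges(contigNames,
                       IRanges(contigLen - 24999L, contigLen - 20000L))
  new("SimulatedGenome", genome = genome, peaks = peaks, tss = tss,
      ctcfSites = ctcfSites, blacklist = blacklist,
      designatedSnp = designated)
}

#' Simulate an snATAC fragment stream with a spiked low-quality fraction
#'
#' Good cells draw abundant fragments whose midpoints concentrate around
#' TSSs (normal with 150 bp sd, half of all fragments) with the remainder
#' uniform, and whose lengths come from a sub-nucleosomal-dominant mixture
#' (75% in 40-120 bp, 25% in 160-280 bp). Low-quality cells draw fewer than
#' 200 fragments, uniform positions with 15% forced into blacklist regions,
#' and long-fragment-dominant lengths. Fragments never extend past contig
#' ends.
#'
#' @param config a [simConfig()] object.
#' @param sg a [SimulatedGenome-class].
#' @return list with `fragments` (`GRanges` with mcols `barcode`, `count`)
#'   and `lowqBarcodes` (character).
#' @export
simulateFragments <- function(config, sg) {
  stopifnot(inherits(config, "sim_config"), is(sg, "SimulatedGenome"))
  set.seed(config$seed + 1L)
  nCells <- config$nCellsPerSubset
  nLow <- round(config$fracLowqCells * nCells)
  barcodes <- sprintf("BC%05d", seq_len(nCells))
  lowIdx <- if (nLow > 0) sample.int(nCells, nLow) else integer(0)
  goodIdx <- setdiff(seq_len(nCells), lowIdx)

  contigLen <- setNames(Biostrings::width(sg@genome), names(sg@genome))
  tssChrom <- as.character(seqnames(sg@tss))
  tssPos <- start(sg@tss)
  bl <- sg@blacklist
  blChrom <- as.character(seqnames(bl))

  draw_len <- function(n, monoFrac) {
    mono <- runif(n) < monoFrac
    len <- integer(n)
    len[mono] <- sample(160:280, sum(mono), replace = TRUE)
    len[!mono] <- sample(40:120, sum(!mono), replace = TRUE)
    len
  }

  frag_block <- function(chrom, mid, len) {
    maxLen <- contigLen[chrom]
    s <- pmax(1L, pmin(as.integer(mid - floor(len / 2)),
                       as.integer(maxLen - len)))
    GRanges(chrom, IRanges(s, width = len))
  }

  parts <- list(); bcs <- list()

  if (length(goodIdx)) {
    nf <- pmax(300L, round(rnorm(length(goodIdx),
                                 config$fragsPerGoodCell, 100)))
    total <- sum(nf)
    cellBc <- rep(barcodes[goodIdx], nf)
    isTss <- runif(total) < config$tssFragFrac & length(tssPos) > 0
    chrom <- character(total); mid <- numeric(total)
    nT <- sum(isTss)
    if (nT) {
      ti <- sample.int(length(tssPos), nT, replace = TRUE)
      chrom[isTss] <- tssChrom[ti]
      mid[isTss] <- tssPos[ti] + round(rnorm(nT, 0, 150))
    }
    nB <- total - nT
    if (nB) {
      ci <- sample.int(length(contigLen), nB, replace = TRUE,
                       prob = contigLen)
      chrom[!isTss] <- names(contigLen)[ci]
      mid[!isTss] <- ceiling(runif(nB) * contigLen[ci])
    }
    len <- draw_len(total, 0.25)
    parts <- c(parts, list(frag_block(chrom, mid, len)))
    bcs <- c(bcs, list(cellBc))
  }

  if (length(lowIdx)) {
    nf <- sample(50:config$fragsPerLowqCell, length(lowIdx), replace = TRUE)
    total <- sum(nf)
    cellBc <- rep(barcodes[lowIdx], nf)
    inBl <- runif(total) < 0.15
    chrom <- character(total); mid <- numeric(total)
    nBl <- sum(inBl)
    if (nBl) {
      bi <- sample.int(length(bl), nBl, replace = TRUE)
      chrom[inBl] <- blChrom[bi]
      mid[inBl] <- start(bl)[bi] +
        ceiling(runif(nBl) * (width(bl)[bi] - 1L))
    }
    nU <- total - nBl
    if (nU) {
      ci <- sample.int(length(contigLen), nU, replace = TRUE,
                       prob = contigLen)
      chrom[!inBl] <- names(contigLen)[ci]
      mid[!inBl] <- ceiling(runif(nU) * contigLen[ci])
    }
    len <- draw_len(total, 0.7)
    parts <- c(parts, list(frag_block(chrom, mid, len)))
    bcs <- c(bcs, list(cellBc))
  }

  frags <- if (length(parts)) do.call(c, parts) else GRanges()
  frags$barcode <- unlist(bcs, use.names = FALSE)
  frags$count <- 1L + rpois(length(frags), 0.2)
  list(fragments = frags, lowqBarcodes = barcodes[lowIdx])
}

## Mean of an NB with size r whose probability of a nonzero draw is p_on.
.nb_mu_for_on_rate <- function(p_on, r) r * ((1 - p_on)^(-1 / r) - 1)

#' Simulate peaks-by-cells count matrices for the NK subsets
#'
#' Per-peak baseline means follow a gamma-weighted split of the per-cell
#' depth; counts are negative binomial with per-cell lognormal depth
#' factors. In non-reference subsets the means of the shifted DRE set are
#' multiplied by `2^dreShiftLog2` and promoter means by
#' `2^promoterShiftLog2`; total depth is deliberately NOT rebalanced
#' afterwards — the planted global shift is real, which is exactly the
#' situation in which zero-centred normalization misleads. Planted
#' co-accessible DRE pairs share a per-cell latent Bernoulli activity whose
#' high/low negative-binomial means are calibrated in closed form so the
#' binarized cross-cell correlation equals `coaccessRho`; pair peaks are
#' exempt from the DRE shift.
#'
#' @param config a [simConfig()] object.
#' @param sg a [SimulatedGenome-class].
#' @return list with `se` (a `SummarizedExperiment`, assay `counts`,
#'   colData `barcode`/`subset`/`donor`, rowRanges the peaks),
#'   `shiftedDreIds` and `plantedPairs` (data.frame peak_a, peak_b, rho).
#' @export
simulateCounts <- function(config, sg) {
  stopifnot(inherits(config, "sim_config"), is(sg, "SimulatedGenome"))
  set.seed(config$seed + 2L)
  peaks <- sg@peaks
  n <- length(peaks)
  r <- 1 / config$dispersion

  wgt <- rgamma(n, shape = 2, rate = 1)
  lambda <- config$meanDepthPerCell * wgt / sum(wgt)

  dreIds <- peaks$id[peaks$class == "dre"]
  ## planted pairs: consecutive DRE peaks on the same contig
  pairs <- data.frame(peak_a = character(0), peak_b = character(0),
                      rho = numeric(0))
  pairPeaks <- character(0)
  if (config$nCoaccessPairs > 0) {
    if (config$coaccessRho <= 0)
      stop("planted co-accessibility requires coaccessRho in (0, 1)")
    dre <- peaks[peaks$class == "dre"]
    dre <- dre[order(as.character(seqnames(dre)), start(dre))]
    avail <- which(as.character(seqnames(dre))[-length(dre)] ==
                     as.character(seqnames(dre))[-1])
    take <- integer(0); used <- logical(length(dre))
    for (k in avail) {
      if (!used[k] && !used[k + 1L]) {
        take <- c(take, k); used[c(k, k + 1L)] <- TRUE
        if (length(take) == config$nCoaccessPairs) break
      }
    }
    if (length(take) < config$nCoaccessPairs)
      stop("not enough adjacent DRE peaks to plant ",
           config$nCoaccessPairs, " pairs")
    pairs <- data.frame(peak_a = dre$id[take], peak_b = dre$id[take + 1L],
                        rho = config$coaccessRho,
                        stringsAsFactors = FALSE)
    pairPeaks <- c(pairs$peak_a, pairs$peak_b)
  }

  nShift <- round(config$fracDreShifted * length(dreIds))
  shiftable <- setdiff(dreIds, pairPeaks)
  if (nShift > length(shiftable))
    stop("fracDreShifted leaves too few DREs after excluding planted pairs")
  shifted <- if (nShift > 0) sample(shiftable, nShift) else character(0)

  ## closed-form calibration of the latent-activity on-rates
  d <- sqrt(config$coaccessRho) / 2
  hi <- 0.5 + d; lo <- 0.5 - d
  if (hi >= 1 || lo <= 0)
    stop("coaccessRho infeasible for the latent-activity construction")
  muH <- .nb_mu_for_on_rate(hi, r)
  muL <- .nb_mu_for_on_rate(lo, r)

  nCells <- config$nCellsPerSubset
  blocks <- list(); cd <- list()
  pairRows <- match(pairPeaks, peaks$id)
  for (si in seq_along(config$subsets)) {
    sub <- config$subsets[si]
    lam <- lambda
    if (si > 1L) {
      ish <- peaks$id %in% shifted
      lam[ish] <- lam[ish] * 2^config$dreShiftLog2
      ipr <- peaks$class == "promoter"
      lam[ipr] <- lam[ipr] * 2^config$promoterShiftLog2
    }
    s <- rlnorm(nCells, 0, 0.2)
    mu <- outer(lam, s)
    m <- matrix(rnbinom(n * nCells, mu = as.vector(mu), size = r),
                nrow = n)
    for (p in seq_len(nrow(pairs))) {
      A <- rbinom(nCells, 1L, 0.5)
      muPair <- ifelse(A == 1L, muH, muL)
      ra <- match(pairs$peak_a[p], peaks$id)
      rb <- match(pairs$peak_b[p], peaks$id)
      m[ra, ] <- rnbinom(nCells, mu = muPair, size = r)
      m[rb, ] <- rnbinom(nCells, mu = muPair, size = r)
    }
    colnames(m) <- sprintf("%s_c%04d", sub, seq_len(nCells))
    blocks[[si]] <- m
    cd[[si]] <- data.frame(
      barcode = colnames(m), subset = sub,
      donor = sprintf("d%d", rep_len(seq_len(config$nDonors), nCells)),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- peaks$id
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = peaks,
    colData = S4Vectors::DataFrame(do.call(rbind, cd),
                                   row.names = colnames(counts)))
  list(se = se, shiftedDreIds = shifted, plantedPairs = pairs)
}

.trait_pools <- function() {
  list(
    immune = c("lymphocyte count", "monocyte count",
               "neutrophil percentage", "autoimmune thyroid disease",
               "NK cell surface marker level", "asthma susceptibility"),
    psychological = c("depression", "anxiety disorder",
                      "addiction severity", "schizophrenia risk",
                      "neuroticism score"),
    other = c("height", "body mass index", "hair color",
              "heel bone mineral density")
  )
}

#' Simulate trait-annotated SNPs over the synthetic genome
#'
#' Emits `nSnps` single-nucleotide variants: the designated BLIMP1-creating
#' SNP (always present, always annotated with an immune trait), a
#' configured fraction placed inside DRE peaks, and the remainder in
#' peak-free background. Reference alleles are read from the genome; traits
#' are drawn from small immune / psychological / other phrase pools that
#' the default [categorizeTraits()] keyword lists partition exactly.
#'
#' @param config a [simConfig()] object.
#' @param sg a [SimulatedGenome-class].
#' @return list with `snps` (data.frame chrom, pos, rsid, ref, alt, trait)
#'   and `truth` (list: `snp_peaks` named peak id or NA per rsid,
#'   `snp_category` named category per rsid, `snp_effects` for the
#'   designated SNP).
#' @export
simulateSnps <- function(config, sg) {
  stopifnot(inherits(config, "sim_config"), is(sg, "SimulatedGenome"))
  set.seed(config$seed + 3L)
  nSnps <- config$nSnps
  if (nSnps < 1L) stop("nSnps must be >= 1 (the designated SNP is always emitted)")
  des <- sg@designatedSnp
  peaks <- sg@peaks
  pools <- .trait_pools()
  bases <- c("A", "C", "G", "T")

  nIn <- round(config$fracSnpsInPeaks * nSnps)
  nInExtra <- max(0L, nIn - 1L)          # designated SNP counts as in-peak
  nOut <- nSnps - max(nIn, 1L)

  dre <- peaks[peaks$class == "dre" & peaks$id != des$peak_id]
  rows <- list(data.frame(chrom = des$chrom, pos = des$pos,
                          rsid = des$rsid, ref = des$ref, alt = des$alt,
                          trait = pools$immune[1],
                          stringsAsFactors = FALSE))
  truthPeak <- setNames(des$peak_id, des$rsid)
  truthCat <- setNames("immune", des$rsid)

  k <- 1L
  pick_trait <- function() {
    cat <- sample(names(pools), 1L)
    list(cat = cat, trait = sample(pools[[cat]], 1L))
  }
  if (nInExtra > 0) {
    pi <- sample.int(length(dre), nInExtra, replace = nInExtra > length(dre))
    for (j in seq_len(nInExtra)) {
      k <- k + 1L
      pk <- dre[pi[j]]
      pos <- start(pk) + sample.int(width(pk), 1L) - 1L
      chrom <- as.character(seqnames(pk))
      ref <- substring(as.character(sg@genome[[chrom]]), pos, pos)
      tr <- pick_trait()
      rsid <- sprintf("rs_synthetic_%d", k)
      rows[[k]] <- data.frame(chrom = chrom, pos = pos, rsid = rsid,
                              ref = ref, alt = sample(setdiff(bases, ref), 1L),
                              trait = tr$trait, stringsAsFactors = FALSE)
      truthPeak[rsid] <- pk$id
      truthCat[rsid] <- tr$cat
    }
  }
  if (nOut > 0) {
    contigLen <- setNames(Biostrings::width(sg@genome), names(sg@genome))
    for (j in seq_len(nOut)) {
      k <- k + 1L
      repeat {
        ci <- sample.int(length(contigLen), 1L)
        chrom <- names(contigLen)[ci]
        pos <- sample.int(contigLen[ci], 1L)
        hit <- GRanges(chrom, IRanges(pos, pos))
        if (!any(overlapsAny(hit, peaks))) break
      }
      ref <- substring(as.character(sg@genome[[chrom]]), pos, pos)
      tr <- pick_trait()
      rsid <- sprintf("rs_synthetic_%d", k)
      rows[[k]] <- data.frame(chrom = chrom, pos = pos, rsid = rsid,
                              ref = ref, alt = sample(setdiff(bases, ref), 1L),
                              trait = tr$trait, stringsAsFactors = FALSE)
      truthPeak[rsid] <- NA_character_
      truthCat[rsid] <- tr$cat
    }
  }
  snps <- do.call(rbind, rows)
  list(snps = snps,
       truth = list(
         snp_peaks = truthPeak,
         snp_category = truthCat,
         snp_effects = setNames(
           list(list(gained = "BLIMP1", lost = character(0))), des$rsid)))
}

#' Run the full synthetic-data generator
#'
#' Chains [simulateGenome()], [simulateFragments()], [simulateCounts()] and
#' [simulateSnps()] under one seed and assembles the complete ground truth
#' needed to score every downstream stage without re-simulation.
#'
#' @param config a [simConfig()] object.
#' @return list with `genome` ([SimulatedGenome-class]), `fragments`,
#'   `counts` (`SummarizedExperiment`), `snps`, and `groundTruth` (list:
#'   peak_class_by_id, shifted_dre_ids, planted_pairs, lowq_barcodes,
#'   snp_peaks, snp_category, snp_effects, designated_snp).
#' @export
simulateDataset <- function(config = simConfig()) {
  sg <- simulateGenome(config)
  fr <- simulateFragments(config, sg)
  cm <- simulateCounts(config, sg)
  sn <- simulateSnps(config, sg)
  list(
    genome = sg,
    fragments = fr$fragments,
    counts = cm$se,
    snps = sn$snps,
    groundTruth = list(
      peak_class_by_id = setNames(sg@peaks$class, sg@peaks$id),
      shifted_dre_ids = cm$shiftedDreIds,
      planted_pairs = cm$plantedPairs,
      lowq_barcodes = fr$lowqBarcodes,
      snp_peaks = sn$truth$snp_peaks,
      snp_category = sn$truth$snp_category,
      snp_effects = sn$truth$snp_effects,
      designated_snp = sg@designatedSnp
    )
  )
}
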