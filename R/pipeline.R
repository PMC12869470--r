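#' @include simulate.R qc.R peaks.R diffacc.R coaccess.R variants.R
NULL

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline end to end on a synthetic fixture
#'
#' Simulates a dataset, applies fragment QC, classifies peaks, runs the
#' raw and centered differential modes between the first two subsets,
#' scores co-accessibility on the reference subset, annotates
#' DRE-to-promoter links against loops placed on the planted pairs, scores
#' the designated SNP's allele-specific motif deltas, writes every stage's
#' output as TSV plus a JSON run manifest (seed, parameters, record
#' counts; no absolute paths), and prints the raw-versus-centered
#' compartment-shift table side by side. Byte-identical outputs for equal
#' seeds.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @param config optional [simConfig()]; defaults to a small demo-sized
#'   configuration derived from `seed`.
#' @param poolSize metacell size for co-accessibility.
#' @return invisibly, a list with the in-memory results (`qc`, `classified`,
#'   `diff_raw`, `diff_centered`, `shift_raw`, `shift_centered`, `pairs`,
#'   `links`, `snp_deltas`, `manifest`).
#' @export
runDemo <- function(outDir, seed = 1L, config = NULL, poolSize = 5L) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (is.null(config))
    config <- simConfig(seed = seed, nCellsPerSubset = 150L,
                        nPromoterPeaks = 60L, nCtcfPeaks = 30L,
                        nDrePeaks = 120L, nCoaccessPairs = 5L,
                        nSnps = 20L, meanDepthPerCell = 2000)
  sim <- simulateDataset(config)
  sg <- sim$genome

  ## --- QC ---------------------------------------------------------------
  qc <- computeCellQC(sim$fragments, tssSites(sg), blacklistRegions(sg))
  filt <- filterCells(qc)
  .write_tsv(filt$qc, file.path(outDir, "qc.tsv"))

  ## --- peak classification ---------------------------------------------
  classified <- classifyPeaks(simPeaks(sg), tssSites(sg),
                              genomeSequences(sg),
                              ctcfEvidence = ctcfSites(sg))
  .write_tsv(data.frame(peak_id = classified$id,
                        chrom = as.character(seqnames(classified)),
                        start = start(classified) - 1L,
                        end = end(classified),
                        compartment = classified$compartment,
                        evidence = classified$evidence),
             file.path(outDir, "peak_classes.tsv"))
  classes <- setNames(classified$compartment, classified$id)

  ## --- differential accessibility, raw vs centered ----------------------
  cd <- as.data.frame(colData(sim$counts))
  pb <- pseudobulk(sim$counts, paste(cd$subset, cd$donor, sep = "."))
  pbSubset <- sub("\\..*$", "", colnames(pb))
  subA <- config$subsets[1]; subB <- config$subsets[2]
  dRaw <- diffAccessibility(pb, pbSubset, subA, subB, mode = "raw",
                            classes = classes)
  dCen <- diffAccessibility(pb, pbSubset, subA, subB, mode = "centered",
                            classes = classes)
  .write_tsv(dRaw, file.path(outDir, "diff_raw.tsv"))
  .write_tsv(dCen, file.path(outDir, "diff_centered.tsv"))
  sRaw <- compartmentShift(dRaw)
  sCen <- compartmentShift(dCen)
  .write_tsv(sRaw, file.path(outDir, "shift_raw.tsv"))
  .write_tsv(sCen, file.path(outDir, "shift_centered.tsv"))

  side <- merge(sRaw, sCen, by = "compartment",
                suffixes = c("_raw", "_centered"))
  cat("Compartment shift,", subB, "vs", subA,
      "(raw vs centered normalization):\n")
  print(side[, c("compartment", "n_peaks_raw", "mean_log2fc_raw",
                 "mean_log2fc_centered")], row.names = FALSE)

  ## --- co-accessibility on the reference subset -------------------------
  ref <- sim$counts[, cd$subset == subA]
  pooled <- binarizeAndPool(ref, poolSize = poolSize, seed = seed)
  pairs <- coAccessibility(pooled, rowRanges(ref))
  .write_tsv(pairs, file.path(outDir, "coaccess.tsv"))

  ## loops placed on the planted pairs (synthetic loop evidence)
  pp <- sim$groundTruth$planted_pairs
  pk <- simPeaks(sg)
  loops <- if (nrow(pp)) {
    Pairs(pk[match(pp$peak_a, pk$id)], pk[match(pp$peak_b, pk$id)],
          score = rep(1, nrow(pp)))
  } else NULL
  links <- annotateLinks(pairs, classes, loops, pk)
  .write_tsv(links[links$passes_cutoff, , drop = FALSE],
             file.path(outDir, "links.tsv"))

  ## --- allele-specific motif deltas -------------------------------------
  snps <- categorizeTraits(sim$snps)
  .write_tsv(snps, file.path(outDir, "snps.tsv"))
  des <- sim$groundTruth$designated_snp
  deltas <- alleleMotifDelta(
    snps[snps$rsid == des$rsid, , drop = FALSE],
    genomeSequences(sg))
  .write_tsv(deltas, file.path(outDir, "snp_deltas.tsv"))

  manifest <- list(
    pipeline = "nkatac demo",
    seed = seed,
    parameters = unclass(config),
    stages = list(
      qc = list(cells_in = nrow(qc), cells_kept = length(filt$kept)),
      classify = list(peaks = length(classified)),
      diff = list(peaks_tested = nrow(dRaw), modes = c("raw", "centered"),
                  contrast = paste(subB, "vs", subA)),
      coaccess = list(pairs_scored = nrow(pairs),
                      pairs_passing = sum(pairs$passes_cutoff),
                      pool_size = poolSize),
      snpmotif = list(snps = nrow(snps), designated = des$rsid)
    ),
    outputs = c("qc.tsv", "peak_classes.tsv", "diff_raw.tsv",
                "diff_centered.tsv", "shift_raw.tsv", "shift_centered.tsv",
                "coaccess.tsv", "links.tsv", "snps.tsv", "snp_deltas.tsv")
  )
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(qc = filt$qc, classified = classified, diff_raw = dRaw,
                 diff_centered = dCen, shift_raw = sRaw,
                 shift_centered = sCen, pairs = pairs, links = links,
                 snp_deltas = deltas, manifest = manifest))
}
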