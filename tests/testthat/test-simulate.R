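test_that("the generator is deterministic under a fixed seed", {
  a <- simulateDataset(tiny_config(seed = 5))
  b <- simulateDataset(tiny_config(seed = 5))
  expect_identical(as.character(genomeSequences(a$genome)),
                   as.character(genomeSequences(b$genome)))
  expect_identical(a$fragments, b$fragments)
  expect_identical(SummarizedExperiment::assay(a$counts),
                   SummarizedExperiment::assay(b$counts))
  expect_identical(a$snps, b$snps)
  expect_identical(a$groundTruth, b$groundTruth)
  c <- simulateDataset(tiny_config(seed = 6))
  expect_false(identical(as.character(genomeSequences(a$genome)),
                         as.character(genomeSequences(c$genome))))
})

test_that("planted motif architecture is exactly as designed", {
  cfg <- simConfig(seed = 2, nCellsPerSubset = 10L, nPromoterPeaks = 10L,
                   nCtcfPeaks = 6L, nDrePeaks = 20L, nCoaccessPairs = 2L,
                   nSnps = 5L)
  sg <- simulateGenome(cfg)
  pk <- simPeaks(sg)
  seqs <- extractSequences(genomeSequences(sg), pk)
  m4 <- m4Motif(); ctcf <- ctcfMotif()

  prom <- seqs[pk$class == "promoter"]
  expect_length(prom, 10L)
  expect_true(all(vapply(prom, function(s)
    nrow(scanMotif(s, m4)) >= 1L, logical(1))))

  ctcfSeqs <- seqs[pk$class == "ctcf_distal"]
  expect_true(all(vapply(ctcfSeqs, function(s)
    nrow(scanMotif(s, ctcf)) >= 1L, logical(1))))

  dre <- seqs[pk$class == "dre"]
  expect_true(all(vapply(dre, function(s)
    nrow(scanMotif(s, m4)) == 0L, logical(1))))
  expect_true(all(vapply(dre, function(s)
    nrow(scanMotif(s, ctcf)) == 0L, logical(1))))
})

test_that("the designated SNP creates CTTTCT on the alt allele only", {
  cfg <- tiny_config(seed = 8)
  sg <- simulateGenome(cfg)
  des <- designatedSnp(sg)
  pk <- simPeaks(sg)
  peak <- pk[pk$id == des$peak_id]
  refSeq <- extractSequences(genomeSequences(sg), peak)[[1]]
  expect_false(grepl("CTTTCT", refSeq, fixed = TRUE))
  off <- des$pos - start(peak) + 1L
  expect_equal(substring(refSeq, off, off), "C")
  altSeq <- refSeq
  substring(altSeq, off, off) <- "T"
  expect_true(grepl("CTTTCT", altSeq, fixed = TRUE))
  ## the neighbouring STAT3 site is present and does not span the SNP
  hits <- scanMotif(refSeq, stat3Motif())
  expect_gte(nrow(hits), 1L)
  expect_true(all(hits$end < off | hits$start > off))
})

test_that("fragments respect contig bounds and the low-quality contract", {
  cfg <- tiny_config(seed = 4, fracLowqCells = 0.2)
  sg <- simulateGenome(cfg)
  sim <- simulateFragments(cfg, sg)
  fr <- sim$fragments
  expect_length(sim$lowqBarcodes, 0.2 * cfg$nCellsPerSubset)
  lens <- setNames(Biostrings::width(genomeSequences(sg)),
                   names(genomeSequences(sg)))
  expect_true(all(start(fr) >= 1L))
  expect_true(all(end(fr) <= lens[as.character(seqnames(fr))]))
  ## every low-quality barcode has < 200 unique fragments by construction
  tab <- table(fr$barcode)
  expect_true(all(tab[sim$lowqBarcodes] < 200))
})

test_that("null counts have subset-balanced means; planted shifts recover", {
  cfgNull <- tiny_config(seed = 14, dreShiftLog2 = 0,
                         promoterShiftLog2 = 0, nCoaccessPairs = 0L)
  simN <- simulateCounts(cfgNull, simulateGenome(cfgNull))
  m <- SummarizedExperiment::assay(simN$se)
  sub <- SummarizedExperiment::colData(simN$se)$subset
  mA <- mean(m[, sub == "bright"]); mB <- mean(m[, sub == "dim57neg"])
  expect_lt(abs(log2(mB / mA)), 0.1)

  cfg <- simConfig(seed = 15, nCellsPerSubset = 500L, subsets =
                     c("bright", "dim57neg"), nPromoterPeaks = 20L,
                   nCtcfPeaks = 0L, nDrePeaks = 120L, fracDreShifted = 1,
                   dreShiftLog2 = -1, promoterShiftLog2 = 0,
                   nCoaccessPairs = 0L, meanDepthPerCell = 3000)
  sim <- simulateCounts(cfg, simulateGenome(cfg))
  m <- SummarizedExperiment::assay(sim$se)
  sub <- SummarizedExperiment::colData(sim$se)$subset
  dre <- rownames(m) %in% sim$shiftedDreIds
  ratio <- log2(rowMeans(m[dre, sub == "dim57neg"]) /
                  rowMeans(m[dre, sub == "bright"]))
  expect_lt(abs(mean(ratio) - (-1)), 0.1)
})

test_that("planted pairs carry the calibrated binarized correlation", {
  cfg <- simConfig(seed = 16, nCellsPerSubset = 500L, subsets = "bright",
                   nPromoterPeaks = 5L, nCtcfPeaks = 0L, nDrePeaks = 40L,
                   nCoaccessPairs = 5L, coaccessRho = 0.6, nSnps = 2L)
  sim <- simulateCounts(cfg, simulateGenome(cfg))
  m <- SummarizedExperiment::assay(sim$se) > 0
  rhos <- apply(sim$plantedPairs, 1, function(p)
    cor(m[p["peak_a"], ] * 1, m[p["peak_b"], ] * 1))
  expect_true(all(abs(rhos - 0.6) < 0.12))
  expect_lt(abs(mean(rhos) - 0.6), 0.1)
})

test_that("SNP placement and trait pools match their ground truth", {
  cfg <- tiny_config(seed = 17, nSnps = 50L, fracSnpsInPeaks = 0.5)
  sg <- simulateGenome(cfg)
  sim <- simulateSnps(cfg, sg)
  expect_equal(nrow(sim$snps), 50L)
  inPeak <- !is.na(sim$truth$snp_peaks)
  expect_equal(sum(inPeak), 25L)
  got <- snpsInPeaks(sim$snps, simPeaks(sg))
  expect_identical(got, sim$truth$snp_peaks)
  cat_ <- categorizeTraits(sim$snps)$category
  expect_identical(unname(cat_), unname(sim$truth$snp_category))
  ## reference alleles really are the genome base
  g <- genomeSequences(sg)
  refs <- mapply(function(ch, p)
    substring(as.character(g[[ch]]), p, p),
    sim$snps$chrom, sim$snps$pos)
  expect_identical(unname(refs), sim$snps$ref)
})

test_that("config validation rejects impossible settings", {
  expect_error(simConfig(fracDreShifted = 1.5), "\\[0, 1\\]")
  expect_error(simConfig(coaccessRho = 1), "< 1")
  expect_error(simConfig(dispersion = 0), "positive")
  cfg <- tiny_config(coaccessRho = -0.5)
  expect_error(simulateCounts(cfg, simulateGenome(cfg)), "coaccessRho")
})
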