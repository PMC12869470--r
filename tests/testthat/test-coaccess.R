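test_that("pooling with size 1 is the binary indicator and is deterministic", {
  set.seed(67)
  m <- matrix(rpois(20 * 12, 0.7), 20, 12,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  p1 <- binarizeAndPool(m, poolSize = 1L)
  expect_equal(unname(p1), unname((m > 0) * 1), ignore_attr = TRUE)
  pa <- binarizeAndPool(m, poolSize = 4L, seed = 3)
  pb <- binarizeAndPool(m, poolSize = 4L, seed = 3)
  expect_identical(pa, pb)
  expect_identical(attr(pa, "pools"), attr(pb, "pools"))
  ## identical cells -> all pooled entries equal per peak
  mi <- matrix(rep(c(0, 2), each = 1, times = 6), 2, 6)
  pi_ <- binarizeAndPool(mi, poolSize = 2L, seed = 1)
  expect_true(all(pi_[1, ] == pi_[1, 1]))
  expect_error(binarizeAndPool(m, poolSize = 50L), "exceeds")
})

test_that("co-accessibility scores have the right structure", {
  peaks <- GRanges("c1", IRanges(c(1000, 5000, 900000), width = 200),
                   id = c("pA", "pB", "pC"))
  pooled <- rbind(pA = c(1, 0, 1, 0, 1, 0),
                  pB = c(1, 0, 1, 0, 1, 0),
                  pC = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  cc <- coAccessibility(pooled, peaks, maxDistBp = 500000L, cutoff = 0.05)
  ## identical profiles score 1; distant pair absent
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$peak_a, "pA")
  expect_equal(cc$peak_b, "pB")
  expect_equal(cc$score, 1)
  expect_true(cc$passes_cutoff)

  ## zero-variance profile scores 0 with a flag, not NaN
  peaks2 <- GRanges("c1", IRanges(c(1000, 5000), width = 200),
                    id = c("pA", "pC"))
  cc2 <- coAccessibility(pooled[c("pA", "pC"), ], peaks2)
  expect_equal(cc2$score, 0)
  expect_true(cc2$zero_variance)
})

test_that("scores are symmetric and cutoff filtering is monotone", {
  cfg <- tiny_config(seed = 71, nCellsPerSubset = 100L)
  sg <- simulateGenome(cfg)
  sim <- simulateCounts(cfg, sg)
  ref <- sim$se[, SummarizedExperiment::colData(sim$se)$subset == "bright"]
  pooled <- binarizeAndPool(ref, poolSize = 2L, seed = 5)
  pk <- SummarizedExperiment::rowRanges(ref)
  cc <- coAccessibility(pooled, pk, maxDistBp = 20000L, cutoff = 0.05)
  ## canonical ordering: a precedes b in genome order
  st <- setNames(start(pk), pk$id)
  expect_true(all(st[cc$peak_a] <= st[cc$peak_b]))
  ## reversing the input row order changes nothing
  cc2 <- coAccessibility(pooled[rev(seq_len(nrow(pooled))), ],
                         rev(pk), maxDistBp = 20000L, cutoff = 0.05)
  expect_equal(cc[order(cc$peak_a, cc$peak_b), ],
               cc2[order(cc2$peak_a, cc2$peak_b), ],
               ignore_attr = TRUE)
  ## raising the cutoff never adds pairs
  for (cut in c(0.05, 0.25, 0.5)) {
    ccx <- coAccessibility(pooled, pk, maxDistBp = 20000L, cutoff = cut)
    expect_true(all(ccx$passes_cutoff ==
                      (ccx$score > cut)))
  }
  n005 <- sum(coAccessibility(pooled, pk, 20000L, 0.05)$passes_cutoff)
  n025 <- sum(coAccessibility(pooled, pk, 20000L, 0.25)$passes_cutoff)
  expect_lte(n025, n005)
})

test_that("planted pairs are recovered above the null background", {
  cfg <- simConfig(seed = 73, nCellsPerSubset = 600L, subsets = "bright",
                   nPromoterPeaks = 10L, nCtcfPeaks = 0L, nDrePeaks = 80L,
                   nCoaccessPairs = 8L, coaccessRho = 0.6, nSnps = 2L,
                   meanDepthPerCell = 1500)
  sg <- simulateGenome(cfg)
  sim <- simulateCounts(cfg, sg)
  pooled <- binarizeAndPool(sim$se, poolSize = 3L, seed = 7)
  pk <- simPeaks(sg)
  cc <- coAccessibility(pooled, pk, maxDistBp = 500000L, cutoff = 0.05)
  key <- paste(cc$peak_a, cc$peak_b)
  pkey <- paste(sim$plantedPairs$peak_a, sim$plantedPairs$peak_b)
  planted <- cc[key %in% pkey, ]
  nullp <- cc[!key %in% pkey, ]
  expect_equal(nrow(planted), 8L)
  expect_true(all(abs(planted$score - 0.6) < 0.15))
  expect_gt(min(planted$score), quantile(nullp$score, 0.95))
})

test_that("loop support requires both anchors of a single loop", {
  peaks <- GRanges("c1", IRanges(c(1000, 50000, 200000), width = 500),
                   id = c("dreA", "promB", "otherC"))
  classes <- c(dreA = "dre", promB = "promoter", otherC = "dre")
  pairs <- data.frame(peak_a = c("dreA", "dreA"),
                      peak_b = c("promB", "otherC"),
                      score = c(0.5, 0.5), distance_bp = c(49000, 199000),
                      passes_cutoff = TRUE, zero_variance = FALSE)
  ## no loops: nothing supported
  ann0 <- annotateLinks(pairs, classes, NULL, peaks)
  expect_false(any(ann0$loop_supported))
  expect_equal(ann0$dre_to_promoter, c(TRUE, FALSE))

  ## a loop exactly on the first pair's peaks
  loops <- S4Vectors::Pairs(GRanges("c1", IRanges(900, 1600)),
                            GRanges("c1", IRanges(49900, 50600)),
                            score = 1)
  ann1 <- annotateLinks(pairs, classes, loops, peaks)
  expect_equal(ann1$loop_supported, c(TRUE, FALSE))

  ## swapped anchor orientation still matches
  loopsSwap <- S4Vectors::Pairs(GRanges("c1", IRanges(49900, 50600)),
                                GRanges("c1", IRanges(900, 1600)),
                                score = 1)
  ann2 <- annotateLinks(pairs, classes, loopsSwap, peaks)
  expect_true(ann2$loop_supported[1])

  ## single anchors of two different loops do not count
  loops2 <- S4Vectors::Pairs(
    GRanges("c1", IRanges(c(900, 700000), c(1600, 700500))),
    GRanges("c1", IRanges(c(800000, 49900), c(800500, 50600))),
    score = c(1, 1))
  ann3 <- annotateLinks(pairs, classes, loops2, peaks)
  expect_false(ann3$loop_supported[1])
})
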