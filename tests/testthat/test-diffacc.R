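test_that("pseudobulk sums match the brute-force oracle and conserve mass", {
  set.seed(43)
  m <- matrix(rpois(100 * 60, 2), 100, 60,
              dimnames = list(sprintf("p%03d", 1:100), NULL))
  g <- sample(c("g1", "g2", "g3"), 60, TRUE)
  pb <- pseudobulk(m, g)
  expect_equal(pb, brute_pseudobulk_oracle(m, g))
  expect_equal(sum(pb), sum(m))

  ## one group containing all cells equals the row sums
  expect_equal(unname(pseudobulk(m, rep("all", 60))[, 1]),
               unname(rowSums(m)))
  ## identical cells in two equal groups give identical columns
  m2 <- matrix(rep(1:10, 4), 10, 4)
  pb2 <- pseudobulk(m2, c("a", "a", "b", "b"))
  expect_equal(pb2[, "a"], pb2[, "b"])
  expect_error(pseudobulk(m, rep(NA, 60)), "no group")
})

test_that("median-of-ratios factors hit their closed forms", {
  m <- matrix(c(10, 20, 30, 10, 20, 30, 10, 20, 30), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("g", 1:3)))
  expect_equal(medianOfRatiosFactors(m), setNames(rep(1, 3), paste0("g", 1:3)))

  m2 <- cbind(g1 = c(10, 20, 30), g2 = 2 * c(10, 20, 30))
  f <- medianOfRatiosFactors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)

  set.seed(47)
  m3 <- matrix(rpois(200 * 4, 30) + 1, 200, 4,
               dimnames = list(NULL, paste0("g", 1:4)))
  expect_equal(unname(medianOfRatiosFactors(m3)), brute_mor_oracle(m3))

  expect_error(medianOfRatiosFactors(cbind(c(0, 1), c(1, 0))), "nonzero")
})

test_that("median-of-ratios agrees with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(53)
  ## odd row count: the median of ratios then commutes with log, so the
  ## two implementations must agree to numerical precision
  m <- matrix(rnbinom(301 * 6, mu = 50, size = 2) + 1, 301, 6)
  ours <- unname(medianOfRatiosFactors(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("differential test reproduces closed-form examples", {
  tab <- cbind(a1 = c(16, 5), a2 = c(16, 5), b1 = c(4, 5), b2 = c(4, 5))
  rownames(tab) <- c("p1", "p2")
  ## pseudocount -> 0 limit recovers log2(4/16) = -2
  r <- diffAccessibility(tab, c("a", "a", "b", "b"), "a", "b",
                         pseudocount = 1e-9, minMean = 0)
  expect_equal(r$log2fc[r$peak_id == "p1"], -2, tolerance = 1e-6)
  ## identical replicate columns: fc 0, p 1
  expect_equal(r$log2fc[r$peak_id == "p2"], 0)
  expect_equal(r$p_value[r$peak_id == "p2"], 1)

  ## low-count peaks are excluded by the expression filter
  tab2 <- rbind(tab, p3 = c(1, 1, 1, 1))
  r2 <- diffAccessibility(tab2, c("a", "a", "b", "b"), "a", "b",
                          minMean = 5)
  expect_false("p3" %in% r2$peak_id)
  expect_error(diffAccessibility(tab[, 1:3], c("a", "a", "b"), "a", "b"),
               ">= 2 replicate")
})

test_that("BH q-values are monotone in p-rank and bounded below by p", {
  set.seed(59)
  tab <- matrix(rnbinom(500 * 6, mu = 40, size = 2), 500, 6,
                dimnames = list(sprintf("p%03d", 1:500), NULL))
  r <- diffAccessibility(tab, rep(c("a", "b"), each = 3), "a", "b")
  expect_true(all(r$q_value >= r$p_value - 1e-12))
  o <- order(r$p_value)
  expect_true(all(diff(r$q_value[o]) >= -1e-12))
})

test_that("compartment shift summarizes planted fold changes by class", {
  res <- data.frame(peak_id = sprintf("p%02d", 1:40),
                    compartment = rep(c("dre", "promoter"), each = 20),
                    log2fc = c(rnorm(20, -1, 0.05), rnorm(20, 0.2, 0.05)),
                    t_stat = 0, p_value = 0.5, q_value = 0.5,
                    mode = "raw")
  cs <- compartmentShift(res)
  expect_setequal(cs$compartment, c("dre", "promoter"))
  expect_equal(cs$mean_log2fc[cs$compartment == "dre"], -1,
               tolerance = 0.1)
  expect_equal(cs$n_peaks, c(20L, 20L))

  ## all-zero fold changes: mean 0, p 1
  res0 <- res; res0$log2fc <- 0
  cs0 <- compartmentShift(res0)
  expect_true(all(cs0$mean_log2fc == 0))
  expect_true(all(cs0$one_sample_p == 1))
})

test_that("centering masks a planted global DRE loss (small-scale)", {
  cfg <- simConfig(seed = 61, nCellsPerSubset = 240L,
                   subsets = c("bright", "dim57neg"), nDonors = 3L,
                   nPromoterPeaks = 100L, nCtcfPeaks = 0L,
                   nDrePeaks = 400L, dreShiftLog2 = -1,
                   promoterShiftLog2 = 0.2, fracDreShifted = 0.7,
                   nCoaccessPairs = 0L, meanDepthPerCell = 4000)
  sg <- simulateGenome(cfg)
  sim <- simulateCounts(cfg, sg)
  cd <- as.data.frame(SummarizedExperiment::colData(sim$se))
  pb <- pseudobulk(sim$se, paste(cd$subset, cd$donor, sep = "."))
  sub <- sub("\\..*", "", colnames(pb))
  classes <- setNames(simPeaks(sg)$class, simPeaks(sg)$id)
  raw <- compartmentShift(diffAccessibility(pb, sub, "bright", "dim57neg",
                                            mode = "raw",
                                            classes = classes))
  cen <- compartmentShift(diffAccessibility(pb, sub, "bright", "dim57neg",
                                            mode = "centered",
                                            classes = classes))
  dreR <- raw$mean_log2fc[raw$compartment == "dre"]
  dreC <- cen$mean_log2fc[cen$compartment == "dre"]
  prR <- raw$mean_log2fc[raw$compartment == "promoter"]
  prC <- cen$mean_log2fc[cen$compartment == "promoter"]
  expect_gt(dreC, dreR)   # centering attenuates the DRE loss
  expect_gt(prC, prR)     # and inflates the promoter gain
  expect_lt(abs(prR - 0.2), 0.12)
})
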