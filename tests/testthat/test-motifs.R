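test_that("IUPAC scanning matches hand-checked hits", {
  m4 <- m4Motif()
  h <- scanMotif("ACTACGAAACCCA", m4)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$end, 13L)
  expect_equal(h$strand, "+")

  ## STAT3 TTCCNGGAA: N matches A
  expect_gte(nrow(scanMotif("TTCCAGGAA", stat3Motif())), 1L)

  ## BLIMP1 site exists only after the C>T substitution
  expect_equal(nrow(scanMotif("CCTTCT", blimp1Motif())), 0L)
  expect_equal(nrow(scanMotif("CTTTCT", blimp1Motif())), 1L)

  ## an N in the sequence matches nothing but a motif N
  expect_equal(nrow(scanMotif("ACTNCGAAACCCA", m4)), 0L)
  expect_equal(nrow(scanMotif("TTCCNGGAA", stat3Motif(),
                              bothStrands = FALSE)), 1L)
})

test_that("IUPAC scanning equals the regex-expansion oracle on random 50-mers", {
  set.seed(42)
  motifs <- list(m4Motif(), stat3Motif(), blimp1Motif(),
                 iupacMotif("CTCFcons", "CCASYAGRKGGCR"))
  for (rep in 1:250) {
    s <- random_dna(50, alphabet = c("A", "C", "G", "T",
                                     if (rep %% 5 == 0) "N"))
    for (m in motifs) {
      got <- scanMotif(s, m)
      want <- regex_scan_oracle(s, m@consensus)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        want <- want[order(want$start, want$strand), ]
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
      }
    }
  }
})

test_that("strand symmetry: minus hits are plus hits on the reverse complement", {
  set.seed(7)
  m <- stat3Motif()
  for (i in 1:50) {
    s <- random_dna(60)
    h <- scanMotif(s, m)
    hrc <- scanMotif(revComp(s), m)
    minus <- h[h$strand == "-", ]
    plusOnRc <- hrc[hrc$strand == "+", ]
    expect_equal(sort(60 - (minus$start + 9 - 1) + 1), sort(plusOnRc$start))
    expect_equal(nrow(h), nrow(hrc))  # both-strand count is rc-invariant
  }
})

test_that("hit detection is case-insensitive", {
  m4 <- m4Motif()
  expect_equal(scanMotif("actacgaaaccca", m4)$start, 1L)
  set.seed(21)
  for (i in 1:20) {
    s <- random_dna(80)
    expect_identical(scanMotif(tolower(s), m4), scanMotif(s, m4))
  }
})

test_that("reverse complement is an involution with the right values", {
  expect_equal(revComp("ACGT"), "ACGT")
  expect_equal(revComp("TTCCAGGAA"), "TTCCTGGAA")
  set.seed(3)
  for (i in 1:20) {
    s <- random_dna(sample(5:100, 1))
    expect_equal(revComp(revComp(s)), s)
    expect_equal(nchar(revComp(s)), nchar(s))
  }
  expect_error(revComp("ACGU"), "invalid")
})

test_that("PWM scanning agrees with IUPAC scanning via an indicator matrix", {
  ## exact-match indicator PWM: huge positive log-odds on the consensus
  ## base, huge negative elsewhere, threshold just below the max
  cons <- "TTCCAGGAA"
  bases <- c("A", "C", "G", "T")
  mat <- vapply(strsplit(cons, "")[[1]], function(b) {
    v <- rep(-100, 4); v[match(b, bases)] <- 10; v
  }, numeric(4))
  ind <- pwmMotif("IND", mat, 10 * nchar(cons) - 0.5)
  fixed <- iupacMotif("FIXED", cons)
  set.seed(9)
  for (i in 1:1000) {
    s <- random_dna(50)
    got <- scanMotif(s, ind)
    want <- scanMotif(s, fixed)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("degenerate PWM edge cases behave", {
  zero <- pwmMotif("Z", matrix(0, 4, 5), 0)
  s <- "ACGTACGTAC"
  h <- scanMotif(s, zero)
  expect_equal(nrow(h), 2 * (10 - 5 + 1))  # every offset, both strands
  expect_equal(nrow(scanMotif("", zero)), 0L)
  expect_equal(nrow(scanMotif("ACG", zero)), 0L)  # shorter than motif
  ## windows containing N are skipped
  expect_equal(nrow(scanMotif("ACGTNACGT", zero, bothStrands = FALSE)), 0L)
})

test_that("bundled CTCF PWM finds its consensus but not random sequence", {
  ctcf <- ctcfMotif()
  planted <- paste0(random_dna(20), "TGGCCACCAGGGGGCGCTA", random_dna(20))
  set.seed(13)
  expect_gte(nrow(scanMotif(planted, ctcf)), 1L)
  misses <- vapply(1:200, function(i)
    nrow(scanMotif(random_dna(400), ctcf)), integer(1))
  expect_equal(sum(misses), 0L)
})

test_that("motif files load", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tconsensus", "M4\tACTAYRnnnCCCR", "STAT3\tTTCCNGGAA"), f)
  ms <- readMotifsTsv(f)
  expect_named(ms, c("M4", "STAT3"))
  expect_equal(ms$M4@consensus, "ACTAYRNNNCCCR")

  j <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 TEST",
               "A [ 10  0  0  5 ]",
               "C [  0 10  0  5 ]",
               "G [  0  0 10  0 ]",
               "T [  0  0  0  0 ]"), j)
  pm <- readJasparPfm(j)
  expect_s4_class(pm, "Motif")
  expect_equal(motifLength(pm), 4L)
  expect_gte(nrow(scanMotif("ACGA", pm, bothStrands = FALSE)), 1L)
})

test_that("invalid motifs are rejected at construction", {
  expect_error(iupacMotif("bad", "ACGX"), "IUPAC")
  expect_error(iupacMotif("short", "ACG"), "length")
  expect_error(pwmMotif("bad", matrix(Inf, 4, 6), 1), "finite")
})
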