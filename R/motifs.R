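#' @include AllClasses.R
NULL

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over the A/C/G/T/N alphabet
#'   (either case).
#' @return character vector of reverse complements, case preserved.
#' @examples
#' revComp("TTCCAGGAA")  # "TTCCTGGAA"
#' @export
revComp <- function(x) {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad))
    stop("invalid character(s) outside ACGTN alphabet in sequence ",
         which(bad)[1])
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

.seq_chars <- function(sequence) strsplit(toupper(sequence), "")[[1]]

## Offsets (1-based) at which an IUPAC consensus matches; pure position-wise
## set membership. An 'N' in the sequence is only allowed where the motif
## itself has 'N'.
.iupac_offsets <- function(chars, consensus) {
  L <- nchar(consensus)
  n <- length(chars)
  if (n < L) return(integer())
  mot <- strsplit(consensus, "")[[1]]
  ok <- rep(TRUE, n - L + 1L)
  for (p in seq_len(L)) {
    ok <- ok & chars[seq_len(n - L + 1L) + (p - 1L)] %in% IUPAC_SETS[[mot[p]]]
  }
  which(ok)
}

.pwm_scores <- function(chars, mat) {
  L <- ncol(mat)
  n <- length(chars)
  if (n < L) return(numeric())
  idx <- match(chars, c("A", "C", "G", "T"))  # NA for N
  s <- numeric(n - L + 1L)
  for (p in seq_len(L)) {
    s <- s + mat[, p][idx[seq_len(n - L + 1L) + (p - 1L)]]
  }
  s  # NA where the window contains an N
}

.hit_frame <- function(motif_id, starts, L, strand, score) {
  data.frame(
    motif_id = rep(motif_id, length(starts)),
    start = as.integer(starts),
    end = as.integer(starts + L - 1L),
    strand = rep(strand, length(starts)),
    score = rep_len(score, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for motif hits on one or both strands
#'
#' IUPAC motifs match a window iff every position of the window is in the
#' degeneracy set of the corresponding consensus position; a hit scores 1.
#' PWM motifs score each window by the sum of per-position log2-odds and hit
#' iff the score reaches the motif threshold; windows containing an \code{N}
#' are skipped. Minus-strand hits are found by scanning the reverse
#' complement and mapping coordinates back to the input frame, so reported
#' coordinates are always 1-based inclusive positions on the input sequence.
#' Overlapping hits are all reported; scanning is case-insensitive.
#'
#' @param sequence a single DNA string (A/C/G/T/N).
#' @param motif a [Motif-class].
#' @param bothStrands scan the minus strand too (default `TRUE`).
#' @return `data.frame` with columns `motif_id`, `start`, `end`, `strand`,
#'   `score` (one row per hit; zero rows when nothing matches).
#' @examples
#' scanMotif("ACTACGAAACCCA", iupacMotif("M4", "ACTAYRNNNCCCR"))
#' @export
scanMotif <- function(sequence, motif, bothStrands = TRUE) {
  stopifnot(is(motif, "Motif"), length(sequence) == 1L)
  chars <- .seq_chars(sequence)
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("sequence contains non-ACGTN character(s): ",
         paste(bad, collapse = ", "))
  L <- motifLength(motif)
  n <- length(chars)
  if (motif@kind == "iupac") {
    fwd <- .hit_frame(motif@id, .iupac_offsets(chars, motif@consensus),
                      L, "+", 1)
    hits <- fwd
    if (bothStrands) {
      rcchars <- rev(chartr("ACGTN", "TGCAN", chars))
      off <- .iupac_offsets(rcchars, motif@consensus)
      hits <- rbind(fwd, .hit_frame(motif@id, n - (off + L - 1L) + 1L,
                                    L, "-", 1))
    }
  } else {
    sc <- .pwm_scores(chars, motif@matrix)
    keep <- which(!is.na(sc) & sc >= motif@threshold)
    hits <- .hit_frame(motif@id, keep, L, "+", 0)
    hits$score <- sc[keep]
    if (bothStrands) {
      rcchars <- rev(chartr("ACGTN", "TGCAN", chars))
      scm <- .pwm_scores(rcchars, motif@matrix)
      keepm <- which(!is.na(scm) & scm >= motif@threshold)
      mh <- .hit_frame(motif@id, n - (keepm + L - 1L) + 1L, L, "-", 0)
      mh$score <- scm[keepm]
      hits <- rbind(hits, mh)
    }
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Build a PWM from an IUPAC consensus
#'
#' Each consensus position assigns probability `matchProb` split evenly over
#' its degeneracy set and the remainder over the other bases; a fully
#' degenerate position (set size 4) is uniform. Probabilities are converted
#' to log2-odds against a uniform background and the hit threshold is set to
#' `thresholdFrac` of the maximum attainable score.
#'
#' @param id motif identifier.
#' @param consensus IUPAC consensus (no N positions of size 5).
#' @param matchProb total probability mass on the consensus set.
#' @param thresholdFrac threshold as a fraction of the maximum score.
#' @return A [Motif-class] of kind `"pwm"`.
#' @export
pwmFromConsensus <- function(id, consensus, matchProb = 0.85,
                             thresholdFrac = 0.8) {
  mot <- strsplit(toupper(consensus), "")[[1]]
  bases <- c("A", "C", "G", "T")
  mat <- vapply(mot, function(m) {
    set <- intersect(IUPAC_SETS[[m]], bases)
    k <- length(set)
    p <- if (k == 4L) rep(0.25, 4) else {
      pr <- rep((1 - matchProb) / (4 - k), 4)
      pr[match(set, bases)] <- matchProb / k
      pr
    }
    log2(p / 0.25)
  }, numeric(4))
  pwmMotif(id, mat, thresholdFrac * sum(apply(mat, 2, max)))
}

#' Bundled motifs used throughout the NK-cell analysis
#'
#' `m4Motif()` is the hyperconserved lymphocyte promoter motif
#' ACTAYRnnnCCCR (a RUNX + NF-Y + ETS/IKZF1 composite) used to flag
#' promoter-class peaks. `stat3Motif()` (TTCCNGGAA) and `blimp1Motif()`
#' (CTTTCT, the repressor site created by the regulatory C-to-T variant)
#' drive the allele-specific delta analysis. `ctcfMotif()` is a 19-bp
#' core-consensus log-odds matrix (JASPAR-style) thresholded at 80% of its
#' maximum score, used to call CTCF-distal peaks when no ChIP intervals are
#' supplied. `defaultMotifs()` returns all of them plus the three M4
#' component motifs.
#'
#' @return A [Motif-class], or for `defaultMotifs()` a named list of them.
#' @export
m4Motif <- function() iupacMotif("M4", "ACTAYRNNNCCCR")

#' @rdname m4Motif
#' @export
stat3Motif <- function() iupacMotif("STAT3", "TTCCNGGAA")

#' @rdname m4Motif
#' @export
blimp1Motif <- function() iupacMotif("BLIMP1", "CTTTCT")

#' @rdname m4Motif
#' @export
ctcfMotif <- function() pwmFromConsensus("CTCF", "TGGCCACCAGGGGGCGCTA")

#' @rdname m4Motif
#' @export
defaultMotifs <- function() {
  list(
    M4 = m4Motif(),
    STAT3 = stat3Motif(),
    BLIMP1 = blimp1Motif(),
    CTCF = ctcfMotif(),
    RUNX = iupacMotif("RUNX", "AACCACA"),
    NFY = iupacMotif("NFY", "CCAAT"),
    ETS = iupacMotif("ETS", "TCCCA")
  )
}

#' Read IUPAC motifs from a two-column TSV (id, consensus)
#'
#' @param path TSV file with a header line `id<TAB>consensus`.
#' @return named list of [Motif-class] objects.
#' @export
readMotifsTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "consensus") %in% names(df)))
    stop("motif TSV needs 'id' and 'consensus' columns")
  setNames(Map(iupacMotif, df$id, df$consensus), df$id)
}

#' Read a JASPAR-format position frequency matrix as a PWM motif
#'
#' Parses the `>ID name` header plus four `A [ ... ]` style rows, adds a
#' pseudocount, converts column frequencies to log2-odds against a uniform
#' background, and thresholds at `thresholdFrac` of the maximum score.
#'
#' @param path JASPAR .pfm/.jaspar file containing one matrix.
#' @param pseudocount added to every count before normalization.
#' @param thresholdFrac threshold as a fraction of the maximum score.
#' @return A [Motif-class] of kind `"pwm"`.
#' @export
readJasparPfm <- function(path, pseudocount = 0.5, thresholdFrac = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1], ">")) stop("JASPAR file must start with '>'")
  id <- strsplit(sub("^>", "", lines[1]), "[ \t]+")[[1]][1]
  rows <- lapply(lines[2:5], function(l) {
    l <- gsub("^[ACGT]|\\[|\\]", "", l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
  })
  counts <- do.call(rbind, rows) + pseudocount
  probs <- sweep(counts, 2, colSums(counts), "/")
  mat <- log2(probs / 0.25)
  pwmMotif(id, mat, thresholdFrac * sum(apply(mat, 2, max)))
}
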