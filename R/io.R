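#' @include AllClasses.R
NULL

## Readers and writers for the plain-text formats the pipeline touches.
## Externally BED/fragments/BEDPE are 0-based half-open; internally
## everything is a 1-based closed GRanges/IRanges. The conversion happens
## exactly once, here, in each direction.

.open_read <- function(path) {
  # file() auto-detects gzip on read
  con <- file(path, "rt")
  con
}

.open_write <- function(path) {
  if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
}

.read_table_lines <- function(path) {
  con <- .open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(lines = lines[keep], lineno = which(keep))
}

.parse_int <- function(x, what, lineno) {
  suppressWarnings(v <- as.integer(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad))
    stop("non-integer ", what, " at line ", lineno[which(bad)[1]])
  v
}

#' Read a BED file of genomic intervals
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` is 1-based
#' closed (start + 1, same end), so widths equal half-open lengths. Columns
#' 4 and 5, when present, populate mcols `name` and `score`. Input order is
#' preserved. With `oneBasedInclusive = TRUE` the coordinates are instead
#' taken as printed 1-based inclusive ranges (as in methods-section region
#' strings) and used unchanged.
#'
#' @param path BED file (3+ columns, optionally gzipped).
#' @param oneBasedInclusive treat coordinates as 1-based inclusive.
#' @return `GRanges`.
#' @export
readBed <- function(path, oneBasedInclusive = FALSE) {
  tab <- .read_table_lines(path)
  if (!length(tab$lines))
    return(GRanges())
  fields <- strsplit(tab$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("fewer than 3 tab-separated fields at line ",
         tab$lineno[which(nf < 3L)[1]])
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- .parse_int(vapply(fields, `[[`, "", 2L), "start", tab$lineno)
  e <- .parse_int(vapply(fields, `[[`, "", 3L), "end", tab$lineno)
  if (!oneBasedInclusive) {
    bad <- e <= s | s < 0L
    if (any(bad)) stop("invalid interval (end <= start or start < 0) at line ",
                       tab$lineno[which(bad)[1]])
    gr <- GRanges(chrom, IRanges(s + 1L, e))
  } else {
    bad <- e < s | s < 1L
    if (any(bad)) stop("invalid interval (end < start or start < 1) at line ",
                       tab$lineno[which(bad)[1]])
    gr <- GRanges(chrom, IRanges(s, e))
  }
  if (max(lengths(fields)) >= 4L && all(nf >= 4L))
    gr$name <- vapply(fields, `[[`, "", 4L)
  if (max(lengths(fields)) >= 5L && all(nf >= 5L))
    gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr `GRanges`; mcols `name` and `score` become columns 4 and 5.
#' @param path output path (gzipped when it ends in .gz).
#' @export
writeBed <- function(gr, path) {
  con <- .open_write(path)
  on.exit(close(con))
  cols <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  if (!is.null(gr$name)) {
    cols <- c(cols, list(gr$name))
    if (!is.null(gr$score)) cols <- c(cols, list(gr$score))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Parse a printed region string like "chr11:112,879,032-112,879,132"
#'
#' Methods sections typically print regions 1-based inclusive; the default
#' honours that, so the NCAM1 DRE string parses to a 101-bp range. Commas
#' and unicode dashes are tolerated.
#'
#' @param x region string `chrom:start-end`.
#' @param oneBasedInclusive interpret coordinates as 1-based inclusive
#'   (default); otherwise as 0-based half-open.
#' @return `GRanges` of length 1.
#' @examples
#' width(parseRegion("chr11:112,879,032-112,879,132"))  # 101
#' @export
parseRegion <- function(x, oneBasedInclusive = TRUE) {
  clean <- gsub(",", "", x)
  clean <- gsub("–|—|‐|−", "-", clean)
  m <- regmatches(clean, regexec("^([^:]+):([0-9]+)-([0-9]+)$", clean))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  s <- as.numeric(m[3]); e <- as.numeric(m[4])
  if (oneBasedInclusive) GRanges(m[2], IRanges(s, e))
  else GRanges(m[2], IRanges(s + 1, e))
}

#' Read an snATAC fragments file
#'
#' Five tab-separated columns: chrom, start (0-based), end (exclusive),
#' barcode, duplicate count (>= 1). Duplicate identical lines are kept as
#' separate records; deduplication is a QC concern, not an I/O one.
#'
#' @param path fragments TSV (optionally gzipped).
#' @return `GRanges` with mcols `barcode` and `count`; widths equal
#'   fragment lengths.
#' @export
readFragments <- function(path) {
  tab <- .read_table_lines(path)
  if (!length(tab$lines))
    return(GRanges(barcode = character(), count = integer()))
  fields <- strsplit(tab$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop("fragment record needs 5 fields at line ",
         tab$lineno[which(nf < 5L)[1]])
  s <- .parse_int(vapply(fields, `[[`, "", 2L), "start", tab$lineno)
  e <- .parse_int(vapply(fields, `[[`, "", 3L), "end", tab$lineno)
  cnt <- .parse_int(vapply(fields, `[[`, "", 5L), "count", tab$lineno)
  if (any(e <= s))
    stop("fragment with non-positive length at line ",
         tab$lineno[which(e <= s)[1]])
  if (any(cnt < 1L))
    stop("fragment count < 1 at line ", tab$lineno[which(cnt < 1L)[1]])
  gr <- GRanges(vapply(fields, `[[`, "", 1L), IRanges(s + 1L, e))
  gr$barcode <- vapply(fields, `[[`, "", 4L)
  gr$count <- cnt
  gr
}

#' Write fragments in the 5-column TSV convention
#'
#' @param gr `GRanges` with mcols `barcode` and `count`.
#' @param path output path.
#' @export
writeFragments <- function(gr, path) {
  con <- .open_write(path)
  on.exit(close(con))
  writeLines(paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   gr$barcode, gr$count, sep = "\t"), con)
  invisible(path)
}

#' Read Hi-C style loops from BEDPE
#'
#' Six or more tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2 [, name, score]). Anchors are canonically ordered within each
#' record by (chrom, start).
#'
#' @param path BEDPE file.
#' @return `S4Vectors::Pairs` of anchor `GRanges` with mcol `score`
#'   (0 when absent).
#' @export
readBedpe <- function(path) {
  tab <- .read_table_lines(path)
  if (!length(tab$lines))
    return(Pairs(GRanges(), GRanges(), score = numeric()))
  fields <- strsplit(tab$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("BEDPE record needs >= 6 fields at line ",
         tab$lineno[which(nf < 6L)[1]])
  g <- function(i) vapply(fields, `[[`, "", i)
  s1 <- .parse_int(g(2), "start1", tab$lineno)
  e1 <- .parse_int(g(3), "end1", tab$lineno)
  s2 <- .parse_int(g(5), "start2", tab$lineno)
  e2 <- .parse_int(g(6), "end2", tab$lineno)
  if (any(e1 <= s1 | e2 <= s2 | s1 < 0L | s2 < 0L))
    stop("malformed anchor coordinates at line ",
         tab$lineno[which(e1 <= s1 | e2 <= s2 | s1 < 0L | s2 < 0L)[1]])
  a <- GRanges(g(1), IRanges(s1 + 1L, e1))
  b <- GRanges(g(4), IRanges(s2 + 1L, e2))
  swap <- as.character(seqnames(a)) > as.character(seqnames(b)) |
    (as.character(seqnames(a)) == as.character(seqnames(b)) &
       start(a) > start(b))
  a2 <- a; a2[swap] <- b[swap]; b[swap] <- a[swap]
  score <- if (all(nf >= 8L))
    suppressWarnings(as.numeric(g(8))) else rep(0, length(a2))
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("negative loop score at line ",
                           tab$lineno[which(score < 0)[1]])
  Pairs(a2, b, score = score)
}

#' Write loops as BEDPE
#'
#' @param loops `Pairs` of anchor `GRanges` (as from [readBedpe()]).
#' @param path output path.
#' @export
writeBedpe <- function(loops, path) {
  con <- .open_write(path)
  on.exit(close(con))
  a <- S4Vectors::first(loops); b <- S4Vectors::second(loops)
  score <- if (!is.null(mcols(loops)$score)) mcols(loops)$score
           else rep(0, length(loops))
  writeLines(paste(as.character(seqnames(a)), start(a) - 1L, end(a),
                   as.character(seqnames(b)), start(b) - 1L, end(b),
                   ".", score, sep = "\t"), con)
  invisible(path)
}

#' Read DNA sequences from FASTA
#'
#' Case is folded to upper; any character outside A/C/G/T/N is an error
#' that names the offending sequence and position.
#'
#' @param path FASTA file (optionally gzipped).
#' @return `DNAStringSet`.
#' @export
readFasta <- function(path) {
  con <- .open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) {
    if (!length(lines) || !any(nzchar(lines))) return(DNAStringSet())
    stop("FASTA headers must begin with '>'")
  }
  grp <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "[ \t]"), `[[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-ACGTN character in sequence '", names_[i],
         "' at position ", bad[i])
  }
  setNames(DNAStringSet(seqs), names_)
}

#' Write DNA sequences as FASTA
#'
#' @param seqs `DNAStringSet` or named character vector.
#' @param path output path.
#' @param lineWidth wrap width in bp.
#' @export
writeFasta <- function(seqs, path, lineWidth = 70L) {
  con <- .open_write(path)
  on.exit(close(con))
  chs <- as.character(seqs)
  for (i in seq_along(chs)) {
    writeLines(paste0(">", names(chs)[i]), con)
    s <- chs[[i]]
    starts <- seq(1L, nchar(s), by = lineWidth)
    writeLines(substring(s, starts, pmin(starts + lineWidth - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a peaks-by-cells count matrix
#'
#' MatrixMarket coordinate files (`.mtx`) are read with
#' `Matrix::readMM`; a mismatch between the declared and actual
#' number of entries is an error. Dense TSV files must have peak ids as row
#' names and cell barcodes as the header. Entries must be nonnegative
#' integers.
#'
#' @param path `.mtx` or `.tsv` file.
#' @return base `matrix` (dense TSV) or `Matrix` sparse matrix (.mtx).
#' @export
readCountsMatrix <- function(path) {
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
    hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]),
                                                "[ \t]+")[[1]]))
    if (length(hdr) != 3L || anyNA(hdr))
      stop("malformed MatrixMarket size header")
    if (length(body) - 1L != hdr[3])
      stop("MatrixMarket header declares ", hdr[3], " entries but ",
           length(body) - 1L, " are present")
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e)
                    stop("malformed MatrixMarket file: ",
                         conditionMessage(e)))
    v <- m@x
  } else {
    df <- read.delim(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
    v <- as.vector(m)
  }
  if (any(v < 0) || any(v != round(v)))
    stop("count matrix entries must be nonnegative integers")
  m
}

#' Write a count matrix
#'
#' @param m matrix (dense or `Matrix` sparse).
#' @param path `.mtx` for MatrixMarket (names dropped) or `.tsv` for a
#'   dense table with row/column names.
#' @export
writeCountsMatrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"), path)
  } else {
    write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}

#' Read a SNP table
#'
#' Tab-separated with header columns chrom, pos (1-based, VCF convention),
#' rsid, ref, alt, trait. Only single-nucleotide variants are accepted.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
readSnpTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("chrom", "pos", "rsid", "ref", "alt", "trait")
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  if (!all(need %in% names(df)))
    stop("SNP table needs columns: ", paste(need, collapse = ", "))
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
    stop("only single-nucleotide variants are supported")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (any(!df$ref %in% c("A", "C", "G", "T") |
          !df$alt %in% c("A", "C", "G", "T")))
    stop("alleles must be A/C/G/T")
  df
}

#' Write a SNP table
#'
#' @param snps `data.frame` as returned by [readSnpTable()].
#' @param path output path.
#' @export
writeSnpTable <- function(snps, path) {
  write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize chromosome-name dialects
#'
#' Interval sets from different sources mix "chr11" and "11" spellings;
#' silent cross-dialect matching produces false-negative intersections, so
#' the default is to keep names as they are and match strictly. Opt in to
#' a prefix rule to harmonize.
#'
#' @param x `GRanges` or character vector of chromosome names.
#' @param style `"asis"` (default, no change), `"chr"` (ensure the chr
#'   prefix) or `"plain"` (strip it).
#' @return the input with renamed seqnames/names.
#' @export
normalizeChromNames <- function(x, style = c("asis", "chr", "plain")) {
  style <- match.arg(style)
  fix <- function(nm) switch(style,
    asis = nm,
    chr = ifelse(startsWith(nm, "chr"), nm, paste0("chr", nm)),
    plain = sub("^chr", "", nm))
  if (is.character(x)) return(fix(x))
  stopifnot(is(x, "GRanges"))
  if (style == "asis") return(x)
  lv <- seqlevels(x)
  renamed <- fix(lv)
  seqlevels(x) <- unname(renamed)
  x
}

#' Extract peak sequences from a set of contigs
#'
#' @param genome `DNAStringSet` of contigs.
#' @param gr `GRanges` on those contigs.
#' @return character vector of sequences, named by mcol `id` when present.
#' @export
extractSequences <- function(genome, gr) {
  missing <- setdiff(unique(as.character(seqnames(gr))), names(genome))
  if (length(missing))
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "))
  out <- character(length(gr))
  for (chr in unique(as.character(seqnames(gr)))) {
    i <- which(as.character(seqnames(gr)) == chr)
    v <- Biostrings::Views(genome[[chr]], start = start(gr)[i],
                           end = end(gr)[i])
    out[i] <- as.character(v)
  }
  if (!is.null(gr$id)) names(out) <- gr$id
  out
}

#' Distance from a region midpoint to an annotated TSS
#'
#' Looks a gene up in a TSS annotation table (default: the small GRCh38
#' table bundled with the package) and returns the absolute distance from
#' the region's midpoint to the TSS, in bp.
#'
#' @param region `GRanges` of length 1 (e.g. from [parseRegion()]).
#' @param gene gene symbol present in the annotation.
#' @param annotation path to a TSV with columns gene, chrom, tss, strand.
#' @return named numeric: distance in bp.
#' @export
distanceToTss <- function(region, gene,
                          annotation = system.file("extdata",
                                                   "grch38_tss.tsv",
                                                   package = "nkatac")) {
  ann <- read.delim(annotation, comment.char = "#",
                    stringsAsFactors = FALSE)
  row <- ann[ann$gene == gene, , drop = FALSE]
  if (nrow(row) != 1L) stop("gene not found in annotation: ", gene)
  if (row$chrom != as.character(seqnames(region))[1])
    stop("region and gene are on different chromosomes")
  mid <- floor((start(region)[1] + end(region)[1]) / 2)
  c(bp = abs(mid - row$tss))
}
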