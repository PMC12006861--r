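#' Read a multi-record FASTA genome
#'
#' Parses a FASTA file into an uppercase [Biostrings::DNAStringSet]. Contig
#' names are the first whitespace-delimited token of each header line.
#' Only the alphabet `A/C/G/T/N` is accepted after case normalization;
#' anything else (including other IUPAC ambiguity codes) is an error naming
#' the offending contig and position.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 description", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate contig name in FASTA: ", nm[duplicated(nm)][1L])
  seqs <- toupper(as.character(x))
  names(seqs) <- nm
  validate_genome(seqs)
  Biostrings::DNAStringSet(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  g <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

## Normalize any genome-like input to a validated named uppercase character
## vector; the scoring and shuffling code operates on plain strings.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.character(genome)) {
    g <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(g)) || any(!nzchar(names(g))))
    stop("every contig must be named")
  if (anyDuplicated(names(g)))
    stop("duplicate contig name: ", names(g)[duplicated(names(g))][1L])
  g <- toupper(g)
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  for (nm in names(g)) {
    codes <- utf8ToInt(g[[nm]])
    bad <- which(!codes %in% c(65L, 67L, 71L, 84L, 78L))  # A C G T N
    if (length(bad))
      stop(sprintf("contig '%s': illegal character '%s' at position %d",
                   nm, substr(g[[nm]], bad[1L], bad[1L]), bad[1L]))
  }
  invisible(TRUE)
}

contig_lengths <- function(genome) {
  g <- as_genome(genome)
  setNames(nchar(g), names(g))
}

#' Read a BED3/BED6 interval file
#'
#' BED coordinates are 0-based half-open on disk and are converted to the
#' 1-based closed convention of [GenomicRanges::GRanges] in memory (so a
#' BED record `c1 10 20` becomes `c1:11-20`). Optional columns 4-6 populate
#' the `name` and `score` metadata columns and the strand (`.` maps to
#' `*`). Empty intervals (`start >= end`) and non-integer coordinates are
#' errors reporting the file line.
#'
#' @param path Path to a tab-separated BED file.
#' @return A [GenomicRanges::GRanges] in file order with metadata columns
#'   `name` (character) and `score` (numeric).
#' @seealso [write_bed()], [as_bed_frame()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "track") &
                !startsWith(lines, "browser") & !startsWith(lines, "#"))
  if (!length(keep)) return(empty_granges())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    stop("line ", keep[which(n < 3L)[1L]], ": fewer than 3 tab-separated columns")
  contig <- vapply(fields, `[`, character(1), 1L)
  s_chr  <- vapply(fields, `[`, character(1), 2L)
  e_chr  <- vapply(fields, `[`, character(1), 3L)
  start0 <- suppressWarnings(as.numeric(s_chr))
  end0   <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(start0) | is.na(end0) |
               start0 != floor(start0) | end0 != floor(end0))
  if (length(bad))
    stop("line ", keep[bad[1L]], ": non-integer coordinate")
  if (any(start0 < 0))
    stop("line ", keep[which(start0 < 0)[1L]], ": negative start coordinate")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("line ", keep[bad[1L]], ": empty interval (start >= end)")
  name <- ifelse(n >= 4L, vapply(fields, `[`, character(1), 4L), ".")
  score_chr <- ifelse(n >= 5L, vapply(fields, `[`, character(1), 5L), "0")
  score <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score))
    stop("line ", keep[which(is.na(score))[1L]], ": non-numeric score")
  strand <- ifelse(n >= 6L, vapply(fields, `[`, character(1), 6L), ".")
  if (any(!strand %in% c("+", "-", ".")))
    stop("line ", keep[which(!strand %in% c("+", "-", "."))[1L]],
         ": strand must be '+', '-' or '.'")
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = ifelse(strand == ".", "*", strand))
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write intervals as BED6
#'
#' Inverse of [read_bed()]: coordinates are converted back to 0-based
#' half-open, strand `*` becomes `.`, and missing `name`/`score` metadata
#' default to `.` and `0`. `read_bed(write_bed(x))` reproduces `x` for any
#' valid BED6 content.
#'
#' @param x A [GenomicRanges::GRanges].
#' @param path Output path.
#' @param score_digits Optional number of decimal places for the score
#'   column (default `NULL` writes full precision).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, score_digits = NULL) {
  df <- as_bed_frame(x)
  if (!is.null(score_digits))
    df$score <- formatC(df$score, format = "f", digits = score_digits)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert intervals to a 0-based half-open BED data frame
#'
#' The single display/export conversion helper: in-memory intervals are
#' 1-based closed ([GenomicRanges::GRanges] convention); this returns the
#' equivalent 0-based half-open table used by BED and most genome browsers.
#'
#' @param x A [GenomicRanges::GRanges].
#' @return A data frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
as_bed_frame <- function(x) {
  stopifnot(methods::is(x, "GRanges"))
  mc <- S4Vectors::mcols(x)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(x))
  score <- if ("score" %in% names(mc)) as.numeric(mc$score) else rep(0, length(x))
  strand <- as.character(GenomicRanges::strand(x))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    name = name,
    score = score,
    strand = ifelse(strand == "*", ".", strand),
    stringsAsFactors = FALSE)
}

empty_granges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$name <- character(0)
  S4Vectors::mcols(gr)$score <- numeric(0)
  gr
}

#' Read a transcript annotation table (BED6+2)
#'
#' Transcript records are BED6 plus two extra columns, `gene_id` and
#' `biotype`. Every transcript must be stranded (`+` or `-`); the
#' transcription start site (TSS) is the interval start on `+` and the
#' interval end on `-`.
#'
#' @param path Path to a tab-separated BED6+2 file.
#' @return A stranded [GenomicRanges::GRanges] with metadata columns
#'   `gene_id` and `biotype`.
#' @export
read_transcripts <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    S4Vectors::mcols(gr)$biotype <- character(0)
    return(gr)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L))
    stop("line ", keep[which(lengths(fields) < 8L)[1L]],
         ": transcript table needs 8 columns (BED6 + gene_id + biotype)")
  tmpbed <- vapply(fields, function(f) paste(f[1:6], collapse = "\t"), character(1))
  tf <- tempfile(fileext = ".bed")
  on.exit(unlink(tf))
  writeLines(tmpbed, tf)
  gr <- read_bed(tf)
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("transcripts must be stranded ('+' or '-')")
  S4Vectors::mcols(gr)$gene_id <- vapply(fields, `[`, character(1), 7L)
  S4Vectors::mcols(gr)$biotype <- vapply(fields, `[`, character(1), 8L)
  gr
}

#' Transcription start sites of stranded transcripts
#'
#' @param transcripts A stranded [GenomicRanges::GRanges].
#' @return Integer vector of 1-based TSS positions (interval start on `+`,
#'   interval end on `-`).
#' @export
tss <- function(transcripts) {
  str <- as.character(GenomicRanges::strand(transcripts))
  if (any(str == "*")) stop("transcripts must be stranded ('+' or '-')")
  ifelse(str == "+",
         GenomicRanges::start(transcripts),
         GenomicRanges::end(transcripts))
}
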