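## Per-position base classes of the p53 half-site consensus RRRCWWGYYY:
## positions 1-3 purine, 4 C, 5-6 A/T, 7 G, 8-10 pyrimidine.
RE_HALF_CLASSES <- list(
  c("A", "G"), c("A", "G"), c("A", "G"),
  "C",
  c("A", "T"), c("A", "T"),
  "G",
  c("C", "T"), c("C", "T"), c("C", "T"))

## Mismatch count of every 10-mer start position against the half-site
## consensus; N matches no class.
half_site_mismatches <- function(chars) {
  n <- length(chars)
  if (n < 10L) return(integer(0))
  m <- n - 9L
  mm <- integer(m)
  for (j in seq_len(10L))
    mm <- mm + as.integer(!chars[j:(j + m - 1L)] %in% RE_HALF_CLASSES[[j]])
  mm
}

#' Scan a sequence for p53 response-element dimers
#'
#' The p53 response element is two copies of the 10-mer half-site
#' RRRC(A/T)(T/A)GYYY separated by a 0-13 bp spacer. This scanner reports
#' every (position, spacer) placement whose two half-sites accumulate at
#' most `max_mismatch` class violations in total. The consensus class
#' pattern is its own reverse complement, so a forward-strand scan already
#' covers both strands: a minus-strand dimer corresponds to a plus-strand
#' placement at the same locus with the same mismatch count, and only the
#' canonical (forward) representative is reported.
#'
#' @param seq A DNA string of length >= 20.
#' @param max_spacer Maximum spacer length in bp (default 13).
#' @param max_mismatch Maximum total mismatches over both half-sites
#'   (default 3).
#' @return A data frame sorted by (start, spacer, mismatches) with 1-based
#'   inclusive coordinates: `start`, `end` (full dimer span, length
#'   `20 + spacer`), `spacer`, `mismatches`, `half1_start`, `half2_start`.
#' @examples
#' scan_re(strrep("GGGCATGCCC", 2), max_mismatch = 0)
#' @export
scan_re <- function(seq, max_spacer = 13L, max_mismatch = 3L) {
  if (max_spacer < 0) stop("'max_spacer' must be >= 0")
  if (max_mismatch < 0) stop("'max_mismatch' must be >= 0")
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 20L) stop("sequence must be at least 20 nt (two half-sites)")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hm <- half_site_mismatches(chars)
  res <- vector("list", max_spacer + 1L)
  for (sp in 0:max_spacer) {
    span <- 20L + sp
    if (n < span) break
    p <- seq_len(n - span + 1L)
    total <- hm[p] + hm[p + 10L + sp]
    sel <- which(total <= max_mismatch)
    if (length(sel))
      res[[sp + 1L]] <- data.frame(
        start = sel, end = sel + span - 1L, spacer = sp,
        mismatches = total[sel],
        half1_start = sel, half2_start = sel + 10L + sp)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      spacer = integer(0), mismatches = integer(0),
                      half1_start = integer(0), half2_start = integer(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$spacer, out$mismatches), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a genome for p53 response elements
#'
#' Applies [scan_re()] per contig and returns genomic intervals.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @inheritParams scan_re
#' @return A [GenomicRanges::GRanges] with metadata columns `spacer` and
#'   `mismatches`.
#' @export
scan_re_genome <- function(genome, max_spacer = 13L, max_mismatch = 3L) {
  g <- as_genome(genome)
  out <- lapply(names(g), function(nm) {
    if (nchar(g[[nm]]) < 20L) return(NULL)
    df <- scan_re(g[[nm]], max_spacer, max_mismatch)
    if (!nrow(df)) return(NULL)
    df$contig <- nm
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$spacer <- integer(0)
    S4Vectors::mcols(gr)$mismatches <- integer(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+")
  S4Vectors::mcols(gr)$spacer <- df$spacer
  S4Vectors::mcols(gr)$mismatches <- df$mismatches
  gr
}

#' Distance between a response element and a PQS
#'
#' The gap in bases between the nearer ends of two same-contig intervals;
#' intervals sharing at least one base return the string `"overlap"`. The
#' measure is symmetric in its arguments.
#'
#' @param a,b Length-1 [GenomicRanges::GRanges] on the same contig (e.g. an
#'   RE match and a PQS hit).
#' @return A non-negative integer gap, or the character string
#'   `"overlap"`.
#' @export
re_pqs_distance <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"),
            length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b)))
    stop("intervals lie on different contigs")
  gap <- max(GenomicRanges::start(a), GenomicRanges::start(b)) -
         min(GenomicRanges::end(a), GenomicRanges::end(b)) - 1L
  if (gap < 0L) "overlap" else as.integer(gap)
}
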