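#' Per-base G4Hunter scores
#'
#' Assigns every base of a DNA sequence its signed run score: bases inside
#' a maximal guanine homopolymer of length L score `+min(L, 4)`, bases in a
#' cytosine run `-min(L, 4)`, and A/T/N score 0. All bases of one run carry
#' the same value. N is neutral and breaks G/C runs.
#'
#' @param seq A single DNA string over `A/C/G/T/N` (case-insensitive).
#' @return Integer vector of per-base scores in `[-4, 4]`, one per base.
#' @examples
#' base_scores("CCGGGGG")  # -2 -2 4 4 4 4 4
#' @export
base_scores <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty DNA string")
  x <- utf8ToInt(toupper(seq))
  bad <- which(!x %in% c(65L, 67L, 71L, 84L, 78L))  # A C G T N
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d",
                 intToUtf8(x[bad[1L]]), bad[1L]))
  r <- rle(x)
  v <- integer(length(r$lengths))
  g <- r$values == 71L
  cc <- r$values == 67L
  v[g] <- pmin(r$lengths[g], 4L)
  v[cc] <- -pmin(r$lengths[cc], 4L)
  rep(v, r$lengths)
}

#' Whole-sequence G4Hunter score
#'
#' The arithmetic mean of [base_scores()] over the full sequence. Positive
#' values indicate G-quadruplex propensity on the given strand, negative
#' values on the complementary strand; the score is exactly antisymmetric
#' under reverse complementation.
#'
#' @inheritParams base_scores
#' @return A single numeric score in `[-4, 4]`.
#' @examples
#' g4hunter_score("AGGGAGGGGTGGGTGAGGC")    # 2.0
#' g4hunter_score("CGGGGCGGGGCGGGGCGGGGC")  # 2.81
#' @export
g4hunter_score <- function(seq) {
  mean(base_scores(seq))
}

#' Sliding-window G4Hunter scores
#'
#' Per-base scores are computed once on the full sequence (so homopolymer
#' runs are never truncated by window edges) and then averaged over every
#' window of the given width. Sequences shorter than the window yield the
#' single whole-sequence score.
#'
#' @inheritParams base_scores
#' @param window Window width in nucleotides (default 25, the G4Hunter
#'   default).
#' @return Numeric vector of `max(1, nchar(seq) - window + 1)` window means.
#' @export
window_scores <- function(seq, window = 25L) {
  if (length(window) != 1L || is.na(window) || window < 1 ||
      window != floor(window))
    stop("'window' must be a positive integer")
  b <- base_scores(seq)
  n <- length(b)
  if (n < window) return(mean(b))
  cs <- cumsum(c(0, b))
  (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
}

#' Call putative G-quadruplex sequences (PQS) in a genome
#'
#' The G4Hunter detection rule: slide a window along each contig, keep
#' windows whose absolute mean base score reaches the threshold, merge
#' maximal runs of consecutive qualifying windows into one region spanning
#' the first window's start to the last window's end, and report each
#' region with its score recomputed on the region's own sequence (run
#' lengths re-evaluated within the region, not inherited from any window).
#' Regions with a positive recomputed mean are G-rich hits on `+`; negative
#' means are C-rich hits reported on `-`. Contigs shorter than the window
#' are scored whole.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param threshold Minimum absolute window score (default 1.2, the
#'   G4Hunter default).
#' @param window Window width in nucleotides (default 25).
#' @return A [GenomicRanges::GRanges] of PQS hits sorted by contig then
#'   start, with metadata columns `score` (recomputed region mean) and
#'   `sequence` (the region's DNA).
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 50), "GGGTGGGTGGGTGGGTGGG", strrep("A", 50)))
#' find_pqs(g)
#' @export
find_pqs <- function(genome, threshold = 1.2, window = 25L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number")
  g <- as_genome(genome)
  lens <- nchar(g)
  out <- vector("list", length(g))
  for (i in seq_along(g)) {
    s <- g[[i]]
    n <- lens[[i]]
    w <- window_scores(s, window)
    eff_win <- min(window, n)            # short contigs scored whole
    qual <- abs(w) >= threshold
    if (!any(qual)) next
    r <- rle(qual)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    ii <- which(r$values)
    reg_start <- run_start[ii]                       # first window start
    reg_end <- run_end[ii] + eff_win - 1L            # last window end
    reg_seq <- substring(s, reg_start, reg_end)
    reg_score <- vapply(reg_seq, function(z) mean(base_scores(z)),
                        numeric(1), USE.NAMES = FALSE)
    strand <- ifelse(reg_score > 0, "+", ifelse(reg_score < 0, "-", "*"))
    out[[i]] <- data.frame(contig = names(g)[i], start = reg_start,
                           end = reg_end, score = reg_score,
                           sequence = reg_seq, strand = strand,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$sequence <- character(0)
    GenomeInfoDb::seqlevels(gr) <- names(g)
    GenomeInfoDb::seqlengths(gr) <- unname(lens)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$contig, levels = names(g)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    seqlengths = setNames(unname(lens), names(g)))
  S4Vectors::mcols(gr)$score <- df$score
  S4Vectors::mcols(gr)$sequence <- df$sequence
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Reverse complement of a DNA string
#'
#' @inheritParams base_scores
#' @return The reverse-complemented sequence (N maps to N).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
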