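#' Overlaps between PQS hits and a peak set
#'
#' Reports every (PQS, peak) pair on the same contig whose coordinate
#' intersection is at least `min_overlap` bases. Overlap is strand-blind
#' (G4s act in cis regardless of the strand they form on). Half-open
#' semantics of the underlying BED coordinates are preserved: intervals
#' that merely touch do not overlap.
#'
#' @param pqs A [GenomicRanges::GRanges] of PQS hits (e.g. from
#'   [find_pqs()]).
#' @param peaks A [GenomicRanges::GRanges] of binding-site peaks.
#' @param min_overlap Minimum intersection length in bp (default 1).
#' @return A data frame with one row per overlapping pair, sorted by
#'   contig, PQS start, peak start: columns `contig`, `pqs_start`,
#'   `pqs_end`, `pqs_strand`, `pqs_score`, `peak_start`, `peak_end`,
#'   `overlap_bp`, `pqs_idx`, `peak_idx` (indices into the inputs).
#' @export
pqs_peak_overlaps <- function(pqs, peaks, min_overlap = 1L) {
  stopifnot(methods::is(pqs, "GRanges"), methods::is(peaks, "GRanges"))
  if (min_overlap < 1L) stop("'min_overlap' must be >= 1")
  h <- GenomicRanges::findOverlaps(pqs, peaks, minoverlap = min_overlap,
                                   ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  ov <- pmin(GenomicRanges::end(pqs)[qi], GenomicRanges::end(peaks)[si]) -
        pmax(GenomicRanges::start(pqs)[qi], GenomicRanges::start(peaks)[si]) + 1L
  sc <- S4Vectors::mcols(pqs)$score
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(pqs))[qi],
    pqs_start = GenomicRanges::start(pqs)[qi],
    pqs_end = GenomicRanges::end(pqs)[qi],
    pqs_strand = as.character(GenomicRanges::strand(pqs))[qi],
    pqs_score = if (is.null(sc)) NA_real_ else sc[qi],
    peak_start = GenomicRanges::start(peaks)[si],
    peak_end = GenomicRanges::end(peaks)[si],
    overlap_bp = as.integer(ov),
    pqs_idx = qi,
    peak_idx = si,
    stringsAsFactors = FALSE)
  df[order(df$contig, df$pqs_start, df$peak_start), , drop = FALSE]
}

#' Peak-set algebra: subtraction and intersection of binding-site sets
#'
#' Whole-interval semantics, matching how control binding sites are removed
#' from a ChIP-seq peak list: `subtract` keeps the peaks of `a` that share
#' no base with any peak of `b`; `common` keeps the peaks of `a` that share
#' at least one base with some peak of `b`. Peaks are never clipped. The
#' two results partition `a`.
#'
#' @param a,b [GenomicRanges::GRanges] peak sets.
#' @param op `"subtract"` or `"common"`.
#' @return The selected subset of `a`.
#' @export
peakset_algebra <- function(a, b, op = c("subtract", "common")) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  op <- match.arg(op)
  hit <- IRanges::overlapsAny(a, b, ignore.strand = TRUE)
  if (op == "subtract") a[!hit] else a[hit]
}

#' Annotate PQS-bearing targets with overlapping transcripts
#'
#' Assigns every target interval (typically the peaks that carry a PQS) to
#' each transcript it overlaps; one target overlapping several transcripts
#' counts once per transcript. By default the assignment is strand-agnostic
#' (peaks are unstranded); `strict_strand = TRUE` requires matching
#' strands. Targets overlapping no transcript are tallied separately as
#' unannotated and excluded from percentage denominators.
#'
#' @param targets A [GenomicRanges::GRanges] of intervals to annotate.
#' @param transcripts A stranded [GenomicRanges::GRanges] with metadata
#'   columns `gene_id` and `biotype`.
#' @param strict_strand Require target strand to equal transcript strand.
#' @return A data frame `(gene_id, biotype, count)` for every transcript
#'   overlapped by at least one target, with attribute `n_unannotated`
#'   giving the number of targets that touched no transcript.
#' @export
annotate_targets <- function(targets, transcripts, strict_strand = FALSE) {
  stopifnot(methods::is(targets, "GRanges"), methods::is(transcripts, "GRanges"))
  if (any(GenomicRanges::strand(transcripts) == "*"))
    stop("transcripts must be stranded ('+' or '-')")
  h <- GenomicRanges::findOverlaps(targets, transcripts,
                                   ignore.strand = !strict_strand)
  si <- S4Vectors::subjectHits(h)
  cnt <- tabulate(si, nbins = length(transcripts))
  keep <- which(cnt > 0L)
  out <- data.frame(
    gene_id = S4Vectors::mcols(transcripts)$gene_id[keep],
    biotype = S4Vectors::mcols(transcripts)$biotype[keep],
    count = cnt[keep],
    stringsAsFactors = FALSE)
  attr(out, "n_unannotated") <-
    length(targets) - length(unique(S4Vectors::queryHits(h)))
  out
}

#' Biotype composition of annotated targets
#'
#' Collapses an [annotate_targets()] table to per-biotype assignment counts
#' and percentages. Percentages are taken over annotated assignments only
#' (unannotated targets are outside the denominator) and sum to 100.
#'
#' @param annotation A data frame from [annotate_targets()].
#' @return A data frame `(biotype, count, percent)` sorted by decreasing
#'   count.
#' @export
biotype_summary <- function(annotation) {
  stopifnot(all(c("biotype", "count") %in% names(annotation)))
  agg <- aggregate(count ~ biotype, data = annotation, FUN = sum)
  agg$percent <- 100 * agg$count / sum(agg$count)
  agg[order(-agg$count), , drop = FALSE]
}

#' Promoter windows around transcription start sites
#'
#' Builds the strand-aware promoter window `[-upstream, +downstream)`
#' around each TSS: on `+`, the window runs from `upstream` bases before
#' the TSS to `downstream` bases into the transcript; on `-` the window is
#' the mirror image. Windows are clipped at contig bounds when contig
#' lengths are known (from the transcripts' seqinfo or a supplied genome);
#' unclipped windows have length `upstream + downstream`.
#'
#' @param transcripts A stranded [GenomicRanges::GRanges].
#' @param upstream,downstream Non-negative window extents in bp (defaults
#'   1000 and 100).
#' @param genome Optional genome ([Biostrings::DNAStringSet] or named
#'   character vector) supplying contig lengths for clipping.
#' @return A [GenomicRanges::GRanges] of promoter windows carrying the
#'   transcripts' metadata columns.
#' @export
promoter_windows <- function(transcripts, upstream = 1000L, downstream = 100L,
                             genome = NULL) {
  stopifnot(methods::is(transcripts, "GRanges"))
  if (any(GenomicRanges::strand(transcripts) == "*"))
    stop("transcripts must be stranded ('+' or '-')")
  if (upstream < 0 || downstream < 0)
    stop("'upstream' and 'downstream' must be >= 0")
  # out-of-bound windows are expected near contig edges; they are clipped
  prom <- suppressWarnings(
    GenomicRanges::promoters(transcripts, upstream = upstream,
                             downstream = downstream))
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    suppressWarnings({
      GenomeInfoDb::seqlevels(prom) <- names(lens)
      GenomeInfoDb::seqlengths(prom) <- unname(lens)
    })
  }
  GenomicRanges::trim(prom)
}

#' PQS frequency of a peak set
#'
#' The number of distinct PQS hits overlapping at least one peak, per
#' kilobase of total peak length. A PQS overlapping several peaks counts
#' once. An empty peak set has frequency 0 by convention (the behaviour of
#' a knockout control with no binding sites).
#'
#' @inheritParams pqs_peak_overlaps
#' @return A single numeric frequency (overlapping PQS per kb of peaks).
#' @export
pqs_frequency <- function(pqs, peaks) {
  stopifnot(methods::is(pqs, "GRanges"), methods::is(peaks, "GRanges"))
  if (length(peaks) == 0L) return(0)
  n <- sum(IRanges::overlapsAny(pqs, peaks, ignore.strand = TRUE))
  n / (sum(GenomicRanges::width(peaks)) / 1000)
}
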