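# Seeded random-input generators shared across tests.

rand_seq <- function(n, gc = 0.5, with_n = FALSE) {
  alpha <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (with_n) {
    alpha <- c(alpha, "N")
    p <- c(p * 0.95, 0.05)
  }
  paste(sample(alpha, n, replace = TRUE, prob = p), collapse = "")
}

rand_intervals <- function(n, contigs = c("c1", "c2"), max_pos = 10000L,
                           max_len = 200L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  GenomicRanges::GRanges(
    sample(contigs, n, replace = TRUE),
    IRanges::IRanges(start, start + sample.int(max_len, n, replace = TRUE)))
}

granges_to_df <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

make_transcript_gr <- function(contig, start, end, strand, gene_id = NULL,
                               biotype = "protein_coding") {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <-
    if (is.null(gene_id)) sprintf("g%03d", seq_along(gr)) else gene_id
  S4Vectors::mcols(gr)$biotype <- rep_len(biotype, length(gr))
  gr
}
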