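test_that("generators are pure functions of the spec (seed determinism)", {
  spec <- synthetic_spec(seed = 14, contig_lengths = c(chrA = 12000L),
                        n_planted_pqs = 8L, n_peaks = 12L, n_transcripts = 6L)
  a <- make_genome(spec)
  b <- make_genome(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as_bed_frame(a$manifest), as_bed_frame(b$manifest))
  expect_identical(as_bed_frame(make_peaks(a$genome, a$manifest, spec)),
                   as_bed_frame(make_peaks(b$genome, b$manifest, spec)))
  expect_identical(make_reporter_table(spec), make_reporter_table(spec))
  expect_identical(as_bed_frame(make_transcripts(a$genome, spec)),
                   as_bed_frame(make_transcripts(b$genome, spec)))
})

test_that("planted motifs are recovered by detection and recorded faithfully", {
  spec <- synthetic_spec(seed = 3, contig_lengths = c(chrA = 20000L),
                        n_planted_pqs = 10L, n_peaks = 10L)
  gm <- make_genome(spec)
  expect_length(gm$manifest, 10L)
  # manifest sequences really are the motif (or its reverse complement)
  g1 <- as.character(gm$genome[[1]])
  for (i in seq_along(gm$manifest)) {
    s <- substr(g1, GenomicRanges::start(gm$manifest)[i],
                GenomicRanges::end(gm$manifest)[i])
    expected <- if (as.character(GenomicRanges::strand(gm$manifest)[i]) == "+")
      spec$planted_motif else revcomp(spec$planted_motif)
    expect_identical(s, expected)
  }
  hits <- find_pqs(gm$genome)
  expect_gte(length(hits), 10L)
  expect_true(all(IRanges::overlapsAny(gm$manifest, hits,
                                       ignore.strand = TRUE)))
})

test_that("background PQS calls are sparse and increase with GC content", {
  density_at <- function(gc) {
    mean(vapply(1:10, function(s) {
      spec <- synthetic_spec(seed = 3000 + s,
                            contig_lengths = c(chrA = 10000L),
                            gc_content = gc, n_planted_pqs = 0L,
                            enrichment_rho = 0)
      length(find_pqs(make_genome(spec)$genome))
    }, numeric(1)))
  }
  bg41 <- density_at(0.41)
  bg50 <- density_at(0.50)
  # sparse relative to the ~10,000 windows scanned, but nonzero
  expect_lt(bg50, 30)
  expect_gt(bg50, 0)
  # monotone in GC: richer G/C backgrounds yield more chance calls
  expect_lt(bg41, bg50)
})

test_that("peak placement honors the enrichment fraction", {
  spec1 <- synthetic_spec(seed = 21, contig_lengths = c(chrA = 30000L),
                         n_planted_pqs = 20L, n_peaks = 20L,
                         enrichment_rho = 1)
  gm <- make_genome(spec1)
  pk <- make_peaks(gm$genome, gm$manifest, spec1)
  expect_true(all(IRanges::overlapsAny(pk, gm$manifest, ignore.strand = TRUE)))
  expect_true(all(S4Vectors::mcols(pk)$on_pqs))

  # rho = 0 places every peak away from the planted manifest
  spec0 <- synthetic_spec(seed = 21, contig_lengths = c(chrA = 30000L),
                         n_planted_pqs = 20L, n_peaks = 20L,
                         enrichment_rho = 0)
  pk0 <- make_peaks(gm$genome, gm$manifest, spec0)
  expect_false(any(IRanges::overlapsAny(pk0, gm$manifest,
                                        ignore.strand = TRUE)))
  expect_length(pk0, 20L)
})

test_that("PQS frequency rises with the planted enrichment fraction", {
  freq_at <- function(rho) {
    spec <- synthetic_spec(seed = 37, contig_lengths = c(chrA = 30000L),
                          n_planted_pqs = 25L, n_peaks = 30L,
                          enrichment_rho = rho)
    gm <- make_genome(spec)
    pk <- make_peaks(gm$genome, gm$manifest, spec)
    pqs_frequency(find_pqs(gm$genome), pk)
  }
  expect_gt(freq_at(0.8), freq_at(0.2))
})

test_that("transcript generation respects strands, placement and biotype weights", {
  spec <- synthetic_spec(seed = 8, contig_lengths = c(chrA = 50000L),
                        n_transcripts = 15L)
  gm <- make_genome(spec)
  tr <- make_transcripts(gm$genome, spec)
  expect_length(tr, 15L)
  expect_true(all(as.character(GenomicRanges::strand(tr)) %in% c("+", "-")))
  # non-overlapping by construction
  expect_equal(sum(GenomicRanges::countOverlaps(tr, tr)), 15L)
  # TSS invariant holds for every record
  str <- as.character(GenomicRanges::strand(tr))
  expect_identical(tss(tr), ifelse(str == "+", GenomicRanges::start(tr),
                                   GenomicRanges::end(tr)))

  # single-biotype weights produce a single biotype
  spec_pc <- synthetic_spec(seed = 8, contig_lengths = c(chrA = 50000L),
                           n_transcripts = 10L,
                           biotype_weights = c(protein_coding = 1))
  tr_pc <- make_transcripts(gm$genome, spec_pc)
  expect_true(all(S4Vectors::mcols(tr_pc)$biotype == "protein_coding"))

  # biotype proportions track the weights at large n (3 SE)
  spec_big <- synthetic_spec(seed = 9, contig_lengths = c(chrA = 4000000L),
                            n_transcripts = 1000L)
  big_genome <- c(chrA = strrep("A", 4000000L))
  tr_big <- make_transcripts(big_genome, spec_big)
  props <- table(S4Vectors::mcols(tr_big)$biotype) / 1000
  for (bt in names(spec_big$biotype_weights)) {
    w <- spec_big$biotype_weights[[bt]]
    expect_lt(abs(props[[bt]] - w), 3 * sqrt(w * (1 - w) / 1000))
  }
})

test_that("reporter tables carry the planted effects and optional outliers", {
  # all true folds 1: fold-of-empty near 1 in every cell
  flat <- default_assay_effects()
  flat$fold <- 1
  spec <- synthetic_spec(seed = 55, assay_effects = flat,
                        galactose = 1, time_h = 6)
  fo <- fold_of_empty(make_reporter_table(spec))
  expect_true(all(abs(fo$fold - 1) < 0.35))
  expect_equal(mean(fo$fold), 1, tolerance = 0.1)

  # at least five replicates per cell in the default design
  tab <- make_reporter_table(synthetic_spec(seed = 56))
  cells <- table(tab$strain, tab$protein, tab$galactose, tab$time_h)
  expect_true(all(cells >= 5))

  # planted 10x outliers are flagged and removed by the fence
  spec_out <- synthetic_spec(seed = 57, outlier_rate = 0.05,
                            outlier_factor = 10)
  tab_out <- make_reporter_table(spec_out)
  expect_gt(sum(tab_out$outlier), 0)
  removed <- 0L
  pools <- split(tab_out, paste(tab_out$strain, tab_out$protein,
                                tab_out$galactose, tab_out$time_h))
  n_pools <- 0L
  for (p in pools) {
    out_rows <- which(p$outlier)
    if (length(out_rows) != 1L) next  # a single planted gross outlier
    n_pools <- n_pools + 1L
    kept <- iqr_filter(p$luminescence / p$od600)
    if (!any((p$luminescence / p$od600)[out_rows] %in% kept))
      removed <- removed + 1L
  }
  expect_gte(removed / n_pools, 0.99)
})
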