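#' Specification for a synthetic study dataset
#'
#' Bundles every tunable of the synthetic-data generators with validated
#' defaults chosen to emulate the shape of a real ChIP-seq/PQS study at
#' desk scale: a 200 kb three-contig genome at human-like 41% GC, planted
#' G3N1 tracts at roughly the PQS density of the human genome under
#' default G4Hunter parameters, ChIP-seq-scale peaks (250 bp), and a yeast
#' reporter design with four strains, two p53 proteins plus empty vector,
#' two galactose doses, and two time points with at least five replicates
#' per cell. All generators are pure functions of this spec: the same spec
#' reproduces byte-identical data.
#'
#' @param seed Master integer seed; the generators derive fixed offsets
#'   from it.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gc_content Background GC fraction in (0, 1).
#' @param n_planted_pqs Number of planted PQS motifs.
#' @param planted_motif Motif to plant; its whole-sequence G4Hunter score
#'   must exceed `threshold`.
#' @param threshold Detection threshold the planted motif must clear
#'   (default 1.2).
#' @param n_peaks,peak_length Number and fixed width (bp) of peaks.
#' @param enrichment_rho Fraction of peaks centered on planted PQS, in
#'   `[0, 1]`; the rest are placed uniformly away from the manifest.
#' @param n_transcripts Number of non-overlapping transcripts.
#' @param biotype_weights Named sampling weights over biotypes.
#' @param assay_effects Data frame `(strain, protein, fold)` of true fold
#'   inductions; the empty-vector baseline (fold 1) is implicit.
#' @param noise_cv Lognormal coefficient of variation of luminescence
#'   noise.
#' @param n_replicates Replicates per reporter cell (default 6).
#' @param galactose,time_h Factor levels of the reporter design.
#' @param baseline Baseline RLU of the empty vector.
#' @param od_range OD600 sampling band.
#' @param outlier_rate,outlier_factor Optional planted gross outliers in
#'   the luminescence channel (default none).
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           contig_lengths = c(chrA = 100000L, chrB = 60000L,
                                              chrC = 40000L),
                           gc_content = 0.41,
                           n_planted_pqs = 100L,
                           planted_motif = "GGGTGGGTGGGTGGGTGGG",
                           threshold = 1.2,
                           n_peaks = 150L,
                           peak_length = 250L,
                           enrichment_rho = 0.5,
                           n_transcripts = 40L,
                           biotype_weights = c(protein_coding = 0.40,
                                               lncRNA = 0.35,
                                               pseudogene = 0.15,
                                               miRNA = 0.05,
                                               other = 0.05),
                           assay_effects = default_assay_effects(),
                           noise_cv = 0.15,
                           n_replicates = 6L,
                           galactose = c(0.016, 1.0),
                           time_h = c(6, 24),
                           baseline = 1000,
                           od_range = c(0.3, 1.2),
                           outlier_rate = 0,
                           outlier_factor = 10) {
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
  if (enrichment_rho < 0 || enrichment_rho > 1)
    stop("enrichment_rho must be in [0, 1]")
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  if (n_planted_pqs > 0 && g4hunter_score(planted_motif) <= threshold)
    stop("planted motif score must exceed the detection threshold")
  if (!all(c("strain", "protein", "fold") %in% names(assay_effects)))
    stop("assay_effects needs columns strain, protein, fold")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(seed = as.integer(seed),
                 contig_lengths = contig_lengths, gc_content = gc_content,
                 n_planted_pqs = as.integer(n_planted_pqs),
                 planted_motif = toupper(planted_motif),
                 threshold = threshold,
                 n_peaks = as.integer(n_peaks),
                 peak_length = as.integer(peak_length),
                 enrichment_rho = enrichment_rho,
                 n_transcripts = as.integer(n_transcripts),
                 biotype_weights = biotype_weights,
                 assay_effects = assay_effects, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 galactose = galactose, time_h = time_h, baseline = baseline,
                 od_range = od_range, outlier_rate = outlier_rate,
                 outlier_factor = outlier_factor),
            class = "synthetic_spec")
}

#' Default reporter-assay true effects
#'
#' A qualitative emulation of the p53 transactivation pattern: wild-type
#' p53 activates every RE-bearing strain, constructs carrying the native
#' RE+PQS arrangement respond more strongly, and the R282W mutant is a
#' weak activator throughout.
#'
#' @return Data frame `(strain, protein, fold)`.
#' @export
default_assay_effects <- function() {
  data.frame(
    strain = rep(c("BBC3_RE", "BBC3", "MDM2_RE", "MDM2"), each = 2L),
    protein = rep(c("WT", "R282W"), times = 4L),
    fold = c(3.0, 1.2, 4.5, 1.5, 2.5, 1.1, 3.5, 1.3),
    stringsAsFactors = FALSE)
}

#' Generate a background genome with planted PQS
#'
#' Background bases are i.i.d. with the requested GC content (order-0), so
#' an order-1 Markov fit models the background faithfully while remaining
#' blind to planted motifs — randomization therefore erases the planted
#' signal, giving a provable enrichment contrast. Motifs are planted
#' non-overlapping at uniformly drawn positions, each on a random strand
#' (reverse complement for minus), and recorded in a ground-truth
#' manifest.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genome` ([Biostrings::DNAStringSet]) and `manifest`
#'   (stranded [GenomicRanges::GRanges] of planted motif positions).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
         spec$gc_content / 2, (1 - spec$gc_content) / 2)
  mlen <- nchar(spec$planted_motif)
  n_per <- round_allocate(spec$n_planted_pqs, spec$contig_lengths)
  seqs <- character(length(spec$contig_lengths))
  man <- list()
  for (i in seq_along(spec$contig_lengths)) {
    len <- spec$contig_lengths[[i]]
    chars <- sample(BASES, len, replace = TRUE, prob = p)
    k <- n_per[i]
    if (k > 0) {
      if (len < mlen) stop("contig too short for the planted motif")
      starts <- place_nonoverlapping(k, len, mlen)
      strands <- sample(c("+", "-"), k, replace = TRUE)
      for (j in seq_len(k)) {
        m <- if (strands[j] == "+") spec$planted_motif else revcomp(spec$planted_motif)
        chars[starts[j]:(starts[j] + mlen - 1L)] <- strsplit(m, "")[[1L]]
      }
      man[[i]] <- data.frame(contig = names(spec$contig_lengths)[i],
                             start = starts, end = starts + mlen - 1L,
                             strand = strands)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  names(seqs) <- names(spec$contig_lengths)
  genome <- Biostrings::DNAStringSet(seqs)
  man <- man[!vapply(man, is.null, logical(1))]
  if (length(man)) {
    df <- do.call(rbind, man)
    manifest <- GenomicRanges::GRanges(
      seqnames = factor(df$contig, levels = names(spec$contig_lengths)),
      ranges = IRanges::IRanges(df$start, df$end), strand = df$strand,
      seqlengths = setNames(as.integer(spec$contig_lengths),
                            names(spec$contig_lengths)))
    manifest <- GenomicRanges::sort(manifest, ignore.strand = TRUE)
  } else {
    manifest <- GenomicRanges::GRanges(
      seqlengths = setNames(as.integer(spec$contig_lengths),
                            names(spec$contig_lengths)))
  }
  list(genome = genome, manifest = manifest)
}

## Largest-remainder allocation of n items proportional to weights.
round_allocate <- function(n, weights) {
  w <- weights / sum(weights)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

## Uniform non-overlapping placement by rejection; errors out when the
## motifs cannot be placed (density too high).
place_nonoverlapping <- function(k, len, mlen, max_tries = NULL) {
  if (is.null(max_tries)) max_tries <- 200L * k + 1000L
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < k) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", k, " non-overlapping motifs in ", len, " bp")
    cand <- sample.int(len - mlen + 1L, 1L)
    if (!any(cand <= starts + mlen - 1L & cand + mlen - 1L >= starts))
      starts <- c(starts, cand)
  }
  sort(starts)
}

#' Generate a peak set with tunable PQS enrichment
#'
#' `ceiling(rho * n_peaks)` peaks are centered on planted PQS sampled from
#' the manifest (without replacement while possible, with replacement —
#' and a message — when `rho * n_peaks` exceeds the number of planted
#' motifs); the remaining peaks are placed uniformly, rejecting positions
#' that touch the manifest, so `rho = 0` yields only chance-level overlap.
#' Peaks have a fixed width and are clamped inside contig bounds.
#'
#' @param genome A genome ([Biostrings::DNAStringSet] or named character
#'   vector) providing contig lengths.
#' @param manifest Planted-PQS manifest from [make_genome()].
#' @param spec A [synthetic_spec()].
#' @return A [GenomicRanges::GRanges] of `n_peaks` peaks with metadata
#'   column `on_pqs` (logical ground truth).
#' @export
make_peaks <- function(genome, manifest, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  lens <- contig_lengths(genome)
  L <- spec$peak_length
  if (any(lens < L)) stop("contig shorter than the peak length")
  n_on <- ceiling(spec$enrichment_rho * spec$n_peaks)
  n_off <- spec$n_peaks - n_on
  rows <- list()
  if (n_on > 0) {
    if (length(manifest) == 0L)
      stop("enrichment_rho > 0 requires a non-empty manifest")
    replace <- n_on > length(manifest)
    if (replace)
      message("sampling planted PQS with replacement (", n_on, " > ",
              length(manifest), ")")
    pick <- sample.int(length(manifest), n_on, replace = replace)
    centers <- (GenomicRanges::start(manifest)[pick] +
                GenomicRanges::end(manifest)[pick]) %/% 2L
    ctg <- as.character(GenomicRanges::seqnames(manifest))[pick]
    start <- centers - L %/% 2L
    start <- pmax(1L, pmin(start, lens[ctg] - L + 1L))
    rows$on <- data.frame(contig = ctg, start = start, on_pqs = TRUE)
  }
  if (n_off > 0) {
    # vectorized rejection sampling: redraw candidates touching the manifest
    ctg <- character(0)
    start <- integer(0)
    need <- n_off
    for (round in seq_len(100L)) {
      c_ctg <- sample(names(lens), need, replace = TRUE,
                      prob = lens / sum(lens))
      c_start <- vapply(c_ctg, function(cc)
        sample.int(lens[[cc]] - L + 1L, 1L), integer(1), USE.NAMES = FALSE)
      cand_gr <- GenomicRanges::GRanges(c_ctg,
                                        IRanges::IRanges(c_start, width = L))
      ok <- !IRanges::overlapsAny(cand_gr, manifest, ignore.strand = TRUE)
      ctg <- c(ctg, c_ctg[ok])
      start <- c(start, c_start[ok])
      need <- n_off - length(ctg)
      if (need == 0L) break
    }
    if (need > 0L) stop("could not place off-manifest peaks")
    rows$off <- data.frame(contig = ctg, start = start, on_pqs = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$contig, levels = names(lens)),
    ranges = IRanges::IRanges(df$start, width = L),
    seqlengths = setNames(unname(lens), names(lens)))
  S4Vectors::mcols(gr)$name <- sprintf("peak_%04d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- 0
  S4Vectors::mcols(gr)$on_pqs <- df$on_pqs
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Generate stranded transcript annotations
#'
#' Non-overlapping transcripts with lengths drawn in 500-3000 bp, strands
#' chosen at random, and biotypes sampled by weight. The TSS invariant
#' (interval start on `+`, interval end on `-`) holds by construction.
#'
#' @inheritParams make_peaks
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id` and
#'   `biotype`.
#' @export
make_transcripts <- function(genome, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  lens <- contig_lengths(genome)
  n <- spec$n_transcripts
  placed <- GenomicRanges::GRanges(seqlengths = setNames(unname(lens), names(lens)))
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      tlen <- sample(500:3000, 1L)
      ctg <- sample(names(lens), 1L, prob = lens / sum(lens))
      if (lens[[ctg]] < tlen) next
      st <- sample.int(lens[[ctg]] - tlen + 1L, 1L)
      cand <- GenomicRanges::GRanges(ctg, IRanges::IRanges(st, st + tlen - 1L))
      if (!any(IRanges::overlapsAny(cand, placed))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping transcripts")
    GenomicRanges::strand(cand) <- sample(c("+", "-"), 1L)
    placed <- c(placed, cand)
    rows[[j]] <- cand
  }
  gr <- do.call(c, rows)
  S4Vectors::mcols(gr)$gene_id <- sprintf("gene_%03d", seq_len(n))
  S4Vectors::mcols(gr)$biotype <- sample(names(spec$biotype_weights), n,
                                         replace = TRUE,
                                         prob = spec$biotype_weights)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Generate a reporter measurement table with planted effects
#'
#' One row per well over the full strain x protein x galactose x time x
#' replicate grid (proteins are those in the spec's effects plus the
#' `empty` baseline at true fold 1). Luminescence is
#' `baseline * true_fold * lognormal(0, cv) * od600`, OD600 uniform in the
#' spec's band, so RLU recovers `baseline * true_fold * noise`. Optional
#' gross outliers multiply luminescence by `outlier_factor`.
#'
#' @param spec A [synthetic_spec()].
#' @return A measurement data frame (see [read_reporter_table()]) with a
#'   ground-truth column `true_fold` and logical `outlier`.
#' @export
make_reporter_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  eff <- spec$assay_effects
  strains <- unique(eff$strain)
  proteins <- c(unique(eff$protein), "empty")
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      time_h = spec$time_h, galactose = spec$galactose,
                      protein = proteins, strain = strains,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("strain", "protein", "galactose", "time_h", "replicate")]
  key <- paste(grid$strain, grid$protein)
  ekey <- paste(eff$strain, eff$protein)
  grid$true_fold <- ifelse(grid$protein == "empty", 1,
                           eff$fold[match(key, ekey)])
  if (anyNA(grid$true_fold)) stop("assay_effects is missing a strain/protein cell")
  m <- nrow(grid)
  grid$od600 <- runif(m, spec$od_range[1L], spec$od_range[2L])
  noise <- rlnorm(m, meanlog = 0, sdlog = spec$noise_cv)
  grid$outlier <- runif(m) < spec$outlier_rate
  grid$luminescence <- spec$baseline * grid$true_fold * noise * grid$od600 *
    ifelse(grid$outlier, spec$outlier_factor, 1)
  grid
}
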