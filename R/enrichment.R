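#' Null PQS frequencies from randomized genomes
#'
#' Runs the detection and frequency stages against each randomized genome
#' using the *same* peak coordinates as the observed analysis: one PQS
#' frequency per replicate. Peak coordinates must fit inside every
#' randomized contig (the replicates are length-matched to the original
#' genome, so a violation indicates mismatched inputs).
#'
#' @param peaks A [GenomicRanges::GRanges] peak set.
#' @param randomized A list of randomized genomes (e.g. from
#'   [randomize_replicates()]); at least two.
#' @param threshold,window G4Hunter detection parameters passed to
#'   [find_pqs()].
#' @return Numeric vector with one null frequency per replicate.
#' @export
null_frequencies <- function(peaks, randomized, threshold = 1.2, window = 25L) {
  stopifnot(methods::is(peaks, "GRanges"))
  if (length(randomized) < 2L)
    stop("at least 2 randomized replicates are required")
  vapply(randomized, function(g) {
    lens <- contig_lengths(g)
    pk_contig <- as.character(GenomicRanges::seqnames(peaks))
    if (any(!pk_contig %in% names(lens)))
      stop("peak contig absent from randomized genome: ",
           setdiff(pk_contig, names(lens))[1L])
    if (any(GenomicRanges::end(peaks) > lens[pk_contig]))
      stop("peak coordinates exceed randomized contig length ",
           "(replicates must be length-matched)")
    pqs_frequency(find_pqs(g, threshold = threshold, window = window), peaks)
  }, numeric(1))
}

#' Test an observed PQS frequency against null replicates
#'
#' The default test is a two-sided one-sample t-test of the null replicate
#' frequencies against the observed frequency taken as a fixed reference:
#' `t = (mean(null) - observed) / (sd(null) / sqrt(n))` with `n - 1`
#' degrees of freedom. This mirrors plotting replicate means with standard
#' deviations against a single observed value; because the observed
#' frequency is itself an estimate, the test is anti-conservative if the
#' observed value is exchangeable with the replicates (see the methods
#' vignette). `method = "prediction"` widens the denominator to
#' `sd * sqrt(1 + 1/n)` (a prediction-interval test), which calibrates the
#' type-I error under exchangeability. If the null replicates have zero
#' spread the test degenerates: p = 1 when the observed value equals the
#' common null value, p = 0 otherwise.
#'
#' Significance tiers follow the conventional star thresholds: `****`
#' (p <= 1e-4), `***` (p <= 1e-3), `**` (p <= 0.01, emitted for
#' completeness), `*` (p <= 0.05), otherwise `ns`.
#'
#' @param observed Observed PQS frequency (single number).
#' @param null_values Numeric vector of at least two null frequencies.
#' @param label Optional label for the peak set.
#' @param method `"t"` (default, fixed-reference one-sample t-test) or
#'   `"prediction"`.
#' @return An object of class `enrichment_result`: list with `label`,
#'   `observed`, `null_values`, `null_mean`, `null_sd`, `t_statistic`,
#'   `p_value`, `tier`.
#' @export
enrichment_test <- function(observed, null_values, label = NA_character_,
                            method = c("t", "prediction")) {
  method <- match.arg(method)
  if (length(null_values) < 2L)
    stop("at least 2 null replicate values are required")
  stopifnot(is.numeric(observed), length(observed) == 1L)
  n <- length(null_values)
  m <- mean(null_values)
  s <- sd(null_values)
  if (s == 0) {
    p <- if (observed == null_values[1L]) 1 else 0
    t_stat <- NA_real_
  } else {
    denom <- if (method == "t") s / sqrt(n) else s * sqrt(1 + 1 / n)
    t_stat <- (m - observed) / denom
    p <- 2 * pt(-abs(t_stat), df = n - 1L)
  }
  structure(list(label = label, observed = observed,
                 null_values = null_values, null_mean = m, null_sd = s,
                 t_statistic = t_stat, p_value = p,
                 tier = significance_tier(p)),
            class = "enrichment_result")
}

significance_tier <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.enrichment_result <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("PQS enrichment%s\n", lab))
  cat(sprintf("  observed frequency: %.4f PQS/kb\n", x$observed))
  cat(sprintf("  null (n = %d):      %.4f +/- %.4f PQS/kb\n",
              length(x$null_values), x$null_mean, x$null_sd))
  tt <- if (is.na(x$t_statistic)) "degenerate (zero null spread)"
        else sprintf("t = %.3f", x$t_statistic)
  cat(sprintf("  %s, p = %.4g  %s\n", tt, x$p_value, x$tier))
  invisible(x)
}

#' End-to-end PQS enrichment analysis of a peak set
#'
#' The full pipeline: call PQS on the genome, compute the observed
#' frequency over the peak set, randomize the genome (Markov model of the
#' given order, `replicates` length-matched samples), recompute the
#' frequency in each randomized genome against the same peak coordinates,
#' and test observed vs null.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param peaks A [GenomicRanges::GRanges] peak set.
#' @param threshold,window G4Hunter parameters (defaults 1.2 and 25).
#' @param order Markov order of the null (default 1).
#' @param replicates Number of randomized genomes (default 5, the study
#'   design).
#' @param seed Integer seed of the first replicate.
#' @param label Optional peak-set label.
#' @param method Test variant, see [enrichment_test()].
#' @return An `enrichment_result`.
#' @export
pqs_enrichment <- function(genome, peaks, threshold = 1.2, window = 25L,
                           order = 1L, replicates = 5L, seed = 1L,
                           label = NA_character_, method = c("t", "prediction")) {
  method <- match.arg(method)
  pqs <- find_pqs(genome, threshold = threshold, window = window)
  observed <- pqs_frequency(pqs, peaks)
  rand <- randomize_replicates(genome, order = order, n = replicates,
                               base_seed = seed)
  nv <- null_frequencies(peaks, rand, threshold = threshold, window = window)
  enrichment_test(observed, nv, label = label, method = method)
}
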