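BASES <- c("A", "C", "G", "T")

## Integer codes A=0 C=1 G=2 T=3, N and anything else -> NA.
encode_bases <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(x))
  code[x == 65L] <- 0L
  code[x == 67L] <- 1L
  code[x == 71L] <- 2L
  code[x == 84L] <- 3L
  code
}

## Context labels in code order (first base is the most significant digit).
kmer_names <- function(k) {
  vapply(0:(4L^k - 1L), function(code) {
    paste(BASES[(code %/% 4L^((k - 1L):0L)) %% 4L + 1L], collapse = "")
  }, character(1))
}

#' Fit a nucleotide Markov model to a genome
#'
#' Counts every (k-mer context, next base) transition, pooled over contigs.
#' Windows containing N are skipped; the initial distribution is the
#' empirical frequency of contexts in the genome. With `order = 1` this is
#' the base-to-base transition structure used to build randomized genomes
#' of matched composition.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param order Markov order (context length), a positive integer
#'   (default 1).
#' @return An object of class `markov_model`: list with `order`, `counts`
#'   (4^order x 4 matrix of transition counts, rows named by context),
#'   `trans_probs` (row-normalized counts; rows with no observations are
#'   `NA`), and `initial` (probability vector over contexts).
#' @export
fit_markov <- function(genome, order = 1L) {
  if (length(order) != 1L || is.na(order) || order < 1 || order != floor(order))
    stop("'order' must be a positive integer")
  order <- as.integer(order)
  g <- as_genome(genome)
  n_ctx <- 4L^order
  counts <- matrix(0, nrow = n_ctx, ncol = 4L,
                   dimnames = list(kmer_names(order), BASES))
  init_counts <- numeric(n_ctx)
  for (s in g) {
    n <- nchar(s)
    if (n <= order) next
    x <- encode_bases(s)
    m <- n - order
    ctx <- integer(m)
    for (j in seq_len(order))
      ctx <- ctx * 4L + x[j:(j + m - 1L)]
    nxt <- x[(order + 1L):n]
    ok_ctx <- !is.na(ctx)
    ok <- ok_ctx & !is.na(nxt)
    if (any(ok))
      counts <- counts + matrix(
        tabulate(ctx[ok] * 4L + nxt[ok] + 1L, nbins = n_ctx * 4L),
        nrow = n_ctx, ncol = 4L, byrow = TRUE)
    if (any(ok_ctx))
      init_counts <- init_counts + tabulate(ctx[ok_ctx] + 1L, nbins = n_ctx)
  }
  if (sum(counts) == 0)
    stop("no transitions observed: every contig is shorter than order + 1")
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA)
  structure(list(order = order, counts = counts, trans_probs = probs,
                 initial = init_counts / sum(init_counts)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov nucleotide model, order", x$order, "\n")
  cat("  contexts observed:", sum(rowSums(x$counts) > 0), "of",
      nrow(x$counts), "\n")
  cat("  total transitions:", sum(x$counts), "\n")
  invisible(x)
}

#' Sample a randomized genome from a fitted Markov model
#'
#' Generates contigs of exactly the requested lengths by ancestral sampling
#' from the fitted chain: the first `order` bases come from a context drawn
#' from the initial distribution, each further base from the transition row
#' of the current context. If a context with zero observed transitions is
#' reached, the chain restarts from the initial distribution (counted and
#' reported via `attr(, "restarts")`). Sampling uses R's RNG, so a fixed
#' seed gives byte-identical output. N is never emitted.
#'
#' @param model A `markov_model` from [fit_markov()].
#' @param contig_lengths Named integer vector of output contig lengths,
#'   each greater than the model order.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] with attribute `restarts`.
#' @export
sample_genome <- function(model, contig_lengths, seed) {
  stopifnot(inherits(model, "markov_model"))
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("'contig_lengths' must be named")
  if (any(contig_lengths <= model$order))
    stop("every contig length must exceed the model order")
  set.seed(as.integer(seed))
  trans_cum <- t(apply(model$trans_probs, 1, cumsum))
  init_cum <- cumsum(model$initial)
  total_restarts <- 0L
  seqs <- character(length(contig_lengths))
  for (i in seq_along(contig_lengths)) {
    res <- .sample_chain_cpp(as.integer(contig_lengths[i]), model$order,
                             trans_cum, init_cum)
    seqs[i] <- rawToChar(as.raw(c(65L, 67L, 71L, 84L)[res$codes + 1L]))
    total_restarts <- total_restarts + res$restarts
  }
  names(seqs) <- names(contig_lengths)
  out <- Biostrings::DNAStringSet(seqs)
  attr(out, "restarts") <- total_restarts
  out
}

#' Generate replicate randomized genomes
#'
#' Fits a Markov model of the given order to `genome` and samples `n`
#' independent randomized genomes, length-matched per contig, with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n - 1`. This is the null
#' ensemble against which observed PQS frequencies are tested; the study
#' design uses five replicates.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param order Markov order (default 1: base-to-base transitions).
#' @param n Number of replicates (default 5).
#' @param base_seed Integer seed of the first replicate.
#' @return A list of `n` [Biostrings::DNAStringSet] genomes.
#' @export
randomize_replicates <- function(genome, order = 1L, n = 5L, base_seed = 1L) {
  if (n < 1) stop("'n' must be >= 1")
  g <- as_genome(genome)
  model <- fit_markov(g, order)
  lens <- setNames(nchar(g), names(g))
  lapply(seq_len(n) - 1L, function(i) sample_genome(model, lens, base_seed + i))
}
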