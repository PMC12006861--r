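# Independent brute-force oracles. These deliberately share no code with
# the package: character-by-character loops and all-pairs enumeration.

oracle_base_scores <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && ch[j] == ch[i]) j <- j + 1L
    run_len <- j - i
    v <- 0
    if (ch[i] == "G") v <- min(run_len, 4)
    if (ch[i] == "C") v <- -min(run_len, 4)
    out[i:(j - 1L)] <- v
    i <- j
  }
  out
}

# Enumerate every window, threshold, merge consecutive qualifying windows,
# rescore each merged region on its own subsequence.
oracle_find_pqs <- function(seq, threshold = 1.2, window = 25L) {
  b <- oracle_base_scores(seq)
  n <- length(b)
  if (n < window) {
    starts <- 1L
    w <- mean(b)
    wl <- n
  } else {
    starts <- 1:(n - window + 1L)
    w <- sapply(starts, function(s) mean(b[s:(s + window - 1L)]))
    wl <- window
  }
  qual <- abs(w) >= threshold
  hits <- list()
  i <- 1L
  while (i <= length(qual)) {
    if (qual[i]) {
      j <- i
      while (j < length(qual) && qual[j + 1L]) j <- j + 1L
      rs <- starts[i]
      re <- starts[j] + wl - 1L
      sub <- substr(seq, rs, re)
      hits[[length(hits) + 1L]] <- data.frame(
        start = rs, end = re, score = mean(oracle_base_scores(sub)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# All-pairs interval intersection on 1-based closed coordinates.
oracle_overlap_pairs <- function(a, b, min_overlap = 1L) {
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  same <- a$contig[idx$i] == b$contig[idx$j]
  ov <- pmin(a$end[idx$i], b$end[idx$j]) -
        pmax(a$start[idx$i], b$start[idx$j]) + 1L
  keep <- same & ov >= min_overlap
  data.frame(i = idx$i[keep], j = idx$j[keep], overlap = ov[keep])
}

# Exhaustive (position, spacer) response-element scan with per-character
# class checks.
oracle_scan_re <- function(seq, max_spacer = 13L, max_mismatch = 3L) {
  classes <- list(c("A", "G"), c("A", "G"), c("A", "G"), "C",
                  c("A", "T"), c("A", "T"), "G",
                  c("C", "T"), c("C", "T"), c("C", "T"))
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  half_mm <- function(p) {
    mm <- 0L
    for (j in 1:10) if (!ch[p + j - 1L] %in% classes[[j]]) mm <- mm + 1L
    mm
  }
  rows <- list()
  for (sp in 0:max_spacer) {
    span <- 20L + sp
    if (n < span) next
    for (p in 1:(n - span + 1L)) {
      mm <- half_mm(p) + half_mm(p + 10L + sp)
      if (mm <= max_mismatch)
        rows[[length(rows) + 1L]] <- data.frame(start = p, spacer = sp,
                                                mismatches = mm)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), spacer = integer(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$spacer, out$mismatches), , drop = FALSE]
}

# Tukey fence by the explicit interpolation formula (type-7 quartiles).
oracle_iqr_filter <- function(v, k = 1.5) {
  s <- sort(v)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- interp(0.25)
  q3 <- interp(0.75)
  v[v >= q1 - k * (q3 - q1) & v <= q3 + k * (q3 - q1)]
}
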