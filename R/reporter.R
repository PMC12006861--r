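#' Normalize luminescence to culture density (RLU)
#'
#' Relative light units: raw luminescence divided by the OD600 of the
#' culture. Invariant to a common gain applied to both readouts.
#'
#' @param luminescence Non-negative luminescence readings.
#' @param od600 Positive OD600 values (same length or length 1).
#' @return Numeric vector of RLU values.
#' @export
normalize_rlu <- function(luminescence, od600) {
  if (any(od600 <= 0)) stop("OD600 must be > 0")
  luminescence / od600
}

#' Tukey-fence outlier filter
#'
#' Keeps the values inside `[Q1 - k*IQR, Q3 + k*IQR]` with quartiles by
#' linear interpolation (type-7 quantiles) and `k = 1.5` by default — the
#' standard 1.5 x interquartile-range fence used to trim empty-vector RLU
#' pools. Fewer than 4 values cannot define quartiles meaningfully and are
#' returned unfiltered with a warning.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @return The filtered vector (order preserved).
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values: returned unfiltered")
    return(values)
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  values[values >= q[1L] - k * iqr & values <= q[2L] + k * iqr]
}

#' Validate and read a reporter measurement table
#'
#' A tidy tab-separated table with one row per well: columns `strain`,
#' `protein`, `galactose`, `time_h`, `replicate`, `od600`, `luminescence`.
#' The key (strain, protein, galactose, time_h, replicate) must be unique
#' and OD600 positive.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_reporter_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_reporter_table(df)
}

validate_reporter_table <- function(df) {
  need <- c("strain", "protein", "galactose", "time_h", "replicate",
            "od600", "luminescence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$od600 <= 0)) stop("OD600 must be > 0")
  if (any(df$luminescence < 0)) stop("luminescence must be >= 0")
  key <- do.call(paste, c(df[c("strain", "protein", "galactose", "time_h",
                               "replicate")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (strain, protein, galactose, time_h, replicate) key")
  df
}

#' Fold induction over the empty-vector control
#'
#' For every (strain, galactose, time) cell, the empty-vector RLU pool is
#' trimmed with the 1.5 x IQR fence ([iqr_filter()]) and averaged; each
#' p53-expressing replicate's RLU is divided by that mean to give a
#' replicate-level fold, and cell-level folds are the means of those
#' ratios (equivalently, mean condition RLU over mean trimmed empty RLU).
#' The result is invariant to a global luminescence gain.
#'
#' @param measurements A measurement data frame (see
#'   [read_reporter_table()]).
#' @param empty_label The `protein` level marking empty-vector wells
#'   (default `"empty"`).
#' @return A data frame of class `fold_induction` with one row per
#'   (strain, protein, galactose, time_h): columns `fold`, `n`, `sd`.
#'   Replicate-level folds are attached as `attr(, "replicates")` (see
#'   [fold_replicates()]).
#' @export
fold_of_empty <- function(measurements, empty_label = "empty") {
  df <- validate_reporter_table(measurements)
  df$rlu <- normalize_rlu(df$luminescence, df$od600)
  cell_key <- interaction(df$strain, df$galactose, df$time_h, drop = TRUE)
  rep_rows <- list()
  for (cell in levels(cell_key)) {
    idx <- which(cell_key == cell)
    sub <- df[idx, , drop = FALSE]
    empties <- sub$rlu[sub$protein == empty_label]
    if (!length(empties))
      stop(sprintf("no empty-vector replicates for cell (strain %s, galactose %s, time %s)",
                   sub$strain[1L], sub$galactose[1L], sub$time_h[1L]))
    denom <- mean(iqr_filter(empties))
    cond <- sub[sub$protein != empty_label, , drop = FALSE]
    if (!nrow(cond)) next
    cond$fold <- cond$rlu / denom
    rep_rows[[cell]] <- cond[, c("strain", "protein", "galactose", "time_h",
                                 "replicate", "fold")]
  }
  reps <- do.call(rbind, rep_rows)
  rownames(reps) <- NULL
  agg <- aggregate(fold ~ strain + protein + galactose + time_h, data = reps,
                   FUN = function(v) c(fold = mean(v), n = length(v), sd = sd(v)))
  out <- data.frame(agg[c("strain", "protein", "galactose", "time_h")],
                    fold = agg$fold[, "fold"], n = as.integer(agg$fold[, "n"]),
                    sd = agg$fold[, "sd"], stringsAsFactors = FALSE)
  out <- out[order(out$galactose, out$time_h, out$strain, out$protein), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  class(out) <- c("fold_induction", "data.frame")
  out
}

#' Replicate-level folds behind a fold-induction table
#'
#' @param x A `fold_induction` object from [fold_of_empty()].
#' @return Data frame of per-replicate fold values.
#' @export
fold_replicates <- function(x) {
  r <- attr(x, "replicates")
  if (is.null(r)) stop("no replicate-level folds attached")
  r
}

#' Two-way ANOVA with Dunnett comparisons against a control strain
#'
#' Within each (galactose, time) stratum, fits the fixed-effects two-way
#' model `fold ~ strain * protein` and reports a type II ANOVA table
#' (robust to the mild imbalance that outlier trimming induces). Dunnett
#' comparisons contrast every strain against the named control strain
#' within each protein level, all jointly adjusted as one family per
#' stratum: adjusted p-values are equicoordinate tail probabilities of the
#' multivariate t distribution with the pooled residual degrees of freedom
#' and the Dunnett correlation structure (shared control within a protein
#' level; zero across levels), evaluated by the seeded Genz-Bretz
#' algorithm with 1e5 integrand evaluations. The single-comparison family
#' reduces exactly to the unadjusted two-sided t-test. A stratum with a
#' single protein level degenerates to a one-way layout (`fold ~ strain`),
#' which is how the two-group limit is reached.
#'
#' @param folds Replicate-level fold values: a `fold_induction` object or
#'   a data frame with columns `strain`, `protein`, `fold` and optionally
#'   `galactose`, `time_h`.
#' @param control Control strain label each other strain is compared to
#'   (required; no default is guessed).
#' @param seed Integer seed for the multivariate-t integration.
#' @return An object of class `reporter_anova`: list with `anova` (one
#'   type II table per stratum) and `comparisons` (data frame with
#'   `galactose`, `time_h`, `protein`, `comparison`, `estimate`, `se`,
#'   `t`, `df`, `p_unadj`, `p_adj`, `tier`).
#' @export
anova_dunnett <- function(folds, control, seed = 1L) {
  if (inherits(folds, "fold_induction")) folds <- fold_replicates(folds)
  need <- c("strain", "protein", "fold")
  miss <- setdiff(need, names(folds))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (missing(control)) stop("'control' strain must be named explicitly")
  if (!control %in% folds$strain)
    stop("control strain '", control, "' not present")
  if (!"galactose" %in% names(folds)) folds$galactose <- NA
  if (!"time_h" %in% names(folds)) folds$time_h <- NA
  set.seed(as.integer(seed))
  strata <- unique(folds[c("galactose", "time_h")])
  anova_tabs <- list()
  comp_rows <- list()
  for (si in seq_len(nrow(strata))) {
    sub <- folds[(folds$galactose %in% strata$galactose[si]) &
                 (folds$time_h %in% strata$time_h[si]), , drop = FALSE]
    sub$strain <- factor(sub$strain)
    sub$protein <- factor(sub$protein)
    if (nlevels(sub$strain) < 2L)
      stop("at least 2 strain levels are required per stratum")
    cell_n <- table(sub$strain, sub$protein)
    if (any(cell_n < 2L)) {
      bad <- which(cell_n < 2L, arr.ind = TRUE)
      stop("cells with fewer than 2 replicates: ",
           paste(rownames(cell_n)[bad[, 1L]], colnames(cell_n)[bad[, 2L]],
                 sep = ":", collapse = ", "))
    }
    # a single protein level degenerates to a one-way layout
    fit <- if (nlevels(sub$protein) >= 2L)
      aov(fold ~ strain * protein, data = sub)
    else
      aov(fold ~ strain, data = sub)
    tab <- car::Anova(fit, type = 2)
    df_res <- fit$df.residual
    mse <- sum(fit$residuals^2) / df_res
    strata_label <- sprintf("galactose=%s, time=%s",
                            strata$galactose[si], strata$time_h[si])
    anova_tabs[[strata_label]] <- tab

    others <- setdiff(levels(sub$strain), control)
    comps <- expand.grid(strain = others, protein = levels(sub$protein),
                         stringsAsFactors = FALSE)
    k <- nrow(comps)
    est <- se <- tval <- lambda <- numeric(k)
    for (ci in seq_len(k)) {
      a_rows <- sub$fold[sub$strain == comps$strain[ci] &
                         sub$protein == comps$protein[ci]]
      c_rows <- sub$fold[sub$strain == control &
                         sub$protein == comps$protein[ci]]
      est[ci] <- mean(a_rows) - mean(c_rows)
      se[ci] <- sqrt(mse * (1 / length(a_rows) + 1 / length(c_rows)))
      tval[ci] <- est[ci] / se[ci]
      lambda[ci] <- sqrt(length(a_rows) / (length(a_rows) + length(c_rows)))
    }
    # Dunnett correlation: comparisons sharing a control cell correlate as
    # lambda_i * lambda_j; comparisons in different protein levels use
    # disjoint cells and are uncorrelated.
    corr <- diag(k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && comps$protein[i] == comps$protein[j])
        corr[i, j] <- lambda[i] * lambda[j]
    }
    p_un <- 2 * pt(-abs(tval), df_res)
    p_adj <- vapply(seq_len(k), function(ci) {
      if (k == 1L) return(p_un[ci])
      1 - mvtnorm::pmvt(lower = rep(-abs(tval[ci]), k),
                        upper = rep(abs(tval[ci]), k),
                        df = df_res, corr = corr, delta = rep(0, k),
                        algorithm = mvtnorm::GenzBretz(maxpts = 1e5,
                                                       abseps = 1e-4))[1]
    }, numeric(1))
    p_adj <- pmin(1, pmax(p_adj, p_un))  # Dunnett dominance, guard MC jitter
    comp_rows[[si]] <- data.frame(
      galactose = strata$galactose[si], time_h = strata$time_h[si],
      protein = comps$protein,
      comparison = paste(comps$strain, "-", control),
      estimate = est, se = se, t = tval, df = df_res,
      p_unadj = p_un, p_adj = p_adj, tier = significance_tier(p_adj),
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, comp_rows)
  rownames(comparisons) <- NULL
  structure(list(anova = anova_tabs, comparisons = comparisons,
                 control = control),
            class = "reporter_anova")
}

#' @export
print.reporter_anova <- function(x, ...) {
  cat("Two-way ANOVA with Dunnett comparisons (control:", x$control, ")\n\n")
  for (nm in names(x$anova)) {
    cat("--", nm, "--\n")
    print(x$anova[[nm]])
    cat("\n")
  }
  print(x$comparisons, digits = 4)
  invisible(x)
}
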