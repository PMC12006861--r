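test_that("RLU normalization divides by OD600 and guards the denominator", {
  expect_equal(normalize_rlu(1000, 0.5), 2000)
  expect_equal(normalize_rlu(0, 0.8), 0)
  expect_error(normalize_rlu(100, 0), "OD600")
  # ratio invariance under a common gain
  expect_equal(normalize_rlu(300 * 7, 0.6 * 7), normalize_rlu(300, 0.6))
})

test_that("the Tukey fence removes gross outliers and keeps ties", {
  expect_equal(iqr_filter(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(iqr_filter(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_warning(kept <- iqr_filter(c(1, 2, 3)), "fewer than 4")
  expect_equal(kept, c(1, 2, 3))
})

test_that("the fence agrees with the interpolation-formula oracle", {
  set.seed(123)
  for (i in 1:200) {
    v <- rnorm(sample(4:30, 1), sd = runif(1, 0.5, 3))
    if (runif(1) < 0.3) v[1] <- v[1] * 20  # occasional gross outlier
    expect_equal(iqr_filter(v), oracle_iqr_filter(v))
  }
})

make_meas <- function(strain, protein, rlu, galactose = 1, time_h = 6) {
  data.frame(strain = strain, protein = protein, galactose = galactose,
             time_h = time_h, replicate = seq_along(rlu), od600 = 1,
             luminescence = rlu, stringsAsFactors = FALSE)
}

test_that("fold-of-empty divides by the trimmed empty mean per cell", {
  m <- rbind(make_meas("S1", "WT", c(200, 200)),
             make_meas("S1", "empty", c(100, 100)))
  suppressWarnings(fo <- fold_of_empty(m))
  expect_equal(fo$fold, 2.0)
  expect_equal(fo$n, 2L)

  # protein distribution equal to empty: fold ~ 1
  set.seed(9)
  m2 <- rbind(make_meas("S1", "WT", rlnorm(8, log(500), 0.1)),
              make_meas("S1", "empty", rlnorm(8, log(500), 0.1)))
  fo2 <- fold_of_empty(m2)
  expect_equal(fo2$fold, 1.0, tolerance = 0.15)

  # scale invariance to a global luminescence gain
  m3 <- m2
  m3$luminescence <- m3$luminescence * 50
  expect_equal(fold_of_empty(m3)$fold, fo2$fold)

  # missing empty cell errors with the cell named
  expect_error(suppressWarnings(fold_of_empty(make_meas("S1", "WT", c(1, 2)))),
               "no empty-vector")

  # the empty pool is fenced before averaging
  m4 <- rbind(make_meas("S1", "WT", rep(300, 6)),
              make_meas("S1", "empty", c(100, 101, 99, 100, 100, 1000)))
  fo4 <- fold_of_empty(m4)
  expect_equal(fo4$fold, 300 / 100, tolerance = 0.01)
})

test_that("planted fold effects are recovered on average within 10%", {
  true_folds <- default_assay_effects()
  rel_err <- matrix(NA_real_, nrow = 30, ncol = nrow(true_folds))
  for (s in 1:30) {
    spec <- synthetic_spec(seed = 1000 + s, galactose = 1, time_h = 6)
    fo <- fold_of_empty(make_reporter_table(spec))
    key_est <- paste(fo$strain, fo$protein)
    key_true <- paste(true_folds$strain, true_folds$protein)
    est <- fo$fold[match(key_true, key_est)]
    rel_err[s, ] <- est / true_folds$fold
  }
  expect_true(all(abs(colMeans(rel_err) - 1) < 0.10))
})

test_that("Dunnett adjustment reduces to the plain t-test for one comparison", {
  set.seed(31)
  m <- rbind(make_meas("ctrl", "WT", rnorm(6, 10)),
             make_meas("trt", "WT", rnorm(6, 12)))
  m$fold <- m$luminescence
  res <- anova_dunnett(m[, c("strain", "protein", "fold")], control = "ctrl")
  expect_equal(nrow(res$comparisons), 1L)
  expect_equal(res$comparisons$p_adj, res$comparisons$p_unadj, tolerance = 1e-12)

  # and matches a hand-computed pooled t-test
  t_manual <- t.test(m$fold[m$strain == "trt"], m$fold[m$strain == "ctrl"],
                     var.equal = TRUE)
  expect_equal(res$comparisons$p_unadj, t_manual$p.value, tolerance = 1e-10)
})

test_that("adjusted p dominates unadjusted p across a full design", {
  spec <- synthetic_spec(seed = 77)
  fo <- fold_of_empty(make_reporter_table(spec))
  res <- anova_dunnett(fo, control = "BBC3_RE", seed = 5)
  expect_true(all(res$comparisons$p_adj >= res$comparisons$p_unadj - 1e-12))
  expect_true(all(res$comparisons$p_adj <= 1))
  # one ANOVA table per (galactose, time) stratum
  expect_length(res$anova, 4L)
  # determinism of the seeded multivariate-t integration
  res2 <- anova_dunnett(fo, control = "BBC3_RE", seed = 5)
  expect_identical(res$comparisons$p_adj, res2$comparisons$p_adj)
})

test_that("a large planted strain effect is detected reliably", {
  set.seed(61)
  detected <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    # 3 strains x 2 proteins, n = 5; one strain shifted by 4 SD
    df <- expand.grid(strain = c("ctrl", "s1", "s2"),
                      protein = c("WT", "mut"), replicate = 1:5,
                      stringsAsFactors = FALSE)
    df$fold <- rnorm(nrow(df), 1, 0.2)
    df$fold[df$strain == "s1"] <- df$fold[df$strain == "s1"] + 4 * 0.2
    res <- anova_dunnett(df, control = "ctrl", seed = i)
    p_s1 <- res$comparisons$p_adj[grepl("^s1", res$comparisons$comparison)]
    if (all(p_s1 < 0.01)) detected <- detected + 1L
  }
  expect_gte(detected / n_sim, 0.95)
})

test_that("measurement tables round-trip through TSV with validation", {
  tab <- make_reporter_table(synthetic_spec(seed = 91, galactose = 1,
                                            time_h = 6))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_reporter_table(tf)
  expect_equal(back$luminescence, tab$luminescence)
  expect_equal(back$od600, tab$od600)

  bad <- tab
  bad$replicate <- 1L  # duplicate keys
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_reporter_table(tf), "duplicate")
})

test_that("cells with too few replicates are reported by name", {
  df <- expand.grid(strain = c("a", "b"), protein = c("WT", "mut"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  df$fold <- rnorm(nrow(df))
  df <- df[-which(df$strain == "a" & df$protein == "WT")[1:2], ]  # 1 replicate left
  expect_error(anova_dunnett(df, control = "a"), "fewer than 2 replicates")
  expect_error(anova_dunnett(df[0, ], control = "a"), "not present")
})
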