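test_that("quantile normalization maps columns onto the rank-mean reference", {
  m <- matrix(c(1, 5, 3, 7), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), matrix(c(2, 6, 2, 6), nrow = 2))
  expect_identical(dimnames(qn), dimnames(m))

  # idempotence and column identity on random data
  set.seed(1)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  q1 <- quantile_normalize(x)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  sorted <- apply(q1, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])

  # cross-check against the established implementation (tie-free input)
  expect_equal(unname(q1), unname(limma::normalizeQuantiles(x)),
               tolerance = 1e-10)

  # fixed points
  same <- matrix(rep(1:5, 3), 5, 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(quantile_normalize(same), same)
  one <- x[, 1, drop = FALSE]
  expect_identical(quantile_normalize(one), one)
  expect_error(quantile_normalize(cbind(x, NA)), "missing")
})

test_that("probe collapsing keeps the probe with maximal mean expression", {
  m <- matrix(c(5, 5, 7, 7, 1, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("G", "G"))
  out <- collapse_probes(m, map)
  expect_identical(rownames(out), "G")
  expect_equal(unname(out["G", ]), c(7, 7))   # p2 wins (mean 7 > 5)

  # bijection renames only; unmapped probe p3 dropped
  map2 <- data.frame(probe_id = c("p1", "p2"),
                     gene_id = c("GA", "GB"))
  out2 <- collapse_probes(m, map2)
  expect_identical(rownames(out2), c("GA", "GB"))
  expect_equal(unname(out2), unname(m[1:2, ]))
  expect_error(collapse_probes(m, data.frame(probe_id = "zz",
                                             gene_id = "G")), "no probe")
})

test_that("batch correction zeroes batch residual means and preserves contrasts", {
  sim <- tiny_sim(seed = 2)
  shifted <- sim$expr
  b2 <- sim$samples$batch == sim$samples$batch[nrow(sim$samples)]
  shifted[, b2] <- shifted[, b2] + 3   # extra offset on the last batch
  corrected <- correct_batch(shifted, sim$samples)

  cell <- interaction(sim$samples$condition, sim$samples$context)
  cm <- vapply(levels(cell), function(lv)
    rowMeans(corrected[, cell == lv, drop = FALSE]),
    numeric(nrow(corrected)))
  resid <- corrected - cm[, as.integer(cell)]
  for (b in unique(sim$samples$batch)) {
    bm <- rowMeans(resid[, sim$samples$batch == b, drop = FALSE])
    expect_lt(max(abs(bm)), 1e-10)
  }

  # case-control contrast preserved exactly
  is_case <- sim$samples$condition == "case"
  d_before <- rowMeans(shifted[, is_case]) - rowMeans(shifted[, !is_case])
  d_after <- rowMeans(corrected[, is_case]) - rowMeans(corrected[, !is_case])
  expect_equal(d_after, d_before, tolerance = 1e-10)

  # single batch is a no-op
  one_batch <- sim$samples
  one_batch$batch <- "B1"
  expect_equal(correct_batch(sim$expr, one_batch), sim$expr)

  # planted DEG effect survives a 5-unit batch offset
  cfg <- sim_config(n_genes = 60, n_samples_per_group = 25, n_modules = 0,
                    n_degs = 4, deg_effect = 2, n_rewired = 0, n_tfs = 0,
                    batch_sd = 5, seed = 12)
  sim2 <- simulate_expression(cfg)
  cor2 <- correct_batch(sim2$expr, sim2$samples)
  ic <- sim2$samples$condition == "case"
  for (g in names(sim2$truth$deg_genes)) {
    d <- mean(cor2[g, ic]) - mean(cor2[g, !ic])
    expect_equal(d, sim2$truth$deg_genes[[g]], tolerance = 0.7)
  }
})

test_that("qc_filter removes missing-heavy and constant features with reasons", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m["g2", ] <- 5                       # constant
  m["g3", 1:6] <- NA                   # 60% missing
  out <- qc_filter(m, max_missing_frac = 0.5)
  expect_setequal(rownames(out$expr), c("g1", "g4"))
  expect_setequal(out$report$id, c("g2", "g3"))
  expect_match(out$report$reason[out$report$id == "g2"], "zero variance")

  clean <- qc_filter(m[c("g1", "g4"), ])
  expect_identical(nrow(clean$report), 0L)
  expect_equal(clean$expr, m[c("g1", "g4"), ])
  expect_error(qc_filter(matrix(1, 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y")))),
               "removed")
})

test_that("variance filter applies a strict type-7 percentile threshold", {
  # two-sample rows with exact variances 1..10 (sample var of (-a, a) = 2a^2)
  vars <- 1:10
  m <- t(vapply(vars, function(v) c(-1, 1) * sqrt(v / 2), numeric(2)))
  dimnames(m) <- list(paste0("g", vars), c("s1", "s2"))
  kept <- filter_variance(m, percentile = 70)
  expect_identical(rownames(kept), c("g8", "g9", "g10"))  # threshold 7.3

  expect_identical(rownames(filter_variance(m, percentile = 0)),
                   paste0("g", 2:10))
  expect_warning(empty <- filter_variance(m, percentile = 100),
                 "no gene")
  expect_identical(nrow(empty), 0L)

  # monotone: raising the percentile never adds genes
  set.seed(3)
  x <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  prev <- rownames(filter_variance(x, 0))
  for (p in c(20, 50, 70, 90)) {
    cur <- rownames(filter_variance(x, p))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("outlier detection flags gross shifts and spares homogeneous data", {
  set.seed(4)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  expect_length(detect_outlier_samples(m), 0L)

  shifted <- m
  shifted[, "s5"] <- shifted[, "s5"] + 20
  expect_identical(detect_outlier_samples(shifted), "s5")

  dup <- m[, c(1, 1, 1), drop = FALSE]
  colnames(dup) <- c("a", "b", "c")
  expect_length(detect_outlier_samples(dup), 0L)
  expect_error(detect_outlier_samples(m[, 1:2]), "3 samples")

  # false-flag rate under i.i.d. sampling stays low at the auto cut
  flags <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    x <- matrix(rnorm(30 * 15), 30, 15,
                dimnames = list(NULL, paste0("s", 1:15)))
    length(detect_outlier_samples(x)) > 0
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})
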