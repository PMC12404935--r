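test_that("TOM formula reproduces hand-computed overlaps and bounds", {
  a <- matrix(c(0, 1, 1,
                1, 0, 0,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  tom <- tom_from_adjacency(a)
  expect_equal(tom["b", "c"], 0.5)
  expect_equal(tom["a", "b"], 1.0)
  expect_equal(diag(tom), setNames(rep(1, 3), letters[1:3]))

  zero <- matrix(0, 4, 4)
  tz <- tom_from_adjacency(zero)
  expect_true(all(tz[upper.tri(tz)] == 0))
  ones <- matrix(1, 4, 4)
  expect_true(all(tom_from_adjacency(ones) == 1))

  # structural invariants on a data-driven TOM
  sim <- tiny_sim(seed = 5)
  tom2 <- build_tom(sim$expr[1:40, ], beta = 6)
  expect_equal(tom2, t(tom2))
  expect_true(all(tom2 >= 0 & tom2 <= 1 + 1e-12))
  expect_equal(unname(diag(tom2)), rep(1, 40))
})

test_that("raising the power never increases off-diagonal adjacency", {
  sim <- tiny_sim(seed = 6)
  ac <- abs(cor(t(sim$expr[1:30, ])))
  prev <- ac^1
  for (b in c(2, 4, 8)) {
    cur <- ac^b
    expect_true(all(cur[upper.tri(cur)] <= prev[upper.tri(prev)] + 1e-15))
    prev <- cur
  }
})

test_that("soft-threshold report matches an independent regression and the selection rule", {
  cfg <- sim_config(n_genes = 300, n_samples_per_group = 10, n_modules = 3,
                    module_size = 30, module_cor = 0.8, n_degs = 0,
                    n_rewired = 0, n_tfs = 0, seed = 31)
  sim <- simulate_expression(cfg)
  suppressWarnings(sft <- pick_soft_threshold(sim$expr))
  rep <- sft$report

  # recompute one power's fit index independently
  b <- rep$power[6]
  ac <- abs(cor(t(sim$expr))); diag(ac) <- 0
  k <- rowSums(ac^b)
  bin <- cut(k[k > 0], breaks = 10)
  freq <- as.vector(table(bin))
  dk <- tapply(k[k > 0], bin, mean)
  keep <- freq > 0 & !is.na(dk)
  fit <- lm(log10(freq[keep]) ~ log10(dk[keep]))
  expect_equal(rep$r_squared[6],
               -sign(coef(fit)[[2]]) * summary(fit)$r.squared,
               tolerance = 1e-8)
  expect_equal(rep$mean_k[6], mean(k), tolerance = 1e-10)

  # chosen power obeys smallest-above-target, with argmax fallback
  hit <- rep$power[rep$r_squared >= 0.80]
  if (length(hit)) {
    expect_identical(sft$power, hit[1])
  } else {
    expect_identical(sft$power, rep$power[which.max(rep$r_squared)])
  }
  expect_warning(fallback <- pick_soft_threshold(sim$expr,
                                                 r2_target = 0.9999),
                 "argmax")
  expect_identical(fallback$power,
                   fallback$report$power[which.max(
                     fallback$report$r_squared)])
})

test_that("module detection recovers separated blocks and merges collinear ones", {
  # two independent 30-gene blocks among noise
  cfg <- sim_config(n_genes = 120, n_samples_per_group = 10, n_modules = 2,
                    module_size = 30, module_cor = 0.8, n_degs = 0,
                    n_rewired = 0, n_tfs = 0, seed = 41)
  sim <- simulate_expression(cfg)
  tom <- build_tom(sim$expr, beta = 8)
  mod <- detect_modules(tom, sim$expr, min_module_size = 20)
  truth <- rep(0L, nrow(sim$expr))
  names(truth) <- rownames(sim$expr)
  truth[names(sim$truth$module_assignments)] <-
    sim$truth$module_assignments
  expect_identical(max(mod), 2L)
  expect_gte(mclust::adjustedRandIndex(mod, truth[names(mod)]), 0.9)

  # two blocks driven by near-identical factors merge (eigengene cor > 0.8)
  set.seed(42)
  f <- rnorm(40)
  blockA <- t(sapply(1:25, function(i) 3 * f + rnorm(40, sd = 0.5)))
  blockB <- t(sapply(1:25, function(i)
    3 * (0.97 * f + sqrt(1 - 0.97^2) * rnorm(40)) + rnorm(40, sd = 0.5)))
  noise <- matrix(rnorm(30 * 40), 30, 40)
  expr <- rbind(blockA, blockB, noise)
  rownames(expr) <- sprintf("g%03d", 1:80)
  colnames(expr) <- sprintf("s%02d", 1:40)
  tom2 <- build_tom(expr, beta = 6)
  merged <- detect_modules(tom2, expr, min_module_size = 15)
  expect_identical(max(merged), 1L)
  expect_true(all(merged[1:50] == 1L))

  # all-identical genes collapse to one module
  same <- matrix(rep(rnorm(20), each = 30), 30, 20,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%02d", 1:20)))
  same <- same + matrix(rnorm(600, sd = 1e-6), 30, 20)
  tom3 <- build_tom(same, beta = 6)
  expect_true(all(detect_modules(tom3, same, min_module_size = 5) == 1L))

  # nothing reaches the minimum size
  expect_warning(none <- detect_modules(tom2, expr, min_module_size = 70),
                 "unassigned")
  expect_true(all(none == 0L))
})

test_that("eigengenes match an SVD oracle and satisfy their contracts", {
  sim <- tiny_sim(seed = 51)
  part <- setNames(rep(1L, 5), rownames(sim$expr)[1:5])
  me <- module_eigengenes(sim$expr, part)
  e <- me$eigengenes["ME1", ]

  xs <- t(scale(t(sim$expr[1:5, ])))
  sv <- svd(xs)
  oracle <- sv$v[, 1]
  expect_gte(abs(cor(e, oracle)), 0.9999)
  expect_equal(sd(e), 1, tolerance = 1e-10)
  expect_gte(cor(e, colMeans(xs)), 0)
  expect_equal(me$var_explained[["ME1"]], sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-10)

  # rank-1 module: eigengene equals the standardized common profile
  prof <- rnorm(ncol(sim$expr))
  rank1 <- matrix(rep(prof, each = 4), 4,
                  dimnames = list(paste0("r", 1:4), colnames(sim$expr)))
  me1 <- module_eigengenes(rank1, setNames(rep(1L, 4), paste0("r", 1:4)))
  expect_equal(unname(me1$eigengenes["ME1", ]),
               as.vector(scale(prof)), tolerance = 1e-8)
  expect_equal(me1$var_explained[["ME1"]], 1.0)

  # sign alignment survives flipping every gene
  me_flip <- module_eigengenes(-sim$expr, part)
  xs_flip <- t(scale(t(-sim$expr[1:5, ])))
  expect_gte(cor(me_flip$eigengenes["ME1", ], colMeans(xs_flip)), 0)

  # no random unit-norm gene combination explains more sample variance
  # than the eigengene direction
  set.seed(99)
  ev_eig <- var(as.numeric(t(sv$u[, 1]) %*% xs))
  best_rand <- max(vapply(1:100, function(i) {
    w <- rnorm(5); w <- w / sqrt(sum(w^2))
    var(as.numeric(w %*% xs))
  }, numeric(1)))
  expect_gte(ev_eig + 1e-10, best_rand)
})

test_that("module-trait correlation agrees with cor.test", {
  sim <- tiny_sim(seed = 61)
  part <- setNames(rep(1:2, each = 10), rownames(sim$expr)[1:20])
  me <- module_eigengenes(sim$expr, part)
  mt <- module_trait_correlation(me$eigengenes, sim$samples)
  for (i in seq_len(nrow(mt))) {
    tv <- if (mt$trait[i] == "disease")
      as.numeric(sim$samples$condition == "case")
    else as.numeric(sim$samples$sex == "female")
    ct <- cor.test(me$eigengenes[mt$module[i], ], tv)
    expect_equal(mt$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(mt$p[i], ct$p.value, tolerance = 1e-10)
  }

  # self-correlation and constant trait
  trait <- as.numeric(sim$samples$condition == "case")
  fake <- rbind(ME1 = as.vector(scale(trait)))
  colnames(fake) <- sim$samples$sample_id
  self <- module_trait_correlation(fake, sim$samples,
                                   traits = data.frame(disease = trait))
  expect_equal(self$r, 1.0, tolerance = 1e-10)
  expect_warning(const <- module_trait_correlation(
    fake, sim$samples, traits = data.frame(flat = rep(1, ncol(fake)))),
    "constant")
  expect_true(is.na(const$r))
})
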