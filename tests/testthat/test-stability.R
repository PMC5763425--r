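test_that("hypergeometric overlap tail matches enumeration and direct summation", {
  # full draw enumeration: M=10, K=N=5, x=5 -> 1/252
  expect_equal(hypergeometric_overlap_p(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_overlap_p(5, 5, 5, 10),
               oracle_hyper_enum(5, 5, 5, 10), tolerance = 1e-12)
  # M=2, K=N=1: the two draws overlap or not, p = 1/2
  expect_equal(hypergeometric_overlap_p(1, 1, 1, 2), 0.5, tolerance = 1e-15)
  # empty sum boundary
  expect_identical(hypergeometric_overlap_p(0, 5, 5, 10), 1)

  expect_error(hypergeometric_overlap_p(6, 5, 5, 10), "exceeds")
  expect_error(hypergeometric_overlap_p(1, 11, 5, 10), "universe")
})

test_that("hypergeometric tail agrees with direct summation for all feasible cases M <= 20", {
  worst <- 0
  for (M in 2:20) for (K in 1:M) for (N in 1:M) for (x in 0:min(K, N)) {
    worst <- max(worst, abs(hypergeometric_overlap_p(x, K, N, M) -
                            oracle_hyper_direct(x, K, N, M)))
  }
  expect_lt(worst, 1e-12)

  # literal draw-by-draw enumeration on a denser sweep of small universes
  worst_enum <- 0
  for (M in 2:9) for (K in 1:(M - 1)) for (N in 1:(M - 1)) for (x in 0:min(K, N)) {
    worst_enum <- max(worst_enum, abs(hypergeometric_overlap_p(x, K, N, M) -
                                      oracle_hyper_enum(x, K, N, M)))
  }
  expect_lt(worst_enum, 1e-12)

  # agreement with the standard distribution function at large sizes,
  # including deep tails
  expect_equal(hypergeometric_overlap_p(40, 300, 400, 5000),
               stats::phyper(39, 300, 4700, 400, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hypergeometric_overlap_p(90, 100, 100, 5000),
               stats::phyper(89, 100, 4900, 100, lower.tail = FALSE),
               tolerance = 1e-10)

  # monotone in x
  p_seq <- vapply(0:8, function(x) hypergeometric_overlap_p(x, 8, 10, 30), numeric(1))
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("half_split_selection screens both halves and builds the overlap input", {
  cfg <- synth_config(n_sites = 150, n_samples = 160, n_modules = 5,
                      module_size = 20, n_drivers = 10, driver_effect = 3,
                      seed = 47)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)
  hs <- half_split_selection(gen$m, clin, alpha = 0.05, seed = 2)
  expect_equal(hs$overlap$M, nrow(gen$m))
  expect_equal(hs$overlap$x, length(intersect(hs$set_a, hs$set_b)))
  expect_lte(hs$overlap$x, min(hs$overlap$K, hs$overlap$N))
  # planted shared drivers: overlap above the hypergeometric expectation
  expect_gt(hs$overlap$x, hs$overlap$K * hs$overlap$N / hs$overlap$M)
  expect_lt(hs$p_value, 0.05)
})

test_that("duplicated samples in both halves give identical selections", {
  cfg <- synth_config(n_sites = 80, n_samples = 60, n_modules = 4,
                      module_size = 15, n_drivers = 8, seed = 53)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)
  # duplicate the cohort with cloned sample ids so each half can hold a copy
  m2 <- cbind(gen$m, gen$m)
  colnames(m2) <- c(colnames(gen$m), paste0(colnames(gen$m), "_dup"))
  cl2 <- rbind(clin, transform(clin, sample = paste0(sample, "_dup")))
  # force the split to put one copy in each half by screening each copy directly
  idsA <- colnames(gen$m)
  res_a <- screen_hubs(m2[, idsA], cl2[match(idsA, cl2$sample), ], rownames(m2), 0.05)
  idsB <- paste0(colnames(gen$m), "_dup")
  res_b <- screen_hubs(m2[, idsB], cl2[match(idsB, cl2$sample), ], rownames(m2), 0.05)
  expect_identical(res_a$entries$site, res_b$entries$site)
})

test_that("run_stability is reproducible and separates strong from weak platforms", {
  cfg <- synth_config(n_samples = 120, n_drivers = 15, censoring_rate = 0.3,
                      platform_profiles = list(
                        strong = list(n_features = 120, attenuation = 1.0, bounded = TRUE),
                        weak = list(n_features = 120, attenuation = 0.15, bounded = FALSE)),
                      seed = 61)
  gp <- generate_platforms(cfg)

  rep1 <- run_stability(gp$platforms$strong, gp$clinical, B = 5, seed = 3)
  rep2 <- run_stability(gp$platforms$strong, gp$clinical, B = 5, seed = 3)
  expect_equal(nrow(rep1$table), 5)
  expect_identical(rep1$table, rep2$table)
  expect_true(all(rep1$table$p_value >= 0 & rep1$table$p_value <= 1))

  st_strong <- run_stability(gp$platforms$strong, gp$clinical, B = 15, seed = 5)
  st_weak <- run_stability(gp$platforms$weak, gp$clinical, B = 15, seed = 5)
  expect_lt(median(st_strong$table$p_value), median(st_weak$table$p_value))
})

test_that("stability replicate p-values carry no signal when survival is pure noise", {
  # With no drivers the two halves select independently, so overlap
  # p-values must not pile up near zero. (The overlap statistic is
  # discrete, so at a small feature universe the null p-values are
  # conservative rather than exactly uniform; the full uniformity check at
  # a large universe runs in the acceptance suite.)
  cfg <- synth_config(n_sites = 150, n_samples = 120, n_modules = 3,
                      module_size = 10, n_drivers = 0, censoring_rate = 0.2,
                      seed = 67)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)
  rep0 <- run_stability(gen$m, clin, B = 30, seed = 7)
  expect_gt(median(rep0$table$p_value), 0.2)
  expect_lte(mean(rep0$table$p_value < 0.05), 0.2)
})

test_that("compare_platforms matches exhaustive rank enumeration and detects separation", {
  # small tie-free case against the enumeration oracle
  a <- c(0.02, 0.11, 0.35, 0.48)
  b <- c(0.25, 0.57, 0.77, 0.91)
  expect_equal(compare_platforms(a, b), oracle_wilcoxon(a, b), tolerance = 1e-12)

  set.seed(71)
  for (i in 1:20) {
    x <- runif(sample(3:8, 1))
    y <- runif(sample(3:8, 1))
    expect_equal(compare_platforms(x, y), oracle_wilcoxon(x, y), tolerance = 1e-12)
  }

  # identical vectors: no difference signal
  expect_gt(compare_platforms(a, a), 0.5)

  # clearly separated distributions
  set.seed(73)
  expect_lt(compare_platforms(runif(100, 0, 0.1), runif(100, 0.5, 1)), 1e-10)
})
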