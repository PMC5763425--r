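test_that("train/test split halves are disjoint, sized and reproducible", {
  ids <- sprintf("P%02d", 1:10)
  sp <- split_train_test(ids, seed = 4)
  expect_equal(length(sp$train), 5)
  expect_equal(length(sp$test), 5)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, seed = 4))

  odd <- split_train_test(sprintf("P%02d", 1:7), seed = 1)
  expect_equal(length(odd$train), 4)
  expect_equal(length(odd$test), 3)
  expect_error(split_train_test(ids[1:3], 1), "at least 4")
})

test_that("risk scores evaluate the signed-sum rule and its symmetries", {
  m <- rbind(cgP = c(0.7, 0.3), cgN = c(0.2, 0.6), cgP2 = c(0.1, 0.9))
  colnames(m) <- c("s1", "s2")

  sig <- make_signature(c("cgP", "cgN"), c(1.5, -0.8))
  sc <- compute_risk_scores(sig, m)
  expect_equal(sc$score[sc$sample == "s1"], 0.7 - 0.2)

  # 3 positive + 2 negative hand case
  m2 <- matrix(c(0.1, 0.2, 0.3, 0.05, 0.15), ncol = 1,
               dimnames = list(paste0("s", 1:5), "pat"))
  sig2 <- make_signature(paste0("s", 1:5), c(1, 1, 1, -1, -1))
  expect_equal(compute_risk_scores(sig2, m2)$score, 0.6 - 0.2, tolerance = 1e-12)

  # empty signature scores 0 everywhere
  sig0 <- make_signature(character(0), numeric(0))
  expect_equal(compute_risk_scores(sig0, m)$score, c(0, 0))

  # additivity over a disjoint union
  sig_a <- make_signature("cgP", 1)
  sig_b <- make_signature(c("cgN", "cgP2"), c(-1, 2))
  sig_ab <- make_signature(c("cgP", "cgN", "cgP2"), c(1, -1, 2))
  expect_equal(compute_risk_scores(sig_ab, m)$score,
               compute_risk_scores(sig_a, m)$score + compute_risk_scores(sig_b, m)$score)

  # flipping every sign negates every score
  sig_flip <- make_signature(c("cgP", "cgN"), c(-1.5, 0.8))
  expect_equal(compute_risk_scores(sig_flip, m)$score, -sc$score)

  expect_error(compute_risk_scores(make_signature("nope", 1), m), "nope")
})

test_that("stratification takes the top half deterministically, ties by sample id", {
  sc <- data.frame(sample = sprintf("s%02d", 1:10), score = c(10:6, 5:1) / 10)
  st <- stratify(sc)
  expect_equal(sum(st$group == "bad"), 5)
  expect_setequal(st$sample[st$group == "bad"], sprintf("s%02d", 1:5))

  odd <- stratify(data.frame(sample = letters[1:5], score = c(5, 4, 3, 2, 1)))
  expect_equal(sum(odd$group == "bad"), 2)  # floor(5/2)

  # boundary tie: identical scores, assignment resolved by id and repeatable
  tie <- data.frame(sample = c("z", "a", "m", "b"), score = c(1, 0.5, 0.5, 0.2))
  st1 <- stratify(tie)
  st2 <- stratify(tie[c(3, 1, 4, 2), ])
  expect_setequal(st1$sample[st1$group == "bad"], c("z", "a"))
  expect_setequal(st2$sample[st2$group == "bad"], c("z", "a"))
})

test_that("hub screening recovers planted drivers and stays calibrated under the null", {
  cfg <- synth_config(n_sites = 400, n_samples = 300, n_modules = 10,
                      module_size = 20, n_drivers = 20, driver_effect = 2.5,
                      seed = 17)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)

  # drivers planted among a 200-site candidate pool: strong effects retained
  pool <- union(gen$truth$drivers, rownames(gen$m)[1:200])
  sig <- screen_hubs(gen$m, clin, pool, alpha = 0.05)
  recovered <- mean(gen$truth$drivers %in% sig$entries$site)
  expect_gte(recovered, 0.8)
  expect_true(all(sig$entries$p_value < 0.05))
  expect_setequal(c(sig$positive_sites, sig$negative_sites), sig$entries$site)

  # alpha = 0: empty signature
  expect_equal(nrow(screen_hubs(gen$m, clin, pool, alpha = 0)$entries), 0)

  # permuted survival: ~5% retained
  clin_perm <- methnetprog:::with_seed(55, {
    p <- clin; p$sample <- sample(p$sample); p
  })
  sig_null <- screen_hubs(gen$m, clin_perm, rownames(gen$m), alpha = 0.05)
  expect_lt(abs(nrow(sig_null$entries) / nrow(gen$m) - 0.05), 0.035)

  expect_error(screen_hubs(gen$m, clin, c("cg_not_there"), 0.05), "absent")
})

test_that("control_signature returns the genome-wide smallest p-values", {
  cfg <- synth_config(n_sites = 150, n_samples = 120, n_modules = 5,
                      module_size = 20, n_drivers = 10, seed = 23)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)

  ctrl <- control_signature(gen$m, clin, size = 12)
  expect_equal(nrow(ctrl$entries), 12)

  # full-sort oracle: per-site fits one at a time
  p_all <- vapply(rownames(gen$m), function(s)
    cox_univariate(gen$m[s, ], clin$time_days, clin$event)$p_value, numeric(1))
  expect_setequal(ctrl$entries$site, names(sort(p_all))[1:12])

  all_sites <- control_signature(gen$m, clin, size = nrow(gen$m))
  expect_equal(nrow(all_sites$entries), nrow(gen$m))
  expect_false(is.unsorted(all_sites$entries$p_value))

  expect_error(control_signature(gen$m, clin, size = nrow(gen$m) + 1), "exceeds")
})

test_that("evaluate_signature stratifies planted-signal cohorts but not permuted ones", {
  cfg <- synth_config(n_sites = 300, n_samples = 200, n_modules = 6,
                      module_size = 30, n_drivers = 12, driver_effect = 2.5,
                      seed = 29)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)
  sig <- make_signature(gen$truth$drivers,
                        gen$truth$driver_coefficients[gen$truth$drivers])

  ev <- evaluate_signature(sig, gen$m, clin, "truth")
  expect_lt(ev$logrank$p_value, 0.01)
  expect_gt(ev$hr$hr, 1)
  expect_identical(ev$label, "truth")

  # permuted outcome: no signal
  p_null <- vapply(1:30, function(i) {
    clp <- methnetprog:::with_seed(800 + i, { p <- clin; p$sample <- sample(p$sample); p })
    evaluate_signature(sig, gen$m, clp, "null")$logrank$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
})

test_that("the fitted estimator object exposes coef/predict and is deterministic", {
  cfg <- synth_config(n_sites = 200, n_samples = 120, n_modules = 5,
                      module_size = 30, n_drivers = 10, seed = 31)
  gen <- generate_methylation(cfg)
  clin <- generate_survival(gen$m, gen$truth, cfg)
  fit1 <- methnet_fit(gen$m, clin, k = 5)
  fit2 <- methnet_fit(gen$m, clin, k = 5)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$signature$entries, fit2$signature$entries)

  sc <- predict(fit1, gen$m, type = "group")
  expect_true(all(sc$group %in% c("bad", "good")))
  expect_equal(sum(sc$group == "bad"), floor(ncol(gen$m) / 2))
  expect_true(all(fit1$signature$entries$site %in% fit1$hubs$sites))
})
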