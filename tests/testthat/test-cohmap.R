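# coherence change scores, permutation significance, change maps, ANOVA

test_that("coherence change score follows the normalized-difference formula", {
  expect_equal(coherence_change_score(rep(0.6, 4), rep(0.4, 4)), 0.2)
  expect_equal(coherence_change_score(c(0.3, 0.5), c(0.5, 0.3)), 0)
  expect_true(is.na(coherence_change_score(c(0, 0), c(0, 0))))
  expect_error(coherence_change_score(numeric(0), 0.5), "non-empty")
  expect_error(coherence_change_score(c(0.5, 1.4), c(0.2)), "\\[0, 1\\]")
})

test_that("change score is bounded and antisymmetric for random inputs", {
  set.seed(1)
  for (i in 1:500) {
    b <- runif(sample(2:10, 1))
    r <- runif(sample(2:10, 1))
    s <- coherence_change_score(b, r)
    expect_gte(s, -1); expect_lte(s, 1)
    expect_equal(coherence_change_score(r, b), -s, tolerance = 1e-12)
  }
})

test_that("identical groups are never significant; calibration is nominal", {
  x <- runif(10, 0.2, 0.8)
  res <- permutation_significance(x, x, n_perm = 500, alpha = 0.05,
                                  seed = 1)
  expect_false(res$significant)
  expect_equal(res$statistic, 0)

  # zero-variance pooled data: trivially non-significant
  z <- permutation_significance(rep(0.5, 5), rep(0.5, 5), n_perm = 200,
                                alpha = 0.05)
  expect_false(z$significant)

  # quick type-I calibration at alpha = 0.05 (fuller check in acceptance)
  set.seed(33)
  rej <- mean(vapply(1:200, function(i) {
    permutation_significance(rnorm(15), rnorm(15), n_perm = 400,
                             alpha = 0.05)$significant
  }, logical(1)))
  expect_gte(rej, qbinom(0.005, 200, 0.05) / 200)
  expect_lte(rej, qbinom(0.995, 200, 0.05) / 200)

  expect_warning(permutation_significance(rnorm(5), rnorm(5), n_perm = 50,
                                          alpha = 0.05), "coarse")
  expect_error(permutation_significance(0.5, c(0.2, 0.3), alpha = 0.05),
               "at least 2")
  expect_error(permutation_significance(rnorm(5), rnorm(5)), "alpha")
})

test_that("permutation test detects a clear group shift", {
  set.seed(12)
  hits <- mean(vapply(1:20, function(i) {
    b <- rnorm(20, mean = 1.5); r <- rnorm(20)
    permutation_significance(b, r, n_perm = 600, alpha = 0.01)$significant
  }, logical(1)))
  expect_gte(hits, 0.9)
})

test_that("ANOVA F matches brute-force mean-square arithmetic and Tukey flags the shifted group", {
  rel <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                    ratio = c(1.0, 1.1, 0.9, 1.0,
                              1.2, 1.3, 1.1, 1.2,
                              0.8, 0.7, 0.9, 0.8))
  out <- compare_epoch_coherence(rel, alpha = 0.05)
  # brute-force one-way ANOVA arithmetic
  gm <- mean(rel$ratio)
  means <- tapply(rel$ratio, rel$condition, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((rel$ratio - means[rel$condition])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(out$F_stat, f_oracle, tolerance = 1e-10)

  # all groups identical constants -> F = 0, nothing significant
  flat <- data.frame(condition = rep(c("a", "b"), each = 3), ratio = 1)
  out0 <- compare_epoch_coherence(flat, alpha = 0.05)
  expect_equal(out0$F_stat, 0)
  expect_false(any(out0$tukey$significant))

  # a condition with < 2 observations is dropped with a warning
  expect_warning(compare_epoch_coherence(
    rbind(rel, data.frame(condition = "d", ratio = 1)), alpha = 0.05),
    "dropping")
})

test_that("a 2-SD-shifted group is picked out by Tukey HSD", {
  set.seed(4)
  hit <- vapply(1:30, function(i) {
    rel <- data.frame(condition = rep(paste0("g", 1:6), each = 25),
                      ratio = rnorm(150))
    rel$ratio[rel$condition == "g3"] <- rel$ratio[rel$condition == "g3"] + 2
    out <- compare_epoch_coherence(rel, alpha = 0.05)
    sig <- out$tukey$significant
    g3 <- grepl("g3", out$tukey$comparison)
    all(sig[g3]) && !any(sig[!g3])
  }, logical(1))
  expect_gte(mean(hit), 0.85)
})

test_that("the cortico-cortical map has 1024 voxels for 32x32 sites", {
  cfg <- synth_config(seed = 17, n_trials = 2, light = NULL,
                      gamma_bands = list(low_gamma = c(45, 75)),
                      epoch_durations = c(center = 1, cue = 1, decision = 1))
  ses <- generate_dataset(cfg)
  map <- suppressWarnings(
    build_change_map(ses, "OFC", "V2", "low_gamma", "decision",
                     alpha = 0.05, n_perm = 60,
                     freqs = c(50, 60, 71), seed = 1))
  expect_s3_class(map, "coherence_change_map")
  expect_equal(dim(map$scores), c(32, 32))
  expect_equal(length(map$scores), 1024)
  expect_true(all(abs(map$scores[!is.na(map$scores)]) <= 1))
  expect_equal(dim(map$mask), dim(map$scores))
})

test_that("an injected hotspot voxel is recovered significant and positive", {
  cfg <- synth_config(seed = 23, n_trials = 12, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 4),
                                           probe_layout("V2", 1, 4)),
                      gamma_bands = list(low_gamma = c(45, 75)),
                      hotspots = list(hotspot_spec("OFC03", "V202",
                                                   "low_gamma", "decision",
                                                   coupling = 0.8)))
  ses <- generate_dataset(cfg)
  map <- build_change_map(ses, "OFC", "V2", "low_gamma", "decision",
                          alpha = 0.01, n_perm = 500, seed = 2)
  expect_true(map$mask["OFC03", "V202"])
  expect_gt(map$scores["OFC03", "V202"], 0)
  rec <- evaluate_map_recovery(map, ses$ground_truth)
  expect_equal(rec$sensitivity, 1)
  expect_lte(rec$fdp, 0.5)
})

test_that("a session missing the epoch gives an empty map with status", {
  cfg <- synth_config(seed = 2, n_trials = 2, light = NULL,
                      probe_layouts = small_pair_layouts())
  ses <- generate_dataset(cfg)
  map <- build_change_map(ses, "OFC", "V2", "low_gamma", "nonexistent",
                          alpha = 0.05, n_perm = 100)
  expect_equal(map$status, "no usable trials")
  expect_true(all(is.na(map$scores)))
  expect_false(any(map$mask))
})
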