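# spike-unit physiology: rate modulation, optotagging, CCG detection,
# waveform features, classification

# epochs with unit-duration center/decision pairs and spike counts equal to
# the requested per-trial rates
rates_session <- function(epoch_rates, base_rates) {
  n <- length(epoch_rates)
  ep <- do.call(rbind, lapply(seq_len(n), function(t) {
    t0 <- (t - 1) * 2
    data.frame(trial = t, label = c("center", "decision"),
               t_start_s = c(t0, t0 + 1), t_end_s = c(t0 + 1, t0 + 2))
  }))
  tt <- unlist(lapply(seq_len(n), function(t) {
    t0 <- (t - 1) * 2
    c(if (base_rates[t] > 0) t0 + seq_len(base_rates[t]) /
        (base_rates[t] + 1),
      if (epoch_rates[t] > 0) t0 + 1 + seq_len(epoch_rates[t]) /
        (epoch_rates[t] + 1))
  }))
  list(epochs = ep, times = sort(tt))
}

test_that("rank-sum p matches exhaustive enumeration on a 4-vs-4 table", {
  er <- c(5, 7, 9, 11); br <- c(1, 2, 3, 4)
  ses <- rates_session(er, br)
  out <- epoch_rate_modulation(ses$times, ses$epochs, "decision",
                               min_trials = 4)
  # brute-force permutation oracle over all choose(8,4) = 70 assignments
  pooled <- c(er, br)
  combs <- combn(8, 4)
  w_obs <- sum(rank(pooled)[1:4])
  w_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  p_oracle <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(out$p, p_oracle, tolerance = 1e-12)
  expect_equal(length(w_all), 70)
})

test_that("identical epoch and baseline rates give p = 1 and Z ~ 0", {
  ses <- rates_session(c(4, 5, 6, 5, 4), c(4, 5, 6, 5, 4))
  out <- epoch_rate_modulation(ses$times, ses$epochs, "decision")
  expect_gt(out$p, 0.99)
  expect_lt(abs(out$z_mean), 1e-9)
  expect_true(all(out$rates_scaled$rate_scaled >= 0 &
                    out$rates_scaled$rate_scaled <= 1))
})

test_that("a rate doubling during decision is detected across seeds", {
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = 700 + s, n_trials = 30, light = NULL,
                        probe_layouts = list(probe_layout("OFC", 1, 2)),
                        units = list(unit_spec("u", "OFC", 4,
                                               epoch_rate_mod =
                                                 list(decision = 2))))
    ep <- make_epoch_table(cfg)
    gu <- generate_units(cfg, ep)
    epoch_rate_modulation(gu$units$u, ep, "decision")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("optotag follows the 2 SD criterion and refuses scant stimuli", {
  cfg <- synth_config(seed = 5, n_trials = 2,
                      probe_layouts = list(probe_layout("BF", 1, 2)),
                      units = list(unit_spec("c1", "BF", 2.16,
                                             is_cholinergic = TRUE,
                                             light_prob = 0.8),
                                   unit_spec("n1", "BF", 5)))
  ses <- generate_dataset(cfg)
  ot <- optotag(ses$units$c1, ses$light)
  expect_true(ot$responsive)
  expect_equal(ot$direction, "up")
  expect_gt(ot$evoked_rate, ot$control_mean + 2 * ot$control_sd)
  expect_false(optotag(ses$units$n1, ses$light)$responsive)

  expect_error(optotag(ses$units$c1, ses$light[1:99, ]),
               "insufficient stimuli")
})

test_that("the optotag decision is invariant to rescaling all rates", {
  cfg <- synth_config(seed = 31, n_trials = 2,
                      probe_layouts = list(probe_layout("BF", 1, 2)),
                      units = list(unit_spec("u", "BF", 6,
                                             light_prob = 0.5)))
  ses <- generate_dataset(cfg)
  tt <- ses$units$u$spike_times
  le <- ses$light
  base <- optotag(tt, le)
  for (c_mult in c(0.5, 3)) {
    le2 <- data.frame(t_s = le$t_s / c_mult,
                      duration_s = le$duration_s / c_mult)
    scaled <- optotag(tt / c_mult, le2,
                      response_window = le$duration_s[1] / c_mult,
                      control_window = 2 / c_mult)
    expect_equal(scaled$responsive, base$responsive)
    expect_equal(scaled$evoked_rate, base$evoked_rate * c_mult,
                 tolerance = 1e-9)
  }
})

test_that("CCG thresholds equal the brute-force Poisson quantile oracle", {
  set.seed(8)
  lams <- runif(300, 0.01, 30)
  oracle_q <- function(lambda, q) {
    k <- 0; acc <- dpois(0, lambda)
    while (acc < q) { k <- k + 1; acc <- acc + dpois(k, lambda) }
    k
  }
  th <- ccg_poisson_threshold(lams, 0.9999)
  expect_equal(th$upper,
               vapply(lams, oracle_q, numeric(1), q = 0.9999))
  expect_equal(th$lower,
               vapply(lams, oracle_q, numeric(1), q = 1 - 0.9999))
})

test_that("CCG is lag-symmetric under swapping the trains", {
  set.seed(3)
  a <- sort(runif(800, 0, 100)); b <- sort(runif(900, 0, 100))
  ab <- cross_correlogram(a, b)
  ba <- cross_correlogram(b, a)
  expect_equal(ab$counts, rev(ba$counts))
  expect_equal(sum(ab$counts), sum(ba$counts))
})

test_that("independent Poisson trains yield no detected connection", {
  set.seed(14)
  det <- vapply(1:15, function(i) {
    a <- cumsum(rexp(3000, 5)); b <- cumsum(rexp(3000, 5))
    ccg_detect(a, b)$detected
  }, logical(1))
  expect_false(any(det))
})

test_that("an injected excitatory coupling is detected at its lag", {
  cfg <- synth_config(seed = 3, n_trials = 50, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("u1", "OFC", 5),
                                   unit_spec("u2", "OFC", 5)),
                      couplings = list(coupling_spec("u1", "u2",
                                                     "excitatory",
                                                     efficacy = 0.2,
                                                     lag_ms = 2.5)))
  gu <- generate_units(cfg)
  expect_gt(length(gu$units$u1$spike_times), 3000)
  cr <- ccg_detect(gu$units$u1, gu$units$u2)
  expect_true(cr$detected)
  expect_equal(cr$sign, "excitatory")
  expect_true(any(abs(cr$significant_bins$lag_ms - 2.5) <= 1))

  inh <- synth_config(seed = 4, n_trials = 50, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("a", "OFC", 8),
                                   unit_spec("b", "OFC", 8)),
                      couplings = list(coupling_spec("a", "b", "inhibitory",
                                                     efficacy = 1,
                                                     lag_ms = 3,
                                                     jitter_ms = 1.5)))
  gi <- generate_units(inh)
  ci <- ccg_detect(gi$units$a, gi$units$b)
  expect_equal(ci$sign, "inhibitory")

  expect_error(ccg_detect(cumsum(rexp(50, 5)), cumsum(rexp(200, 5))),
               "at least")
  expect_error(ccg_detect(1:200, 1:200 + 1e4), "overlap")
})

test_that("burst index is the 3-5 ms over 200-300 ms count ratio", {
  edges <- seq(0, 0.3, by = 1e-3)
  counts <- rep(10, 300)
  expect_equal(burst_index_from_acg(counts, edges), 1)
  counts2 <- counts
  counts2[4:5] <- 20        # bins [3,4) and [4,5) ms
  expect_equal(burst_index_from_acg(counts2, edges), 2)
  # zero baseline -> undefined
  expect_true(is.na(burst_index_from_acg(c(rep(5, 200), rep(0, 100)),
                                         edges)))
})

test_that("trough-to-peak latency reads 0.6 ms for the wide template", {
  for (tpl in list(c("wide", 0.6), c("narrow", 0.25))) {
    u <- spike_unit(tpl[1], "OFC", c(1, 2),
                    waveform = matrix(waveform_template(tpl[1]), 1,
                                      dimnames = list("OFC01", NULL)),
                    peak_channel = "OFC01")
    expect_equal(waveform_features(u)$tp_latency_ms, as.numeric(tpl[2]))
  }
})

test_that("waveform PCA matches an eigen-decomposition oracle and separates families", {
  cfg <- synth_config(seed = 2, n_trials = 1, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 4)),
                      units = c(lapply(1:4, function(i) {
                        unit_spec(paste0("w", i), "OFC", 5, "wide")
                      }), lapply(1:4, function(i) {
                        unit_spec(paste0("n", i), "OFC", 5, "narrow")
                      })))
  gu <- generate_units(cfg)
  pca <- waveform_pca(gu$units)
  fam <- substr(pca$unit, 1, 1)
  expect_true(all(sign(pca$w_pca1[fam == "w"]) ==
                    sign(pca$w_pca1[fam == "w"][1])))
  expect_true(all(sign(pca$w_pca1[fam == "n"]) !=
                    sign(pca$w_pca1[fam == "w"][1])))

  # oracle: same documented transform, projected via eigen() instead of svd
  rows <- lapply(gu$units, function(u) {
    w <- u$waveform[which.max(apply(abs(u$waveform), 1, max)), ]
    up <- spline(seq_along(w), w, xout = seq(1, length(w), by = 1 / 5))$y
    d2 <- diff(diff(up))
    it <- which.min(up)
    d2[it:(it + 80)]
  })
  X <- do.call(rbind, rows)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc))
  oracle <- Xc %*% ev$vectors[, 1:2]
  expect_equal(abs(unname(cbind(pca$w_pca1, pca$w_pca2))), abs(oracle),
               tolerance = 1e-6, ignore_attr = TRUE)

  # identical waveforms -> all scores 0
  same <- lapply(1:4, function(i) {
    spike_unit(paste0("s", i), "OFC", c(1, 2),
               waveform = matrix(waveform_template("wide"), 1,
                                 dimnames = list("OFC01", NULL)),
               peak_channel = "OFC01")
  })
  p0 <- waveform_pca(same)
  expect_equal(max(abs(c(p0$w_pca1, p0$w_pca2))), 0, tolerance = 1e-9)
})

test_that("k-means recovers well-separated clusters and is order-invariant", {
  set.seed(6)
  centers <- matrix(rnorm(18, sd = 5), 6, 3)
  truth <- rep(1:6, each = 20)
  X <- centers[truth, ] + matrix(rnorm(360), 120, 3)
  feats <- data.frame(unit = sprintf("u%03d", 1:120),
                      tp_latency_ms = X[, 1], w_pca1 = X[, 2],
                      w_pca2 = X[, 3], mean_rate = 5)
  km <- classify_units(feats, k = 6, seed = 3)
  expect_gte(adjusted_rand_index(km$labels, truth), 0.95)

  perm <- sample(120)
  km2 <- classify_units(feats[perm, ], k = 6, seed = 3)
  expect_equal(adjusted_rand_index(km$labels[perm], km2$labels), 1)

  # all-identical features: one stable occupied cluster
  flat <- feats; flat[, 2:4] <- 0; flat$tp_latency_ms <- 0.5
  expect_warning(kf <- classify_units(flat, k = 6, seed = 1), "distinct")
  expect_equal(length(unique(kf$labels)), 1)

  expect_error(classify_units(feats[1:4, ], k = 6), "exceeds")
})

test_that("bagged trees validate separable labels and predict cholinergic units as wide", {
  set.seed(9)
  centers <- matrix(rnorm(18, sd = 6), 6, 3)
  truth <- rep(1:6, each = 25)
  X <- centers[truth, ] + matrix(rnorm(450, sd = 0.5), 150, 3)
  feats <- data.frame(unit = sprintf("u%03d", 1:150),
                      tp_latency_ms = X[, 1], w_pca1 = X[, 2],
                      w_pca2 = X[, 3], mean_rate = rnorm(150, 5))
  labels <- setNames(truth, feats$unit)
  bt <- crossvalidate_bagged_tree(feats, labels, seed = 2)
  expect_gte(bt$oob_accuracy, 0.95)

  # shuffled labels -> chance-level out-of-bag accuracy
  sh <- setNames(sample(truth), feats$unit)
  bt0 <- crossvalidate_bagged_tree(feats, sh, seed = 2)
  expect_lt(abs(bt0$oob_accuracy - 1 / 6), 0.12)

  # generator-built wide/narrow units; held-out wide "cholinergic" units
  # must be predicted into a wide-dominated cluster
  cfg <- synth_config(seed = 12, n_trials = 20, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 4),
                                           probe_layout("BF", 1, 4)),
                      units = c(
                        lapply(1:8, function(i) {
                          unit_spec(paste0("w", i), "OFC", 4, "wide")
                        }),
                        lapply(1:8, function(i) {
                          unit_spec(paste0("n", i), "OFC", 9, "narrow")
                        }),
                        lapply(1:3, function(i) {
                          unit_spec(paste0("c", i), "BF", 2.16, "wide",
                                    is_cholinergic = TRUE)
                        })))
  gu <- generate_units(cfg)
  f <- compute_unit_features(gu$units)
  km <- classify_units(f, k = 2, seed = 4)
  bt2 <- crossvalidate_bagged_tree(f, km$labels, seed = 5)
  wide_cluster <- unique(km$labels[paste0("w", 1:8)])
  expect_length(wide_cluster, 1)
  expect_true(all(bt2$predicted_cholinergic == wide_cluster))
})
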