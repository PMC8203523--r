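# synthetic-data generator: determinism, rate fidelity, injected-effect
# bookkeeping, probe complement, and coupling/light mechanics

test_that("identical config and seed give a bit-identical dataset", {
  cfg <- synth_config(seed = 9, n_trials = 2,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("u", "OFC", 3)),
                      light = light_spec(n_trains = 2))
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$lfp$samples, s2$lfp$samples)
  expect_identical(s1$units$u$spike_times, s2$units$u$spike_times)
  expect_identical(s1$units$u$waveform, s2$units$u$waveform)
  expect_identical(s1$epochs, s2$epochs)
})

test_that("realized firing rates stay within 3 SE of their specification", {
  # ~630 s session so the Poisson rate estimate is tight
  cfg <- synth_config(seed = 21, n_trials = 45, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("a", "OFC", 2.16),
                                   unit_spec("b", "OFC", 5),
                                   unit_spec("c", "OFC", 10)))
  ep <- make_epoch_table(cfg)
  dur <- max(ep$t_end_s)
  expect_gte(dur, 600)
  gu <- generate_units(cfg, ep)
  for (u in gu$units) {
    spec_rate <- c(a = 2.16, b = 5, c = 10)[[u$id]]
    realized <- length(u$spike_times) / dur
    se <- sqrt(spec_rate / dur)
    expect_lt(abs(realized - spec_rate), 3 * se)
  }
})

test_that("every injected effect is logged exactly once and absent lists stay empty", {
  hs <- list(hotspot_spec("OFC01", "V201", "low_gamma", "decision", 0.8))
  cp <- list(coupling_spec("a", "b", "excitatory", efficacy = 0.3))
  se <- list(sta_effect_spec("a", "V201", "low_gamma", gain = 2))
  cfg <- synth_config(seed = 5, n_trials = 3,
                      probe_layouts = small_pair_layouts(),
                      hotspots = hs, couplings = cp, sta_effects = se,
                      units = list(unit_spec("a", "OFC", 5,
                                             is_cholinergic = TRUE),
                                   unit_spec("b", "V2", 5)),
                      light = NULL)
  gu <- generate_units(cfg)
  gt <- gu$ground_truth
  expect_equal(nrow(gt$hotspots), 1)
  expect_equal(nrow(gt$couplings), 1)
  expect_equal(nrow(gt$sta_effects), 1)
  expect_equal(gt$cholinergic_units, "a")

  empty <- generate_units(synth_config(seed = 5, n_trials = 1,
                                       probe_layouts = small_pair_layouts(),
                                       light = NULL))
  expect_equal(nrow(empty$ground_truth$hotspots), 0)
  expect_equal(nrow(empty$ground_truth$couplings), 0)
  expect_equal(length(empty$units), 0)
})

test_that("excitatory insertions match efficacy and land near the lag", {
  cfg <- synth_config(seed = 3, n_trials = 50, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("u1", "OFC", 5),
                                   unit_spec("u2", "OFC", 5)),
                      couplings = list(coupling_spec("u1", "u2",
                                                     "excitatory",
                                                     efficacy = 0.2,
                                                     lag_ms = 2.5)))
  gu <- generate_units(cfg)
  n_pre <- length(gu$units$u1$spike_times)
  n_ins <- gu$ground_truth$couplings$n_inserted
  # binomial: inserted ~ Binom(n_pre, 0.2)
  expect_lt(abs(n_ins - 0.2 * n_pre), 4 * sqrt(n_pre * 0.2 * 0.8))
  cc <- cross_correlogram(gu$units$u1, gu$units$u2)
  peak_bin <- cc$centers[which.max(cc$counts)] * 1000
  expect_lt(abs(peak_bin - 2.5), 1)
})

test_that("inhibitory coupling at efficacy 1 empties the deletion window", {
  cfg <- synth_config(seed = 4, n_trials = 40, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)),
                      units = list(unit_spec("a", "OFC", 8),
                                   unit_spec("b", "OFC", 8)),
                      couplings = list(coupling_spec("a", "b", "inhibitory",
                                                     efficacy = 1,
                                                     lag_ms = 3,
                                                     jitter_ms = 1.5)))
  gu <- generate_units(cfg)
  pre <- gu$units$a$spike_times
  post <- gu$units$b$spike_times
  # no post spike may survive inside (lag - jitter, lag + jitter) after a pre
  lags <- unlist(lapply(pre, function(t0) {
    d <- post - t0
    d[d > 0.0015 & d < 0.0045]
  }))
  expect_length(lags, 0)
})

test_that("light-unresponsive units show no evoked response", {
  cfg <- synth_config(seed = 6, n_trials = 1,
                      probe_layouts = list(probe_layout("BF", 1, 2)),
                      units = list(unit_spec("n", "BF", 5, light_prob = 0)))
  ep <- make_epoch_table(cfg)
  le <- make_light_events(cfg, ep)
  gu <- generate_units(cfg, ep, le)
  ot <- optotag(gu$units$n, le)
  expect_false(ot$responsive)
})

test_that("default probe complement is BF 64 + OFC 32 + V2 32 channels", {
  cfg <- synth_config(seed = 1, n_trials = 1, light = light_spec(n_trains = 3))
  ses <- generate_dataset(cfg)
  tab <- table(ses$lfp$channels$region)
  expect_equal(unname(tab[c("BF", "OFC", "V2")]), c(64L, 32L, 32L),
               ignore_attr = TRUE)
  expect_equal(ncol(ses$lfp$samples), 128)
  expect_false(anyDuplicated(ses$lfp$channels$id) > 0)
  # epochs tile the trial contiguously with the 4-s cue
  e1 <- ses$epochs[!is.na(ses$epochs$trial) & ses$epochs$trial == 1, ]
  expect_equal(e1$label[1:6],
               c("center", "cue", "decision", "approach", "consume",
                 "return"))
  expect_equal(e1$t_end_s[2] - e1$t_start_s[2], 4)
  expect_equal(e1$t_start_s[-1], e1$t_end_s[-6])
  expect_gte(nrow(ses$light), 100)
})

test_that("zero-trial config yields an empty epoch table but valid files", {
  cfg <- synth_config(seed = 2, n_trials = 0, light = NULL,
                      probe_layouts = list(probe_layout("OFC", 1, 2)))
  ses <- generate_dataset(cfg)
  expect_equal(nrow(ses$epochs), 0)
  expect_equal(nrow(ses$lfp$samples), 0)
  dir <- withr::local_tempdir()
  expect_no_error(write_dataset(ses, dir))
})

test_that("a hotspot raises epoch coherence above the center baseline", {
  cfg <- synth_config(seed = 8, n_trials = 6, light = NULL,
                      probe_layouts = small_pair_layouts(),
                      hotspots = list(hotspot_spec("OFC01", "V201",
                                                   "low_gamma", "decision",
                                                   coupling = 0.9)))
  ses <- generate_dataset(cfg)
  cs <- wavelet_coherence(ses$lfp, "OFC01", "V201", "low_gamma")
  iv <- function(lab) {
    e <- ses$epochs[ses$epochs$label == lab, ]
    lapply(seq_len(nrow(e)), function(i) c(e$t_start_s[i], e$t_end_s[i]))
  }
  expect_gt(band_average(cs, interval = iv("decision")),
            band_average(cs, interval = iv("center")) + 0.1)
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(synth_config(gamma_bands = list(bad = c(45, 700))),
               "Nyquist")
  expect_error(coupling_spec("a", "b", "excitatory", efficacy = 0),
               "efficacy")
  expect_error(coupling_spec("a", "b", "excitatory", efficacy = 1.2),
               "efficacy")
  expect_error(synth_config(units = list(unit_spec("u", "OFC", 5)),
                            couplings = list(coupling_spec("u", "zz",
                                                           "excitatory",
                                                           0.5))),
               "unknown unit")
  expect_error(synth_config(epoch_durations = c(center = 0, cue = 4)),
               "> 0")
})
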