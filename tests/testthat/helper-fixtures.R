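# shared fixture builders; everything is generated in code at test time

# small white-noise recording
tiny_rec <- function(n = 4000, nch = 2, rate = 1250, seed = 1,
                     region = rep("OFC", nch)) {
  set.seed(seed)
  ch <- data.frame(id = sprintf("%s%02d", region, seq_len(nch)),
                   region = region, shank = 1L, site = seq_len(nch),
                   depth_um = 0, stringsAsFactors = FALSE)
  lfp_recording(matrix(rnorm(n * nch), n, nch), rate, ch)
}

# minimal two-region probe set (2 sites each) for fast coherence sessions
small_pair_layouts <- function(sites = 2) {
  list(probe_layout("OFC", 1, sites), probe_layout("V2", 1, sites))
}

# hand-built coherence series for band_average oracle checks
manual_coh_series <- function(values, rate = 10) {
  structure(list(values = values, time = (seq_along(values) - 1) / rate,
                 valid = rep(TRUE, length(values)), pair = c("a", "b"),
                 band = NULL, rate = rate),
            class = "coherence_series")
}

# crafted STA result table: n_sig significant sites out of n for one
# (unit, region, band) group
fake_sta_results <- function(unit, region, band, n_sig, n = 32) {
  data.frame(unit = unit, channel = sprintf("%s%02d", region, seq_len(n)),
             region = region, band = band, n_spikes = 100,
             D = 0.1, p = 0.5, diff_score = 0,
             significant = c(rep(TRUE, n_sig), rep(FALSE, n - n_sig)),
             stringsAsFactors = FALSE)
}
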