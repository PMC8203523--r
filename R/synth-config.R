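# configuration objects for the synthetic-recording generator

#' Probe layout description
#'
#' Geometry of one silicon probe: the basal-forebrain probe carries 64 sites
#' on 8 shanks (8 sites per shank); each cortical probe carries 32 sites on
#' 4 shanks with 100 um vertical site separation.
#'
#' @param region One of `"BF"`, `"OFC"`, `"V2"` (other labels allowed).
#' @param n_shanks Number of shanks.
#' @param sites_per_shank Recording sites per shank.
#' @param vertical_pitch Vertical site separation in um.
#' @param shank_pitch Horizontal shank separation in um.
#' @return Object of class `probe_layout`.
#' @export
probe_layout <- function(region, n_shanks, sites_per_shank = 8,
                         vertical_pitch = 100, shank_pitch = 200) {
  stopifnot(n_shanks >= 1, sites_per_shank >= 1,
            vertical_pitch > 0, shank_pitch > 0)
  structure(list(region = region, n_shanks = as.integer(n_shanks),
                 sites_per_shank = as.integer(sites_per_shank),
                 vertical_pitch = vertical_pitch, shank_pitch = shank_pitch),
            class = "probe_layout")
}

#' Default probe complement: BF 8x8, OFC 4x8, V2 4x8
#' @return List of three [probe_layout()] objects (128 channels total).
#' @export
default_probe_layouts <- function() {
  list(probe_layout("BF", 8), probe_layout("OFC", 4), probe_layout("V2", 4))
}

# channel table for a set of layouts: one row per recording site
channel_table <- function(layouts) {
  do.call(rbind, lapply(layouts, function(p) {
    n <- p$n_shanks * p$sites_per_shank
    shank <- rep(seq_len(p$n_shanks), each = p$sites_per_shank)
    site <- rep(seq_len(p$sites_per_shank), times = p$n_shanks)
    data.frame(
      id = sprintf("%s%02d", p$region, seq_len(n)),
      region = p$region, shank = shank, site = site,
      depth_um = (site - 1) * p$vertical_pitch,
      x_um = (shank - 1) * p$shank_pitch,
      stringsAsFactors = FALSE)
  }))
}

#' Coherence hotspot specification
#'
#' Declares a shared narrow-band gamma source injected into a channel pair
#' during one behavioral epoch, producing a localized coherence increase
#' relative to the center/rest baseline.
#'
#' @param channel_a,channel_b Channel ids (as in the generated channel table).
#' @param band Band label (default bands: `"low_gamma"`, `"high_gamma"`).
#' @param epoch Epoch label during which the shared source is active.
#' @param coupling Amplitude fraction in `[0, 1]` of the shared source; the
#'   independent band noise is scaled by `sqrt(1 - coupling^2)` during the
#'   epoch so total band power is unchanged.
#' @param lag_ms Delay of the shared source on `channel_b` (ms).
#' @return Object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(channel_a, channel_b, band = "low_gamma",
                         epoch = "decision", coupling = 0.8, lag_ms = 0) {
  stopifnot(coupling >= 0, coupling <= 1)
  structure(list(channel_a = channel_a, channel_b = channel_b, band = band,
                 epoch = epoch, coupling = coupling, lag_ms = lag_ms),
            class = "hotspot_spec")
}

#' Synthetic spike-unit specification
#'
#' @param id Unit id (character or integer).
#' @param region Region label; the unit's waveform is placed on a shank of
#'   this region's probe.
#' @param rate_hz Mean firing rate (Hz). Cholinergic units default to about
#'   2 Hz in the synthetic sessions.
#' @param template Waveform template: `"wide"` (trough-to-peak 0.6 ms) or
#'   `"narrow"` (0.25 ms).
#' @param is_cholinergic Logical tag carried into the ground truth.
#' @param light_prob Probability of one extra evoked spike per 10-ms light
#'   pulse (0 = unresponsive).
#' @param epoch_rate_mod Named list of multiplicative rate factors per epoch
#'   label (unlisted epochs keep the base rate).
#' @return Object of class `unit_spec`.
#' @export
unit_spec <- function(id, region, rate_hz, template = c("wide", "narrow"),
                      is_cholinergic = FALSE, light_prob = 0,
                      epoch_rate_mod = list()) {
  template <- match.arg(template)
  stopifnot(rate_hz > 0, light_prob >= 0, light_prob <= 1)
  structure(list(id = as.character(id), region = region, rate_hz = rate_hz,
                 template = template, is_cholinergic = is_cholinergic,
                 light_prob = light_prob, epoch_rate_mod = epoch_rate_mod),
            class = "unit_spec")
}

#' Pairwise spike-coupling specification
#'
#' Excitatory couplings insert, for each presynaptic spike and with
#' probability `efficacy`, one postsynaptic spike at `lag_ms` (+/- Gaussian
#' jitter). Inhibitory couplings delete, with probability `efficacy`,
#' postsynaptic spikes falling in `(lag_ms - jitter_ms, lag_ms + jitter_ms)`
#' after a presynaptic spike. Lags are constrained to the 1.5--5 ms window the
#' cross-correlogram detector scans.
#'
#' @param pre,post Unit ids.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @param efficacy Coupling probability in `(0, 1]`.
#' @param lag_ms Synaptic lag in ms.
#' @param jitter_ms Jitter SD (excitatory) / half-width (inhibitory), ms.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(pre, post, sign = c("excitatory", "inhibitory"),
                          efficacy, lag_ms = 2.5, jitter_ms = 0.2) {
  sign <- match.arg(sign)
  if (!(efficacy > 0 && efficacy <= 1)) {
    stop("coupling efficacy must lie in (0, 1]")
  }
  if (lag_ms < 1 || lag_ms > 6) {
    stop("coupling lag_ms must lie in the short-latency window [1, 6] ms")
  }
  structure(list(pre = as.character(pre), post = as.character(post),
                 sign = sign, efficacy = efficacy, lag_ms = lag_ms,
                 jitter_ms = jitter_ms),
            class = "coupling_spec")
}

#' Spike-triggered gamma modulation specification
#'
#' After each spike of `unit`, the band-limited gamma component of the target
#' channels is multiplied by `gain` for the following 500 ms, emulating a
#' cholinergic cell that modulates gamma power at specific cortical sites.
#'
#' @param unit Trigger unit id.
#' @param channels Character vector of target channel ids.
#' @param band Band label.
#' @param gain Multiplicative amplitude gain (> 0) applied on (0, +500 ms].
#' @param window_s Post-spike window length in seconds.
#' @return Object of class `sta_effect_spec`.
#' @export
sta_effect_spec <- function(unit, channels, band = "low_gamma", gain = 2,
                            window_s = 0.5) {
  stopifnot(gain > 0, window_s > 0)
  structure(list(unit = as.character(unit), channels = as.character(channels),
                 band = band, gain = gain, window_s = window_s),
            class = "sta_effect_spec")
}

#' Light-stimulation protocol
#'
#' Post-session optogenetic tagging block: trains of 10-ms pulses delivered
#' for 2 s per train. The inter-pulse interval within a train is not a fixed
#' property of the protocol and is therefore a parameter; the default (50 ms
#' period, i.e. 20 Hz for 2 s, 10 trains) yields 400 pulses, comfortably
#' above the >= 100 stimuli required for tagging.
#'
#' @param pulse_width_s Pulse duration (s).
#' @param pulse_period_s Within-train pulse period (s).
#' @param train_duration_s Train length (s).
#' @param n_trains Number of trains.
#' @param inter_train_s Gap between trains (s).
#' @return Object of class `light_spec`.
#' @export
light_spec <- function(pulse_width_s = 0.010, pulse_period_s = 0.050,
                       train_duration_s = 2, n_trains = 10,
                       inter_train_s = 3) {
  stopifnot(pulse_width_s > 0, pulse_period_s >= pulse_width_s,
            train_duration_s > 0, n_trains >= 0, inter_train_s >= 0)
  structure(list(pulse_width_s = pulse_width_s,
                 pulse_period_s = pulse_period_s,
                 train_duration_s = train_duration_s,
                 n_trains = as.integer(n_trains),
                 inter_train_s = inter_train_s),
            class = "light_spec")
}

#' Default behavioral epoch durations (seconds)
#'
#' Each trial is divided into six periods: center/rest, cue presentation
#' (4 s), decision making, reward approach, consumption, and return.
#' Durations other than the 4-s cue are representative task values.
#'
#' @return Named numeric vector of epoch durations in seconds.
#' @export
default_epoch_durations <- function() {
  c(center = 2, cue = 4, decision = 2, approach = 2, consume = 2,
    "return" = 2)
}

#' Synthetic-session configuration
#'
#' Bundles every parameter of the synthetic recording generator: probe
#' geometry, trial/epoch structure, LFP noise model, gamma bands, injected
#' coherence hotspots, spike units, pairwise couplings, spike-triggered gamma
#' effects, and the light-stimulation protocol. A fixed `seed` makes the
#' generated dataset fully reproducible.
#'
#' @param seed Integer RNG seed.
#' @param n_trials Number of behavioral trials.
#' @param epoch_durations Named vector of per-epoch durations (s).
#' @param probe_layouts List of [probe_layout()] objects.
#' @param lfp_rate LFP sampling rate in Hz (1250 after decimation).
#' @param noise_exponent Spectral slope of the 1/f background.
#' @param gamma_bands Named list of band edges (Hz).
#' @param background_sd SD (uV) of the 1/f background per channel.
#' @param gamma_sd SD (uV) of each channel's independent band-limited gamma
#'   noise, per band.
#' @param hotspots List of [hotspot_spec()].
#' @param units List of [unit_spec()].
#' @param couplings List of [coupling_spec()].
#' @param sta_effects List of [sta_effect_spec()].
#' @param light [light_spec()] or `NULL` for no tagging block.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_trials = 30,
                         epoch_durations = default_epoch_durations(),
                         probe_layouts = default_probe_layouts(),
                         lfp_rate = 1250, noise_exponent = 1,
                         gamma_bands = default_gamma_bands(),
                         background_sd = 10, gamma_sd = 5,
                         hotspots = list(), units = list(),
                         couplings = list(), sta_effects = list(),
                         light = light_spec()) {
  stopifnot(n_trials >= 0, lfp_rate > 0, background_sd >= 0, gamma_sd >= 0)
  if (any(epoch_durations <= 0)) stop("all epoch durations must be > 0")
  for (b in gamma_bands) {
    if (!(b[1] > 0 && b[2] > b[1] && b[2] < lfp_rate / 2)) {
      stop("band edges must satisfy 0 < f_lo < f_hi < lfp_rate/2 (Nyquist)")
    }
  }
  unit_ids <- vapply(units, function(u) u$id, character(1))
  if (anyDuplicated(unit_ids)) stop("duplicate unit ids in config")
  for (cp in couplings) {
    if (!all(c(cp$pre, cp$post) %in% unit_ids)) {
      stop("coupling references unknown unit id")
    }
  }
  for (e in sta_effects) {
    if (!e$unit %in% unit_ids) stop("sta effect references unknown unit id")
    if (!e$band %in% names(gamma_bands)) {
      stop("sta effect band '", e$band, "' not in gamma_bands")
    }
  }
  for (h in hotspots) {
    if (!h$band %in% names(gamma_bands)) {
      stop("hotspot band '", h$band, "' not in gamma_bands")
    }
    if (!h$epoch %in% names(epoch_durations)) {
      stop("hotspot epoch '", h$epoch, "' not an epoch label")
    }
  }
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 epoch_durations = epoch_durations,
                 probe_layouts = probe_layouts, lfp_rate = lfp_rate,
                 noise_exponent = noise_exponent, gamma_bands = gamma_bands,
                 background_sd = background_sd, gamma_sd = gamma_sd,
                 hotspots = hotspots, units = units, couplings = couplings,
                 sta_effects = sta_effects, light = light),
            class = "synth_config")
}

#' Build the per-trial epoch table for a configuration
#'
#' Trials tile the session contiguously in the fixed epoch order
#' center -> cue -> decision -> approach -> consume -> return; when a light
#' protocol is configured, a single `optostim` epoch is appended after the
#' last trial.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `trial`, `label`, `t_start_s`, `t_end_s`;
#'   intervals are half-open `[start, end)`.
#' @export
make_epoch_table <- function(config) {
  durs <- config$epoch_durations
  labels <- names(durs)
  rows <- vector("list", config$n_trials + 1L)
  t <- 0
  if (config$n_trials > 0) {
    for (tr in seq_len(config$n_trials)) {
      starts <- t + cumsum(c(0, unname(durs)[-length(durs)]))
      rows[[tr]] <- data.frame(trial = tr, label = labels,
                               t_start_s = starts,
                               t_end_s = starts + unname(durs),
                               stringsAsFactors = FALSE)
      t <- t + sum(durs)
    }
  }
  if (!is.null(config$light) && config$light$n_trains > 0) {
    dur <- config$light$n_trains *
      (config$light$train_duration_s + config$light$inter_train_s)
    rows[[config$n_trials + 1L]] <-
      data.frame(trial = NA_integer_, label = "optostim",
                 t_start_s = t, t_end_s = t + dur, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(trial = integer(0), label = character(0),
                      t_start_s = numeric(0), t_end_s = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Light-pulse onset table for a configuration
#'
#' @param config A [synth_config()].
#' @param epochs Epoch table from [make_epoch_table()] (regenerated if
#'   missing); pulses are laid out inside its `optostim` epoch.
#' @return Data frame with columns `t_s` (pulse onset) and `duration_s`.
#' @export
make_light_events <- function(config, epochs = make_epoch_table(config)) {
  ls <- config$light
  opto <- epochs[epochs$label == "optostim", , drop = FALSE]
  if (is.null(ls) || ls$n_trains == 0 || nrow(opto) == 0) {
    return(data.frame(t_s = numeric(0), duration_s = numeric(0)))
  }
  per_train <- floor(ls$train_duration_s / ls$pulse_period_s)
  onsets <- unlist(lapply(seq_len(ls$n_trains) - 1L, function(k) {
    t0 <- opto$t_start_s[1] + k * (ls$train_duration_s + ls$inter_train_s)
    t0 + (seq_len(per_train) - 1L) * ls$pulse_period_s
  }))
  data.frame(t_s = onsets, duration_s = ls$pulse_width_s)
}
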