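# synthetic spike-unit generation: Poisson base trains with epoch-dependent
# rates, light-evoked spikes, and pairwise excitatory/inhibitory couplings

#' Extracellular waveform templates
#'
#' Biphasic mean-waveform templates at 20 kHz (32 samples): the wide template
#' has its global trough at sample 11 and subsequent peak at sample 23
#' (trough-to-peak 12 samples = 0.6 ms, matching wide/putative-excitatory
#' cells); the narrow template peaks 5 samples after the trough (0.25 ms).
#'
#' @param template `"wide"` or `"narrow"`.
#' @param n_samples Samples per waveform.
#' @param rate Waveform sampling rate (Hz).
#' @return Numeric vector of length `n_samples` (unit trough depth).
#' @export
waveform_template <- function(template = c("wide", "narrow"), n_samples = 32,
                              rate = 20000) {
  template <- match.arg(template)
  i <- seq_len(n_samples)
  trough <- 11
  if (template == "wide") {
    peak <- 23; s_t <- 2.2; s_p <- 4.0; a_p <- 0.45
  } else {
    peak <- 16; s_t <- 1.5; s_p <- 2.0; a_p <- 0.50
  }
  w <- -exp(-((i - trough)^2) / (2 * s_t^2)) +
    a_p * exp(-((i - peak)^2) / (2 * s_p^2))
  attr(w, "rate") <- rate
  w
}

# multi-site mean waveform on one shank: template on the peak site with
# amplitude decaying over neighbouring sites, plus small seeded perturbation
make_unit_waveform <- function(spec, chtab, amp_uv = 120, noise_sd = 0.005) {
  reg <- chtab[chtab$region == spec$region, , drop = FALSE]
  if (nrow(reg) == 0) stop("unit region '", spec$region, "' has no channels")
  peak_row <- reg[sample.int(nrow(reg), 1), ]
  shank <- reg[reg$shank == peak_row$shank, , drop = FALSE]
  shank <- shank[order(shank$site), , drop = FALSE]
  tmpl <- waveform_template(spec$template)
  prof <- 1 / (1 + ((shank$site - peak_row$site) / 1.2)^2)
  wf <- outer(prof, as.numeric(tmpl)) * amp_uv
  wf <- wf + matrix(rnorm(length(wf), sd = noise_sd * amp_uv), nrow(wf))
  rownames(wf) <- shank$id
  list(waveform = wf, peak_channel = peak_row$id)
}

#' Spike-unit container
#'
#' @param id Unit id.
#' @param region Region label.
#' @param spike_times Strictly increasing spike times (s).
#' @param waveform Mean waveform matrix, channel x sample (uV), rows named by
#'   channel id.
#' @param peak_channel Channel id with the largest waveform deviation.
#' @param waveform_rate Waveform sampling rate (Hz), 20 kHz by default.
#' @param is_cholinergic Logical tag.
#' @param template Template label used by the generator (or `NA`).
#' @return Object of class `spike_unit`.
#' @export
spike_unit <- function(id, region, spike_times, waveform = NULL,
                       peak_channel = NULL, waveform_rate = 20000,
                       is_cholinergic = FALSE, template = NA_character_) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing (unit ", id, ")")
  }
  structure(list(id = as.character(id), region = region,
                 spike_times = spike_times, waveform = waveform,
                 peak_channel = peak_channel, waveform_rate = waveform_rate,
                 mean_rate = if (length(spike_times) > 1) {
                   length(spike_times) / diff(range(spike_times))
                 } else NA_real_,
                 is_cholinergic = is_cholinergic, template = template),
            class = "spike_unit")
}

#' @export
print.spike_unit <- function(x, ...) {
  cat(sprintf("<spike_unit> %s (%s) %d spikes, %.2f Hz%s\n", x$id, x$region,
              length(x$spike_times),
              if (is.na(x$mean_rate)) NA else x$mean_rate,
              if (isTRUE(x$is_cholinergic)) ", cholinergic" else ""))
  invisible(x)
}

# inhomogeneous (piecewise-constant over epochs) Poisson train
poisson_train <- function(spec, epochs) {
  times <- numeric(0)
  for (i in seq_len(nrow(epochs))) {
    mult <- spec$epoch_rate_mod[[epochs$label[i]]]
    lam <- spec$rate_hz * (if (is.null(mult)) 1 else mult)
    dur <- epochs$t_end_s[i] - epochs$t_start_s[i]
    k <- rpois(1, lam * dur)
    if (k > 0) times <- c(times, epochs$t_start_s[i] + sort(runif(k, 0, dur)))
  }
  times
}

#' Generate synthetic spike units and the session ground truth
#'
#' Base trains are Poisson at each unit's rate, modulated per epoch by the
#' unit's `epoch_rate_mod`. Light-responsive units emit one extra spike with
#' probability `light_prob` during each 10-ms pulse. Excitatory couplings
#' insert post-unit spikes at `lag +/- jitter` for a fraction `efficacy` of
#' pre-unit spikes; inhibitory couplings delete post-unit spikes inside
#' `(lag - jitter, lag + jitter)` after pre-unit spikes with probability
#' `efficacy`. Every injected effect is logged in the returned ground truth
#' (including realized inserted/deleted spike counts).
#'
#' @param config A [synth_config()].
#' @param epochs Epoch table; defaults to [make_epoch_table()].
#' @param light_events Light-pulse table; defaults to [make_light_events()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with elements `units` (list of [spike_unit()]) and
#'   `ground_truth` (class `ground_truth`).
#' @export
generate_units <- function(config, epochs = make_epoch_table(config),
                           light_events = make_light_events(config, epochs),
                           seed = config$seed) {
  validate_epoch_table(epochs)
  with_seed(seed, {
    chtab <- channel_table(config$probe_layouts)
    trains <- list()
    for (spec in config$units) {
      tt <- poisson_train(spec, epochs)
      if (spec$light_prob > 0 && nrow(light_events) > 0) {
        hit <- runif(nrow(light_events)) < spec$light_prob
        extra <- light_events$t_s[hit] +
          runif(sum(hit), 0, light_events$duration_s[hit])
        tt <- sort(c(tt, extra))
      }
      trains[[spec$id]] <- tt
    }
    coup_log <- list()
    for (cp in config$couplings) {
      pre <- trains[[cp$pre]]; post <- trains[[cp$post]]
      lag <- cp$lag_ms / 1000; jit <- cp$jitter_ms / 1000
      if (cp$sign == "excitatory") {
        sel <- runif(length(pre)) < cp$efficacy
        ins <- pre[sel] + lag + rnorm(sum(sel), 0, jit)
        trains[[cp$post]] <- sort(c(post, ins))
        n_ins <- length(ins); n_del <- 0L
      } else {
        # post spikes falling in the deletion window after any pre spike
        prev <- findInterval(post - lag, pre)          # last pre before lag
        cand_lo <- prev >= 1 & (post - pre[pmax(prev, 1)]) > (lag - jit) &
          (post - pre[pmax(prev, 1)]) < (lag + jit)
        nxt <- pmin(prev + 1L, length(pre))
        cand_hi <- length(pre) > 0 & (post - pre[nxt]) > (lag - jit) &
          (post - pre[nxt]) < (lag + jit)
        cand <- which(cand_lo | cand_hi)
        kill <- cand[runif(length(cand)) < cp$efficacy]
        if (length(kill) > 0) trains[[cp$post]] <- post[-kill]
        n_ins <- 0L; n_del <- length(kill)
      }
      coup_log[[length(coup_log) + 1L]] <-
        data.frame(pre = cp$pre, post = cp$post, sign = cp$sign,
                   efficacy = cp$efficacy, lag_ms = cp$lag_ms,
                   jitter_ms = cp$jitter_ms, n_inserted = n_ins,
                   n_deleted = n_del, stringsAsFactors = FALSE)
    }
    duration <- max(epochs$t_end_s, 0)
    units <- vector("list", length(config$units))
    for (k in seq_along(config$units)) {
      spec <- config$units[[k]]
      tt <- trains[[spec$id]]
      tt <- tt[tt >= 0 & tt <= duration]
      tt <- sort(unique(tt))
      wf <- make_unit_waveform(spec, chtab)
      units[[k]] <- spike_unit(spec$id, spec$region, tt,
                               waveform = wf$waveform,
                               peak_channel = wf$peak_channel,
                               is_cholinergic = spec$is_cholinergic,
                               template = spec$template)
    }
    names(units) <- vapply(units, function(u) u$id, character(1))
    gt <- ground_truth(
      hotspots = hotspots_as_df(config$hotspots),
      couplings = if (length(coup_log)) do.call(rbind, coup_log) else
        data.frame(),
      tagged_units = vapply(
        Filter(function(u) u$light_prob > 0, config$units),
        function(u) u$id, character(1)),
      cholinergic_units = vapply(
        Filter(function(u) isTRUE(u$is_cholinergic), config$units),
        function(u) u$id, character(1)),
      sta_effects = sta_effects_as_df(config$sta_effects))
    list(units = units, ground_truth = gt)
  })
}

hotspots_as_df <- function(hotspots) {
  if (length(hotspots) == 0) return(data.frame())
  do.call(rbind, lapply(hotspots, function(h) {
    data.frame(channel_a = h$channel_a, channel_b = h$channel_b,
               band = h$band, epoch = h$epoch, coupling = h$coupling,
               lag_ms = h$lag_ms, stringsAsFactors = FALSE)
  }))
}

sta_effects_as_df <- function(effects) {
  if (length(effects) == 0) return(data.frame())
  do.call(rbind, lapply(effects, function(e) {
    data.frame(unit = e$unit, channel = e$channels, band = e$band,
               gain = e$gain, window_s = e$window_s, stringsAsFactors = FALSE)
  }))
}

#' Ground-truth record of injected synthetic effects
#'
#' Book-keeping object used as the recovery oracle in validation: which
#' coherence hotspots, spike couplings, light-responsive units and
#' spike-triggered gamma effects were injected into a synthetic session.
#'
#' @param hotspots,couplings,sta_effects Data frames (possibly empty).
#' @param tagged_units,cholinergic_units Character vectors of unit ids.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(hotspots = data.frame(), couplings = data.frame(),
                         tagged_units = character(0),
                         cholinergic_units = character(0),
                         sta_effects = data.frame()) {
  structure(list(hotspots = hotspots, couplings = couplings,
                 tagged_units = as.character(tagged_units),
                 cholinergic_units = as.character(cholinergic_units),
                 sta_effects = sta_effects),
            class = "ground_truth")
}
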