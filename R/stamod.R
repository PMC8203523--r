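# cholinergic spike-triggered spatial analysis of cortical gamma power:
# before/after window power, ECDF comparison by two-sample KS test,
# normalized difference scores, and per-cell percent-significant summaries

#' Band power time series of one channel
#'
#' Wavelet power (`|W|^2 / scale`) averaged over the analysis frequencies
#' inside a gamma band.
#'
#' @param rec An [lfp_recording()].
#' @param channel Channel id.
#' @param band Band label or numeric range (Hz).
#' @param freqs Analysis frequencies (defaults to the grid inside the band).
#' @param omega0 Morlet parameter.
#' @return List: `power` (numeric vector), `rate`, `edge_dist` (s).
#' @export
band_power_series <- function(rec, channel, band, freqs = NULL, omega0 = 6) {
  if (is.null(freqs)) freqs <- band_freqs(band)
  sg <- cwt_spectrogram(rec, channel, freqs = freqs, omega0 = omega0)
  list(power = colMeans(spectrogram_power(sg)), rate = sg$rate,
       edge_dist = sg$edge_dist)
}

#' Spike-triggered band power before and after each spike
#'
#' For every trigger spike, the band power is averaged over the 500 ms
#' window before the spike (`[-500, 0)` ms) and after it (`(0, +500]` ms),
#' yielding one before-sample and one after-sample per spike. Spikes closer
#' than the half-window to a recording edge are dropped; by default,
#' triggers are additionally thinned so consecutive windows do not overlap
#' (the KS comparison assumes approximately independent samples).
#'
#' @param unit A [spike_unit()] or spike-time vector.
#' @param rec An [lfp_recording()] (ignored when `power` is supplied).
#' @param channel Channel id.
#' @param band Band label or range.
#' @param half_window Window half-length (s).
#' @param min_spikes Minimum usable trigger spikes.
#' @param enforce_nonoverlap Thin triggers to non-overlapping windows.
#' @param power Optional precomputed [band_power_series()] result (reused
#'   across units/channels for speed).
#' @param per_spike One sample per spike per side (the default,
#'   window-mean power). With `per_spike = FALSE` every power sample inside
#'   the windows is pooled instead; samples within a window are strongly
#'   autocorrelated, so downstream tests should treat that mode as
#'   descriptive.
#' @return List: `before`, `after` (numeric vectors, one entry per used
#'   spike), `n_spikes`, `status` (`"ok"` or `"insufficient events"`).
#' @export
spike_triggered_power <- function(unit, rec = NULL, channel = NULL,
                                  band = "low_gamma", half_window = 0.5,
                                  min_spikes = 50,
                                  enforce_nonoverlap = TRUE, power = NULL,
                                  per_spike = TRUE) {
  tt <- unit_times(unit)
  if (is.null(power)) {
    if (is.null(rec) || is.null(channel)) {
      stop("either `power` or both `rec` and `channel` are required")
    }
    power <- band_power_series(rec, channel, band)
  }
  p <- power$power; rate <- power$rate
  n <- length(p)
  dur <- n / rate
  tt <- tt[tt >= half_window & tt <= dur - half_window]
  if (enforce_nonoverlap && length(tt) > 1) {
    keep <- rep(FALSE, length(tt))
    last <- -Inf
    for (i in seq_along(tt)) {
      if (tt[i] - last >= 2 * half_window) {
        keep[i] <- TRUE
        last <- tt[i]
      }
    }
    tt <- tt[keep]
  }
  if (length(tt) < min_spikes) {
    return(list(before = numeric(0), after = numeric(0),
                n_spikes = length(tt), status = "insufficient events"))
  }
  hw <- as.integer(round(half_window * rate))
  ic <- pmin(pmax(as.integer(floor(tt * rate)) + 1L, hw + 1L), n - hw)
  if (per_spike) {
    cs <- c(0, cumsum(p))
    before <- (cs[ic] - cs[ic - hw]) / hw
    after <- (cs[ic + hw] - cs[ic]) / hw
  } else {
    before <- unlist(lapply(ic, function(i) p[(i - hw):(i - 1L)]))
    after <- unlist(lapply(ic, function(i) p[(i + 1L):(i + hw)]))
  }
  list(before = before, after = after, n_spikes = length(tt), status = "ok")
}

#' Two-sample KS comparison of before/after power distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the empirical cumulative
#' distributions of band power before versus after the trigger spikes
#' (asymptotic p-value).
#'
#' @param before,after Numeric sample vectors (>= 10 each).
#' @param alpha Significance level.
#' @return List: `D` (max ECDF gap), `p`, `significant`, `status`.
#' @export
ks_before_after <- function(before, after, alpha = 0.05) {
  if (length(before) < 10 || length(after) < 10) {
    return(list(D = NA_real_, p = NA_real_, significant = NA,
                status = "insufficient events"))
  }
  kt <- suppressWarnings(ks.test(before, after, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       significant = kt$p.value < alpha, status = "ok")
}

#' Spike-triggered power difference score
#'
#' Normalized difference of the mean band power after versus before the
#' trigger spikes, `(mean(after) - mean(before)) / (mean(after) +
#' mean(before))`, bounded in `[-1, 1]` and antisymmetric under swapping
#' the windows.
#'
#' @param before,after Non-empty numeric vectors.
#' @return Scalar in `[-1, 1]`, or `NA` when both means are zero.
#' @export
sta_difference_score <- function(before, after) {
  if (length(before) == 0 || length(after) == 0) {
    stop("both sample sets must be non-empty")
  }
  mb <- mean(before); ma <- mean(after)
  if (ma + mb == 0) return(NA_real_)
  (ma - mb) / (ma + mb)
}

#' Spike-triggered gamma analysis of one trigger unit over many sites
#'
#' Runs [spike_triggered_power()], [ks_before_after()] and
#' [sta_difference_score()] for every (channel, band) combination.
#'
#' @param unit Trigger [spike_unit()] (typically an identified cholinergic
#'   cell) or spike-time vector.
#' @param rec An [lfp_recording()].
#' @param channels Channel ids (default: all non-BF channels).
#' @param bands Named list of band ranges.
#' @param alpha Significance level for the KS decision.
#' @param half_window,min_spikes,enforce_nonoverlap See
#'   [spike_triggered_power()].
#' @return Data frame with one row per (channel, band): `unit`, `channel`,
#'   `region`, `band`, `n_spikes`, `D`, `p`, `diff_score`, `significant`.
#' @export
sta_analysis <- function(unit, rec, channels = NULL,
                         bands = default_gamma_bands(), alpha = 0.05,
                         half_window = 0.5, min_spikes = 50,
                         enforce_nonoverlap = TRUE) {
  if (is.null(channels)) {
    channels <- rec$channels$id[rec$channels$region != "BF"]
  }
  uid <- if (inherits(unit, "spike_unit")) unit$id else NA_character_
  rows <- list()
  for (bname in names(bands)) {
    for (ch in channels) {
      pw <- band_power_series(rec, ch, bands[[bname]])
      stp <- spike_triggered_power(unit, channel = ch, power = pw,
                                   half_window = half_window,
                                   min_spikes = min_spikes,
                                   enforce_nonoverlap = enforce_nonoverlap)
      ks <- ks_before_after(stp$before, stp$after, alpha = alpha)
      ds <- if (stp$status == "ok") {
        sta_difference_score(stp$before, stp$after)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        unit = uid, channel = ch,
        region = rec$channels$region[rec$channels$id == ch],
        band = bname, n_spikes = stp$n_spikes, D = ks$D, p = ks$p,
        diff_score = ds, significant = ks$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of sites with significant spike-triggered gamma changes
#'
#' Summarizes [sta_analysis()] results per (unit, region, band): the
#' percentage of contact sites whose before/after power ECDFs differ
#' significantly, `100 * n_significant / n_sites` (each cortical probe has
#' 32 sites).
#'
#' @param results Data frame from [sta_analysis()] (possibly several units
#'   combined).
#' @param n_sites Expected sites per probe (32); when more rows are missing
#'   the percentage is computed over the available sites with a
#'   completeness warning. `NULL` uses the available count silently.
#' @return Data frame: `unit`, `region`, `band`, `n_sites`,
#'   `n_significant`, `percent_significant`.
#' @export
summarize_percent_significant <- function(results, n_sites = 32) {
  key <- interaction(results$unit, results$region, results$band,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    avail <- sum(!is.na(g$significant))
    ns <- if (is.null(n_sites)) avail else n_sites
    if (!is.null(n_sites) && avail < n_sites) {
      warning("unit ", g$unit[1], " ", g$region[1], " ", g$band[1], ": only ",
              avail, " of ", n_sites, " sites available; percentage uses ",
              avail)
      ns <- avail
    }
    data.frame(unit = g$unit[1], region = g$region[1], band = g$band[1],
               n_sites = ns, n_significant = sum(g$significant,
                                                 na.rm = TRUE),
               percent_significant = 100 *
                 sum(g$significant, na.rm = TRUE) / ns,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$unit, out$region, out$band), ]
}
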