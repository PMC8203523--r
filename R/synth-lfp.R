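# synthetic LFP generation: 1/f background + band-limited gamma components
# with injected shared (coherent) sources and spike-triggered gain effects

# spectrally shaped Gaussian noise, unit variance; exponent is the 1/f slope
one_over_f_noise <- function(n, rate, exponent = 1) {
  xf <- fft(rnorm(n))
  f <- seq(0, rate, length.out = n + 1)[1:n]
  f[f > rate / 2] <- rate - f[f > rate / 2]     # mirror for negative freqs
  amp <- c(0, abs(f[-1])^(-exponent / 2))        # kill DC
  x <- Re(fft(xf * amp, inverse = TRUE)) / n
  x / sd(x)
}

# band-limited Gaussian noise, unit variance, raised-cosine band edges
bandlimited_noise <- function(n, rate, band, edge_frac = 0.1) {
  xf <- fft(rnorm(n))
  f <- seq(0, rate, length.out = n + 1)[1:n]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  lo <- band[1]; hi <- band[2]
  w <- (hi - lo) * edge_frac
  mask <- numeric(n)
  core <- f >= lo & f <= hi
  mask[core] <- 1
  rise <- f > lo - w & f < lo
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / w))
  fall <- f > hi & f < hi + w
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / w))
  x <- Re(fft(xf * mask, inverse = TRUE)) / n
  x / sd(x)
}

# 0/1 indicator over samples for all rows of `epochs` with label `label`
epoch_indicator <- function(epochs, label, n, rate) {
  ind <- numeric(n)
  rows <- epochs[epochs$label == label, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    idx <- interval_indices(rows$t_start_s[i], rows$t_end_s[i], rate, 0, n)
    ind[idx] <- 1
  }
  ind
}

#' Generate a synthetic multichannel LFP recording
#'
#' Each channel is the sum of a 1/f spectrally shaped Gaussian background and
#' one independent band-limited Gaussian component per configured gamma band.
#' For every [hotspot_spec()], a shared band-limited source replaces a
#' fraction `coupling` of the two target channels' band components during the
#' hotspot's epoch (total band power is preserved), creating an
#' epoch-specific coherence increase for exactly that pair. For every
#' [sta_effect_spec()], the target channels' band component is multiplied by
#' `gain` during the 500 ms following each spike of the trigger unit.
#'
#' @param config A [synth_config()].
#' @param epochs Epoch table (defaults to [make_epoch_table()]); epochs must
#'   tile the session without overlap.
#' @param units List of `spike_unit` objects; required when `config`
#'   contains `sta_effects` (their spike times drive the gain windows).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return Object of class `lfp_recording`: list with `samples`
#'   (time x channel matrix, uV), `rate` (Hz), and `channels` (data frame
#'   with id, region, shank, site, depth).
#' @export
generate_lfp <- function(config, epochs = make_epoch_table(config),
                         units = NULL, seed = config$seed) {
  validate_epoch_table(epochs)
  for (b in config$gamma_bands) {
    if (b[2] >= config$lfp_rate / 2) {
      stop("gamma band upper edge ", b[2], " Hz is outside the Nyquist range")
    }
  }
  if (length(config$sta_effects) > 0 && is.null(units)) {
    stop("sta_effects configured but no units supplied to generate_lfp()")
  }
  chtab <- channel_table(config$probe_layouts)
  rate <- config$lfp_rate
  duration <- max(epochs$t_end_s, 0)
  n <- as.integer(round(duration * rate))
  if (n == 0) {
    return(lfp_recording(matrix(0, 0, nrow(chtab),
                                dimnames = list(NULL, chtab$id)),
                         rate, chtab))
  }

  # index injected effects by channel id for the per-channel assembly loop
  hot_by_chan <- list()
  for (h in config$hotspots) {
    for (side in c("channel_a", "channel_b")) {
      id <- h[[side]]
      if (!id %in% chtab$id) stop("hotspot channel '", id, "' not in probes")
      hot_by_chan[[id]] <- c(hot_by_chan[[id]], list(list(spec = h,
                                                          side = side)))
    }
  }
  sta_by_chan <- list()
  for (e in config$sta_effects) {
    for (id in e$channels) {
      if (!id %in% chtab$id) stop("sta effect channel '", id,
                                  "' not in probes")
      sta_by_chan[[id]] <- c(sta_by_chan[[id]], list(e))
    }
  }

  with_seed(seed, {
    # one shared source per hotspot, drawn first for layout-stable RNG use
    shared <- lapply(config$hotspots, function(h) {
      bandlimited_noise(n, rate, config$gamma_bands[[h$band]])
    })
    # post-spike gain masks per sta effect (same mask for all its channels)
    sta_masks <- lapply(config$sta_effects, function(e) {
      tu <- NULL
      for (u in units) if (u$id == e$unit) tu <- u
      if (is.null(tu)) stop("sta effect trigger unit '", e$unit,
                            "' not found among supplied units")
      m <- rep(1, n)
      i0 <- pmin(n, floor(tu$spike_times * rate) + 2L)   # (0, +window]
      i1 <- pmin(n, floor((tu$spike_times + e$window_s) * rate) + 1L)
      keep <- i0 <= i1
      for (k in which(keep)) m[i0[k]:i1[k]] <- e$gain
      m
    })

    X <- matrix(0, n, nrow(chtab), dimnames = list(NULL, chtab$id))
    for (ci in seq_len(nrow(chtab))) {
      id <- chtab$id[ci]
      x <- config$background_sd * one_over_f_noise(n, rate,
                                                   config$noise_exponent)
      for (bi in seq_along(config$gamma_bands)) {
        bname <- names(config$gamma_bands)[bi]
        own <- bandlimited_noise(n, rate, config$gamma_bands[[bi]])
        comp <- own
        for (hc in hot_by_chan[[id]]) {
          h <- hc$spec
          if (h$band != bname) next
          w <- epoch_indicator(epochs, h$epoch, n, rate)
          s <- shared[[which(vapply(config$hotspots, identical, logical(1),
                                    h))[1]]]
          if (hc$side == "channel_b" && h$lag_ms != 0) {
            k <- as.integer(round(h$lag_ms * rate / 1000))
            s <- c(rep(0, k), s[seq_len(n - k)])
          }
          # during the epoch: sqrt(1-c^2)*own + c*shared, keeping band power
          comp <- comp + w * (h$coupling * s +
                                (sqrt(1 - h$coupling^2) - 1) * own)
        }
        for (e in sta_by_chan[[id]]) {
          if (e$band != bname) next
          mi <- which(vapply(config$sta_effects, identical, logical(1), e))[1]
          comp <- comp * sta_masks[[mi]]
        }
        x <- x + config$gamma_sd * comp
      }
      X[, ci] <- x
    }
    lfp_recording(X, rate, chtab)
  })
}

#' LFP recording container
#'
#' @param samples Numeric matrix, time x channel (uV), columns named by
#'   channel id.
#' @param rate Sampling rate in Hz.
#' @param channels Data frame with at least `id` and `region` columns;
#'   channel ids must be unique and match the sample columns.
#' @return Object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, rate, channels) {
  stopifnot(is.matrix(samples), rate > 0)
  if (anyDuplicated(channels$id)) stop("channel ids must be unique")
  if (ncol(samples) != nrow(channels)) {
    stop("sample columns (", ncol(samples), ") and channel rows (",
         nrow(channels), ") disagree")
  }
  colnames(samples) <- channels$id
  structure(list(samples = samples, rate = rate, channels = channels),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %.1f s @ %g Hz (%s)\n",
              ncol(x$samples), nrow(x$samples) / x$rate, x$rate,
              paste(unique(x$channels$region), collapse = "/")))
  invisible(x)
}
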