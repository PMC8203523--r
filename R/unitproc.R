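# spike-unit physiology: epoch rate modulation, optotagging, waveform
# features and classification, and cross-correlogram connection detection

unit_times <- function(unit) {
  if (inherits(unit, "spike_unit")) unit$spike_times else as.numeric(unit)
}

#' Epoch firing-rate modulation of one unit
#'
#' Per-trial firing rates during a behavioral epoch are compared to the
#' same trials' center/rest baseline with a two-sided Wilcoxon rank-sum
#' test. Z-scores are per-trial epoch rates standardized by the baseline
#' mean and SD; min--max feature scaling of the rates over the session is
#' also returned.
#'
#' @param unit A [spike_unit()] or numeric spike-time vector.
#' @param epochs Epoch table.
#' @param epoch_label Epoch of interest.
#' @param baseline_label Baseline epoch label.
#' @param min_trials Minimum trials carrying both epochs.
#' @return List: `p` (rank-sum p), `z` (per-trial Z-scores), `z_mean`,
#'   `rates_epoch`, `rates_baseline`, `rates_scaled` (min-max over all
#'   trials and both epochs), `n_trials`.
#' @export
epoch_rate_modulation <- function(unit, epochs, epoch_label,
                                  baseline_label = "center",
                                  min_trials = 5) {
  tt <- unit_times(unit)
  tr <- sort(unique(epochs$trial[!is.na(epochs$trial)]))
  rate_in <- function(lab, trial) {
    row <- epochs[!is.na(epochs$trial) & epochs$trial == trial &
                    epochs$label == lab, ]
    if (nrow(row) == 0) return(NA_real_)
    sum(tt >= row$t_start_s[1] & tt < row$t_end_s[1]) /
      (row$t_end_s[1] - row$t_start_s[1])
  }
  er <- vapply(tr, function(x) rate_in(epoch_label, x), numeric(1))
  br <- vapply(tr, function(x) rate_in(baseline_label, x), numeric(1))
  ok <- !is.na(er) & !is.na(br)
  er <- er[ok]; br <- br[ok]
  if (length(er) < min_trials) {
    stop("need at least ", min_trials, " trials with both '", epoch_label,
         "' and '", baseline_label, "' epochs")
  }
  pv <- suppressWarnings(wilcox.test(er, br, alternative = "two.sided"))
  bsd <- sd(br)
  z <- if (bsd > 0) (er - mean(br)) / bsd else rep(NA_real_, length(er))
  allr <- c(er, br)
  rng <- range(allr)
  scaled <- if (diff(rng) > 0) (allr - rng[1]) / diff(rng) else
    rep(0, length(allr))
  list(p = pv$p.value, z = z, z_mean = mean(z), rates_epoch = er,
       rates_baseline = br,
       rates_scaled = data.frame(
         trial = rep(tr[ok], 2),
         epoch = rep(c(epoch_label, baseline_label), each = length(er)),
         rate_scaled = scaled),
       n_trials = length(er))
}

#' Optogenetic tagging of a unit
#'
#' A unit is light-responsive when its firing rate during the light pulses
#' deviates from the mean pre-stimulus control rate by more than
#' `threshold_sd` control SDs (control window: 2000 ms before each pulse).
#' At least `min_stimuli` pulses are required. A peri-light-stimulus time
#' histogram is returned alongside the decision.
#'
#' @param unit A [spike_unit()] or spike-time vector.
#' @param light_events Data frame with `t_s` and `duration_s`.
#' @param response_window Response window length (s); defaults to the pulse
#'   duration.
#' @param control_window Pre-stimulus control window (s).
#' @param min_stimuli Minimum number of stimuli (100).
#' @param threshold_sd SD criterion (2).
#' @param psth_window,psth_bin Peri-stimulus histogram extent and bin (s).
#' @return Object of class `optotag_result`: `evoked_rate`, `control_mean`,
#'   `control_sd` (Hz), `responsive`, `direction` (`"up"`/`"down"`),
#'   `psth` (data frame), `n_stimuli`.
#' @export
optotag <- function(unit, light_events, response_window = NULL,
                    control_window = 2, min_stimuli = 100,
                    threshold_sd = 2, psth_window = 0.05,
                    psth_bin = 0.001) {
  tt <- unit_times(unit)
  ne <- nrow(light_events)
  if (ne < min_stimuli) {
    stop("insufficient stimuli: ", ne, " < ", min_stimuli)
  }
  if (is.null(response_window)) response_window <- light_events$duration_s[1]
  on <- light_events$t_s
  evoked_counts <- findInterval(on + response_window, tt) -
    findInterval(on, tt)
  evoked_rate <- sum(evoked_counts) / (ne * response_window)
  ctrl_counts <- findInterval(on, tt) - findInterval(on - control_window, tt)
  ctrl_rates <- ctrl_counts / control_window
  cm <- mean(ctrl_rates); cs <- sd(ctrl_rates)
  responsive <- abs(evoked_rate - cm) > threshold_sd * cs
  rel <- unlist(lapply(on, function(t0) {
    tt[tt >= t0 - psth_window & tt < t0 + psth_window] - t0
  }))
  edges <- seq(-psth_window, psth_window, by = psth_bin)
  counts <- if (length(rel)) {
    tabulate(findInterval(rel, edges), nbins = length(edges) - 1)
  } else numeric(length(edges) - 1)
  structure(list(unit = if (inherits(unit, "spike_unit")) unit$id else NA,
                 evoked_rate = evoked_rate, control_mean = cm,
                 control_sd = cs, responsive = responsive,
                 direction = if (evoked_rate >= cm) "up" else "down",
                 threshold_sd = threshold_sd, n_stimuli = ne,
                 psth = data.frame(lag_s = edges[-length(edges)] +
                                     psth_bin / 2,
                                   count = counts)),
            class = "optotag_result")
}

#' @export
print.optotag_result <- function(x, ...) {
  cat(sprintf(paste0("<optotag_result> %s: evoked %.2f Hz vs control ",
                     "%.2f +/- %.2f Hz -> %s%s (%d stimuli)\n"),
              x$unit, x$evoked_rate, x$control_mean, x$control_sd,
              if (x$responsive) "responsive" else "not responsive",
              if (x$responsive) paste0(" (", x$direction, ")") else "",
              x$n_stimuli))
  invisible(x)
}

# --- correlograms ---------------------------------------------------------

#' Spike-train cross-correlogram
#'
#' Histogram of lags `t_post - t_pre` within `+/- window`, binned at `bin`
#' (0.5 ms by default).
#'
#' @param pre,post [spike_unit()]s or spike-time vectors (seconds, sorted).
#' @param bin Bin width (s).
#' @param window Half-window (s).
#' @return List: `counts`, `centers` (s), `edges` (s).
#' @export
cross_correlogram <- function(pre, post, bin = 5e-4, window = 0.05) {
  tp <- unit_times(pre); tq <- unit_times(post)
  auto <- identical(tp, tq)
  edges <- seq(-window, window, by = bin)
  lo <- findInterval(tp - window, tq)
  hi <- findInterval(tp + window, tq)
  nper <- hi - lo
  if (sum(nper) > 0) {
    post_idx <- sequence(nper) + rep(lo, nper)
    lags <- tq[post_idx] - rep(tp, nper)
    if (auto) lags <- lags[post_idx != rep(seq_along(tp), nper)]
    # findInterval(t - w) can include a spike exactly at -w's open edge
    lags <- lags[lags > -window - bin / 2 & lags <= window]
    counts <- tabulate(pmin(pmax(findInterval(lags, edges,
                                              left.open = TRUE), 1L),
                            length(edges) - 1L),
                       nbins = length(edges) - 1L)
  } else {
    counts <- numeric(length(edges) - 1L)
  }
  list(counts = counts, centers = edges[-length(edges)] + bin / 2,
       edges = edges)
}

#' Spike-train autocorrelogram (positive lags)
#'
#' @param times [spike_unit()] or spike-time vector.
#' @param bin Bin width (s), 1 ms by default.
#' @param max_lag Maximum lag (s).
#' @return List: `counts`, `centers`, `edges` (all seconds, lags > 0).
#' @export
autocorrelogram <- function(times, bin = 1e-3, max_lag = 0.3) {
  tt <- unit_times(times)
  edges <- seq(0, max_lag, by = bin)
  hi <- findInterval(tt + max_lag, tt)
  lo <- seq_along(tt)
  nper <- hi - lo
  counts <- numeric(length(edges) - 1L)
  if (sum(nper) > 0) {
    idx <- sequence(nper) + rep(lo, nper)
    lags <- tt[idx] - rep(tt, nper)
    lags <- lags[lags > 0 & lags <= max_lag]
    counts <- tabulate(pmin(pmax(findInterval(lags, edges,
                                              left.open = TRUE), 1L),
                            length(edges) - 1L),
                       nbins = length(edges) - 1L)
  }
  list(counts = counts, centers = edges[-length(edges)] + bin / 2,
       edges = edges)
}

#' Burst index from an autocorrelogram
#'
#' Mean spike count in the 3--5 ms autocorrelogram bins divided by the mean
#' count in the 200--300 ms bins (1-ms bins; a bin belongs to a range when
#' it lies entirely inside it).
#'
#' @param counts Autocorrelogram counts.
#' @param edges Bin edges (s) of length `length(counts) + 1`.
#' @param burst_range,baseline_range Lag ranges in ms.
#' @return Scalar burst index, or `NA` when the baseline bins are empty.
#' @export
burst_index_from_acg <- function(counts, edges, burst_range = c(3, 5),
                                 baseline_range = c(200, 300)) {
  left <- edges[-length(edges)] * 1000
  right <- edges[-1] * 1000
  num <- counts[left >= burst_range[1] & right <= burst_range[2]]
  den <- counts[left >= baseline_range[1] & right <= baseline_range[2]]
  if (length(den) == 0 || mean(den) == 0) return(NA_real_)
  mean(num) / mean(den)
}

#' Burst index of a spike train
#'
#' @param times [spike_unit()] or spike-time vector.
#' @param bin Autocorrelogram bin (s).
#' @return Scalar burst index (see [burst_index_from_acg()]).
#' @export
burst_index <- function(times, bin = 1e-3) {
  acg <- autocorrelogram(times, bin = bin, max_lag = 0.3)
  burst_index_from_acg(acg$counts, acg$edges)
}

# --- CCG connection detection --------------------------------------------

#' Poisson outlier thresholds for a predicted baseline rate
#'
#' Upper threshold: smallest integer `k` whose cumulative Poisson
#' probability at the predicted rate reaches `quantile` (99.99th percentile
#' by default); a bin is a significant peak when its count exceeds it.
#' Lower threshold: analogous at `1 - quantile`; a bin is a significant
#' trough when its count falls below it.
#'
#' @param lambda Predicted rate (expected count) per bin.
#' @param quantile Cumulative-probability threshold.
#' @return List `upper`, `lower` (integers, vectorized over `lambda`).
#' @export
ccg_poisson_threshold <- function(lambda, quantile = 0.9999) {
  list(upper = qpois(quantile, lambda), lower = qpois(1 - quantile, lambda))
}

# Gaussian-convolved baseline predictor of a CCG (optionally hollowed),
# edge-renormalized "same" convolution
ccg_predictor <- function(counts, bin, gaussian_sd, hollow_fraction = 0) {
  sd_bins <- gaussian_sd / bin
  L <- max(1L, as.integer(ceiling(4 * sd_bins)))
  off <- seq.int(-L, L)
  kern <- exp(-0.5 * (off / sd_bins)^2)
  kern[off == 0] <- kern[off == 0] * (1 - hollow_fraction)
  kern <- kern / sum(kern)
  n <- length(counts)
  padded <- c(numeric(L), counts, numeric(L))
  wpad <- c(numeric(L), rep(1, n), numeric(L))
  pred <- num <- numeric(n)
  for (i in seq_len(n)) {
    sl <- (i):(i + 2L * L)
    pred[i] <- sum(padded[sl] * kern)
    num[i] <- sum(wpad[sl] * kern)
  }
  pred / num
}

#' Detect a putative monosynaptic connection from a cross-correlogram
#'
#' The cross-correlogram (0.5-ms bins, +/- 50 ms) is convolved with a 10-ms
#' SD Gaussian to form a slow baseline predictor. Each bin is compared to
#' the 99.99th-percentile Poisson thresholds at its predicted rate. A
#' connection is reported when at least `min_consecutive` consecutive bins
#' inside the +1.5 to +5 ms lag window exceed the upper threshold
#' (excitatory) or fall below the lower threshold (inhibitory).
#'
#' @param pre,post [spike_unit()]s or spike-time vectors.
#' @param bin,window CCG bin width and half-window (s).
#' @param gaussian_sd Predictor kernel SD (s).
#' @param quantile Poisson percentile for the thresholds.
#' @param detect_window Lag window scanned for significant bins (s).
#' @param min_consecutive Consecutive significant bins required.
#' @param min_spikes Minimum spikes per train.
#' @param hollow_fraction Fraction of the kernel's central weight removed
#'   (0 = the plain Gaussian predictor).
#' @return Object of class `ccg_result`: `detected`, `sign`
#'   (`"excitatory"`, `"inhibitory"`, or `"none"`), `significant_bins`
#'   (data frame with lag, count, thresholds), plus the full `counts`,
#'   `predictor`, `centers`, and thresholds.
#' @export
ccg_detect <- function(pre, post, bin = 5e-4, window = 0.05,
                       gaussian_sd = 0.01, quantile = 0.9999,
                       detect_window = c(1.5e-3, 5e-3), min_consecutive = 2,
                       min_spikes = 100, hollow_fraction = 0) {
  tp <- unit_times(pre); tq <- unit_times(post)
  if (length(tp) < min_spikes || length(tq) < min_spikes) {
    stop("both spike trains need at least ", min_spikes, " spikes")
  }
  if (min(tq) > max(tp) || min(tp) > max(tq)) {
    stop("spike trains do not overlap in time")
  }
  cc <- cross_correlogram(tp, tq, bin = bin, window = window)
  pred <- ccg_predictor(cc$counts, bin, gaussian_sd, hollow_fraction)
  th <- ccg_poisson_threshold(pred, quantile)
  sig_up <- cc$counts > th$upper
  sig_dn <- cc$counts < th$lower
  inwin <- cc$centers >= detect_window[1] & cc$centers <= detect_window[2]
  run_ok <- function(flags) {
    r <- rle(flags[inwin])
    any(r$values & r$lengths >= min_consecutive)
  }
  exc <- run_ok(sig_up); inh <- run_ok(sig_dn)
  sign <- if (exc) "excitatory" else if (inh) "inhibitory" else "none"
  sel <- inwin & (sig_up | sig_dn)
  structure(list(
    pre = if (inherits(pre, "spike_unit")) pre$id else NA,
    post = if (inherits(post, "spike_unit")) post$id else NA,
    detected = exc || inh, sign = sign,
    significant_bins = data.frame(lag_ms = cc$centers[sel] * 1000,
                                  count = cc$counts[sel],
                                  predicted = pred[sel],
                                  upper = th$upper[sel],
                                  lower = th$lower[sel]),
    counts = cc$counts, centers = cc$centers, predictor = pred,
    upper = th$upper, lower = th$lower, quantile = quantile),
    class = "ccg_result")
}

#' @export
print.ccg_result <- function(x, ...) {
  cat(sprintf("<ccg_result> %s -> %s: %s (%d significant bins in window)\n",
              x$pre, x$post, x$sign, nrow(x$significant_bins)))
  invisible(x)
}

# --- waveform features ----------------------------------------------------

#' Trough-to-peak latency and burst index of one unit
#'
#' The waveform row with the largest absolute deviation (the peak channel)
#' is used; trough-to-peak latency is the time from the global trough to the
#' subsequent maximum.
#'
#' @param unit A [spike_unit()] with a mean waveform.
#' @return List: `tp_latency_ms`, `burst_index`, `peak_channel`.
#' @export
waveform_features <- function(unit) {
  wf <- unit$waveform
  if (is.null(wf)) stop("unit ", unit$id, " has no waveform")
  if (is.vector(wf)) wf <- matrix(wf, nrow = 1)
  peak_row <- which.max(apply(abs(wf), 1, max))
  w <- wf[peak_row, ]
  it <- which.min(w)
  if (it >= length(w)) stop("waveform trough has no subsequent peak")
  ip <- it + which.max(w[(it + 1):length(w)])
  tp <- (ip - it) / unit$waveform_rate * 1000
  bi <- if (length(unit$spike_times) >= 2 &&
              diff(range(unit$spike_times)) > 0.3) {
    burst_index(unit$spike_times)
  } else NA_real_
  list(tp_latency_ms = tp, burst_index = bi,
       peak_channel = rownames(wf)[peak_row])
}

#' Waveform principal components (second derivative)
#'
#' Each unit's peak-channel mean waveform is upsampled (cubic
#' interpolation), differentiated twice, aligned at its global trough, and
#' cropped to the 0--0.8 ms window after the trough; the first two principal
#' components of the stacked, mean-centered matrix are returned per unit.
#'
#' @param units List of [spike_unit()]s (at least 3).
#' @param window_ms Post-trough crop window (ms).
#' @param upsample Upsampling factor (5: 20 kHz -> 100 kHz).
#' @return Data frame: `unit`, `w_pca1`, `w_pca2`.
#' @export
waveform_pca <- function(units, window_ms = c(0, 0.8), upsample = 5) {
  if (length(units) < 3) stop("waveform PCA needs at least 3 units")
  rows <- lapply(units, function(u) {
    wf <- u$waveform
    if (is.vector(wf)) wf <- matrix(wf, nrow = 1)
    w <- wf[which.max(apply(abs(wf), 1, max)), ]
    n <- length(w)
    up_rate <- u$waveform_rate * upsample
    up <- spline(seq_len(n), w, xout = seq(1, n, by = 1 / upsample))$y
    d2 <- diff(diff(up))
    it <- which.min(up)
    i0 <- it + as.integer(round(window_ms[1] / 1000 * up_rate))
    i1 <- it + as.integer(round(window_ms[2] / 1000 * up_rate))
    if (i1 > length(d2)) {
      stop("PCA window exceeds the waveform span after trough alignment ",
           "(unit ", u$id, ")")
    }
    d2[i0:i1]
  })
  X <- do.call(rbind, rows)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  data.frame(unit = vapply(units, function(u) u$id, character(1)),
             w_pca1 = scores[, 1], w_pca2 = scores[, 2],
             stringsAsFactors = FALSE)
}

#' Physiological feature table for a set of units
#'
#' @param units List of [spike_unit()]s.
#' @return Data frame: `unit`, `region`, `tp_latency_ms`, `burst_index`,
#'   `mean_rate`, `w_pca1`, `w_pca2`, `is_cholinergic`.
#' @export
compute_unit_features <- function(units) {
  pca <- waveform_pca(units)
  base <- do.call(rbind, lapply(units, function(u) {
    f <- waveform_features(u)
    data.frame(unit = u$id, region = u$region,
               tp_latency_ms = f$tp_latency_ms,
               burst_index = f$burst_index, mean_rate = u$mean_rate,
               is_cholinergic = isTRUE(u$is_cholinergic),
               stringsAsFactors = FALSE)
  }))
  out <- merge(base, pca, by = "unit", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Preliminary excitatory/inhibitory grouping
#'
#' Wide-waveform or slow-firing units are grouped as putative excitatory
#' (trough-to-peak latency > 0.485 ms or mean rate < 6 Hz); the rest as
#' putative inhibitory.
#'
#' @param tp_latency_ms,mean_rate Numeric vectors.
#' @param tp_threshold,rate_threshold Split thresholds.
#' @return Character vector `"excitatory"`/`"inhibitory"`.
#' @export
preliminary_ei_split <- function(tp_latency_ms, mean_rate,
                                 tp_threshold = 0.485, rate_threshold = 6) {
  ifelse(tp_latency_ms > tp_threshold | mean_rate < rate_threshold,
         "excitatory", "inhibitory")
}

#' K-means clustering of unit features
#'
#' Z-standardizes trough-to-peak latency and the two waveform principal
#' components, then runs seeded multi-restart k-means with `k = 6` clusters
#' by default.
#'
#' @param features Feature data frame from [compute_unit_features()].
#' @param k Number of clusters.
#' @param seed RNG seed.
#' @param nstart Random restarts.
#' @return List: `labels` (named integer vector 1..k), `centers` (on the
#'   standardized scale), `inertia` (total within-cluster sum of squares),
#'   `k`.
#' @export
classify_units <- function(features, k = 6, seed = NULL, nstart = 25) {
  cols <- c("tp_latency_ms", "w_pca1", "w_pca2")
  stopifnot(all(cols %in% names(features)))
  X <- as.matrix(features[, cols])
  if (any(!complete.cases(X))) stop("features contain missing values")
  if (nrow(X) < k) stop("k (", k, ") exceeds the number of units (",
                        nrow(X), ")")
  Xs <- apply(X, 2, function(col) {
    s <- sd(col)
    if (s > 0) (col - mean(col)) / s else col * 0
  })
  ux <- unique(Xs)
  if (nrow(ux) < k) {
    # fewer distinct feature points than clusters: each distinct point gets
    # its own (stable) cluster, the remaining clusters stay empty
    warning("only ", nrow(ux), " distinct feature points for k = ", k,
            "; assigning one cluster per distinct point")
    lab <- match(apply(Xs, 1, paste, collapse = "\r"),
                 apply(ux, 1, paste, collapse = "\r"))
    return(list(labels = setNames(lab, features$unit), centers = ux,
                inertia = 0, k = k))
  }
  km <- with_seed(seed, kmeans(Xs, centers = k, nstart = nstart,
                               iter.max = 100))
  list(labels = setNames(km$cluster, features$unit), centers = km$centers,
       inertia = km$tot.withinss, k = k)
}

#' Cross-validate k-means labels with bagged decision trees
#'
#' Trains a bootstrap-aggregated ensemble of decision trees (bagging: every
#' tree sees all four features -- trough-to-peak latency, the two waveform
#' principal components, and mean firing rate -- on a bootstrap resample) on
#' the non-cholinergic units' k-means labels, reports out-of-bag accuracy,
#' and predicts cluster labels for the held-out cholinergic units.
#'
#' @param features Feature data frame.
#' @param labels Named cluster labels from [classify_units()].
#' @param cholinergic_ids Unit ids excluded from training and predicted.
#' @param seed RNG seed.
#' @param ntree Number of trees.
#' @return List: `oob_accuracy`, `predicted_cholinergic` (named factor),
#'   `model`.
#' @export
crossvalidate_bagged_tree <- function(features, labels,
                                      cholinergic_ids = NULL, seed = NULL,
                                      ntree = 300) {
  cols <- c("tp_latency_ms", "w_pca1", "w_pca2", "mean_rate")
  stopifnot(all(cols %in% names(features)))
  if (is.null(cholinergic_ids) && "is_cholinergic" %in% names(features)) {
    cholinergic_ids <- features$unit[features$is_cholinergic]
  }
  train <- !(features$unit %in% cholinergic_ids)
  y <- factor(labels[features$unit[train]])
  if (nlevels(droplevels(y)) < 2) {
    stop("training labels must contain at least 2 classes")
  }
  if (any(table(y) == 1)) {
    warning("a class has a single member; out-of-bag estimates will be noisy")
  }
  X <- as.matrix(features[train, cols])
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = droplevels(y), ntree = ntree, mtry = length(cols)))
  oob <- mean(fit$predicted == droplevels(y))
  pred <- NULL
  if (any(!train)) {
    pred <- predict(fit, as.matrix(features[!train, cols]))
    names(pred) <- features$unit[!train]
  }
  list(oob_accuracy = oob, predicted_cholinergic = pred, model = fit)
}
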