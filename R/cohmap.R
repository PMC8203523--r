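# behavior-epoch coherence statistics: change scores, Monte-Carlo
# permutation significance, voxel maps, and epoch-level ANOVA / Tukey HSD

#' Coherence change score
#'
#' Normalized difference of mean wavelet coherence between a behavioral
#' epoch and the center/rest baseline:
#' `(mean(behavior) - mean(resting)) / (mean(behavior) + mean(resting))`,
#' bounded in `[-1, +1]` (+1 = coherence increase during behavior) and
#' antisymmetric under swapping the two groups.
#'
#' @param behavior,resting Non-empty numeric vectors of band-averaged
#'   coherence values in `[0, 1]` (one value per trial).
#' @return Scalar in `[-1, 1]`, or `NA` when both means are zero (reported
#'   as a missing voxel rather than propagating NaN).
#' @export
coherence_change_score <- function(behavior, resting) {
  if (length(behavior) == 0 || length(resting) == 0) {
    stop("both coherence sample groups must be non-empty")
  }
  if (min(behavior, resting) < -1e-9 || max(behavior, resting) > 1 + 1e-9) {
    stop("coherence samples must lie in [0, 1]")
  }
  mb <- mean(behavior); mr <- mean(resting)
  if (mb + mr == 0) return(NA_real_)
  (mb - mr) / (mb + mr)
}

#' Monte-Carlo permutation test for a coherence change
#'
#' Pools the two groups, redraws label-permuted groups of the original sizes
#' `n_perm` times, and compares the observed difference of means to the
#' permutation distribution (two-sided by default; one-sided tests the
#' increase). A bootstrap variant (resampling the merged distribution with
#' replacement) is available via `replace = TRUE`.
#'
#' @param behavior,resting Numeric vectors (each of length >= 2).
#' @param n_perm Number of resamples (3000 by default).
#' @param alpha Significance level; required, no default.
#' @param two_sided Two-sided (default) or one-sided increase.
#' @param replace Resample with replacement instead of permuting labels.
#' @param seed Optional RNG seed.
#' @return List: `score` (coherence change score), `statistic` (observed
#'   difference of means), `p`, `significant`, `n_perm`, `alpha`.
#' @export
permutation_significance <- function(behavior, resting, n_perm = 3000,
                                     alpha, two_sided = TRUE,
                                     replace = FALSE, seed = NULL) {
  if (length(behavior) < 2 || length(resting) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (missing(alpha)) stop("alpha is a required parameter")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  pooled <- c(behavior, resting)
  n1 <- length(behavior); ntot <- length(pooled)
  obs <- mean(behavior) - mean(resting)
  score <- coherence_change_score(pmin(pmax(behavior, 0), 1),
                                  pmin(pmax(resting, 0), 1))
  if (var(pooled) == 0) {
    return(list(score = score, statistic = obs, p = 1, significant = FALSE,
                n_perm = n_perm, alpha = alpha))
  }
  pd <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- if (replace) sample.int(ntot, ntot, replace = TRUE) else
        sample.int(ntot)
      mean(pooled[idx[seq_len(n1)]]) - mean(pooled[idx[-seq_len(n1)]])
    }, numeric(1))
  })
  p_up <- (1 + sum(pd >= obs)) / (n_perm + 1)
  p_dn <- (1 + sum(pd <= obs)) / (n_perm + 1)
  p <- if (two_sided) min(1, 2 * min(p_up, p_dn)) else p_up
  list(score = score, statistic = obs, p = p, significant = p <= alpha,
       n_perm = n_perm, alpha = alpha)
}

# --- per-trial coherence engine ------------------------------------------

# Mean band coherence for every (a, b) channel pair over one time interval.
# The segment is padded on both sides (where recording exists) so that
# cone-of-influence and smoothing margins fall outside the scored interval.
pair_coh_interval_means <- function(lfp, chans_a, chans_b, interval, freqs,
                                    time_smooth = 4, scale_smooth = 1,
                                    pad_s = 0.3) {
  rate <- lfp$rate
  n <- nrow(lfp$samples)
  seg0 <- max(0, interval[1] - pad_s)
  seg1 <- min(n / rate, interval[2] + pad_s)
  idx <- interval_indices(seg0, seg1, rate, 0, n)
  chans <- unique(c(chans_a, chans_b))
  cwts <- lapply(chans, function(ch) {
    cwt_core(lfp$samples[idx, ch], rate, freqs)
  })
  names(cwts) <- chans
  scales <- cwts[[1]]$scales
  smoother <- if (time_smooth > 0) {
    make_time_smoother(length(idx), pmax(time_smooth * scales * rate, 0.5))
  } else identity
  smooth_seg <- function(M) {
    M <- smoother(M)
    if (scale_smooth >= 1) M <- smooth_scale_rows(M, scale_smooth)
    M
  }
  autos <- lapply(cwts, function(cw) Re(smooth_seg(Mod(cw$coef)^2)))
  nt <- length(idx)
  tseg <- seg0 + (seq_len(nt) - 1) / rate
  margin <- max(sqrt(2), 2 * time_smooth) * max(scales)
  edge <- pmin(tseg - seg0, seg1 - tseg)
  keep <- tseg >= interval[1] & tseg < interval[2] & edge >= margin
  if (!any(keep)) keep <- tseg >= interval[1] & tseg < interval[2]
  out <- matrix(NA_real_, length(chans_a), length(chans_b),
                dimnames = list(chans_a, chans_b))
  for (a in chans_a) {
    for (b in chans_b) {
      if (identical(a, b)) next
      sab <- smooth_seg(cwts[[a]]$coef * Conj(cwts[[b]]$coef))
      c2 <- Mod(sab)^2 / pmax(autos[[a]] * autos[[b]], 1e-300)
      out[a, b] <- mean(pmin(pmax(colMeans(c2), 0), 1)[keep])
    }
  }
  out
}

# Per-trial band coherence means for two epoch labels over all pairs.
# Returns list(behavior, resting): matrices [n_pairs x n_trials] with
# rownames "a|b".
cwc_trial_epoch_means <- function(lfp, chans_a, chans_b, band, epochs,
                                  epoch, baseline = "center", freqs = NULL,
                                  time_smooth = 4, scale_smooth = 1,
                                  trials = NULL) {
  if (is.null(freqs)) freqs <- band_freqs(band)
  tr_all <- sort(unique(epochs$trial[!is.na(epochs$trial)]))
  if (!is.null(trials)) tr_all <- intersect(tr_all, trials)
  has_both <- vapply(tr_all, function(tr) {
    e <- epochs[!is.na(epochs$trial) & epochs$trial == tr, ]
    all(c(epoch, baseline) %in% e$label)
  }, logical(1))
  tr_all <- tr_all[has_both]
  pairnames <- as.vector(outer(chans_a, chans_b, paste, sep = "|"))
  beh <- res <- matrix(NA_real_, length(pairnames), length(tr_all),
                       dimnames = list(pairnames, tr_all))
  for (k in seq_along(tr_all)) {
    e <- epochs[!is.na(epochs$trial) & epochs$trial == tr_all[k], ]
    for (lab in c(epoch, baseline)) {
      row <- e[e$label == lab, ][1, ]
      m <- pair_coh_interval_means(lfp, chans_a, chans_b,
                                   c(row$t_start_s, row$t_end_s), freqs,
                                   time_smooth, scale_smooth)
      if (lab == epoch) beh[, k] <- as.vector(m) else res[, k] <- as.vector(m)
    }
  }
  list(behavior = beh, resting = res, trials = tr_all)
}

#' Build a coherence change map with permutation significance
#'
#' For every channel pair between two regions, computes the per-trial
#' band-averaged wavelet coherence during a behavioral epoch and during the
#' same trial's center/rest baseline, the coherence change score, and its
#' Monte-Carlo permutation significance (shared label permutations across
#' voxels). A 32-site x 32-site cortical pairing yields the 1024-voxel map.
#'
#' @param session List with elements `lfp` (an [lfp_recording()]) and
#'   `epochs` (epoch table), e.g. from [load_session()] or
#'   [generate_dataset()].
#' @param region_a,region_b Region labels; all channels of each region are
#'   used unless `chans_a`/`chans_b` are given.
#' @param band Band label or numeric range (Hz).
#' @param epoch Behavioral epoch label.
#' @param alpha Per-voxel significance level; required, no default (the
#'   method family uses both 0.05 and 0.01).
#' @param n_perm Permutations per voxel.
#' @param baseline Baseline epoch label (center/rest).
#' @param chans_a,chans_b Optional explicit channel id vectors.
#' @param freqs,time_smooth,scale_smooth Coherence estimation settings.
#' @param seed Optional RNG seed for the permutations.
#' @param trials Optional subset of trial ids.
#' @return Object of class `coherence_change_map`: matrices `scores`, `p`,
#'   `mask` (significant voxels) over chans_a x chans_b, plus metadata. When
#'   no trial carries both epochs, an empty map with `status =
#'   "no usable trials"`.
#' @export
build_change_map <- function(session, region_a, region_b, band, epoch,
                             alpha, n_perm = 3000, baseline = "center",
                             chans_a = NULL, chans_b = NULL, freqs = NULL,
                             time_smooth = 4, scale_smooth = 1, seed = NULL,
                             trials = NULL) {
  if (missing(alpha)) stop("alpha is a required parameter")
  lfp <- session$lfp
  epochs <- session$epochs
  if (is.null(chans_a)) chans_a <- lfp$channels$id[lfp$channels$region ==
                                                     region_a]
  if (is.null(chans_b)) chans_b <- lfp$channels$id[lfp$channels$region ==
                                                     region_b]
  if (length(chans_a) == 0 || length(chans_b) == 0) {
    stop("both regions must have channels in the recording")
  }
  cm <- cwc_trial_epoch_means(lfp, chans_a, chans_b, band, epochs, epoch,
                              baseline, freqs, time_smooth, scale_smooth,
                              trials)
  na <- length(chans_a); nb <- length(chans_b)
  empty <- matrix(NA_real_, na, nb, dimnames = list(chans_a, chans_b))
  if (length(cm$trials) == 0) {
    return(structure(list(scores = empty, p = empty,
                          mask = matrix(FALSE, na, nb,
                                        dimnames = dimnames(empty)),
                          region_a = region_a, region_b = region_b,
                          band = resolve_band(band)$label, epoch = epoch,
                          alpha = alpha, n_perm = n_perm, n_trials = 0,
                          status = "no usable trials"),
                     class = "coherence_change_map"))
  }
  beh <- cm$behavior; res <- cm$resting
  n1 <- ncol(beh); n2 <- ncol(res); ntot <- n1 + n2
  V <- cbind(beh, res)                               # [n_vox x ntot]
  scores <- (rowMeans(beh) - rowMeans(res)) /
    pmax(rowMeans(beh) + rowMeans(res), 1e-300)
  scores[rowMeans(beh) + rowMeans(res) == 0] <- NA_real_
  obs <- rowMeans(beh) - rowMeans(res)
  W <- with_seed(seed, {
    w <- matrix(-1 / n2, ntot, n_perm)
    for (j in seq_len(n_perm)) w[sample.int(ntot, n1), j] <- 1 / n1
    w
  })
  pd <- V %*% W                                      # [n_vox x n_perm]
  p_up <- (1 + rowSums(pd >= obs)) / (n_perm + 1)
  p_dn <- (1 + rowSums(pd <= obs)) / (n_perm + 1)
  p <- pmin(1, 2 * pmin(p_up, p_dn))
  pm <- matrix(p, na, nb, dimnames = list(chans_a, chans_b))
  sm <- matrix(scores, na, nb, dimnames = list(chans_a, chans_b))
  structure(list(scores = sm, p = pm, mask = !is.na(sm) & pm <= alpha,
                 region_a = region_a, region_b = region_b,
                 band = resolve_band(band)$label, epoch = epoch,
                 alpha = alpha, n_perm = n_perm, n_trials = length(cm$trials),
                 status = "ok"),
            class = "coherence_change_map")
}

#' @export
print.coherence_change_map <- function(x, ...) {
  cat(sprintf(paste0("<coherence_change_map> %s x %s, %s, epoch '%s': ",
                     "%d voxels, %d significant at alpha=%g (%s)\n"),
              x$region_a, x$region_b, x$band, x$epoch, length(x$scores),
              sum(x$mask, na.rm = TRUE), x$alpha, x$status))
  invisible(x)
}

#' Score a change map against the synthetic ground truth
#'
#' A voxel counts as a recovered hotspot when it is significant with a
#' positive change score and its (unordered) channel pair was injected for
#' the map's band and epoch. Sensitivity is the recovered fraction of
#' injected voxels; the false-discovery proportion is the fraction of
#' significant-positive voxels that were not injected.
#'
#' @param map A `coherence_change_map`.
#' @param ground_truth A [ground_truth()].
#' @return List: `sensitivity`, `fdp`, `n_injected`, `n_detected`,
#'   `n_true_positive`.
#' @export
evaluate_map_recovery <- function(map, ground_truth) {
  hs <- ground_truth$hotspots
  if (nrow(hs) > 0) {
    hs <- hs[hs$band == map$band & hs$epoch == map$epoch, , drop = FALSE]
  }
  keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  inj <- if (nrow(hs) > 0) keys(hs$channel_a, hs$channel_b) else character(0)
  det <- which(map$mask & map$scores > 0, arr.ind = TRUE)
  detk <- keys(rownames(map$scores)[det[, 1]],
               colnames(map$scores)[det[, 2]])
  tp <- sum(inj %in% detk)
  list(sensitivity = if (length(inj)) tp / length(inj) else NA_real_,
       fdp = if (length(detk)) sum(!detk %in% inj) / length(detk) else 0,
       n_injected = length(inj), n_detected = length(detk),
       n_true_positive = tp)
}

#' One-way ANOVA with Tukey HSD over relative coherence conditions
#'
#' Compares baseline-normalized coherence (condition coherence divided by
#' the same trial's center/rest coherence) across behavioral epochs and the
#' optical-stimulation condition: a fixed-effects one-way F test followed by
#' all pairwise comparisons with Tukey's Honestly Significant Difference
#' procedure. The family-level alpha is Bonferroni-divided by the number of
#' band/region-pair families tested.
#'
#' @param rel Data frame with columns `condition` and `ratio`.
#' @param alpha Significance level before Bonferroni division.
#' @param n_families Number of families (bands x region pairs) tested.
#' @return List: `F_stat`, `df`, `p_value`, `tukey` (data frame of pairwise
#'   comparisons with `significant` at the corrected level), `alpha_adj`,
#'   `group_means`.
#' @export
compare_epoch_coherence <- function(rel, alpha = 0.05, n_families = 1) {
  stopifnot(all(c("condition", "ratio") %in% names(rel)))
  cnt <- table(rel$condition)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    warning("dropping conditions with < 2 observations: ",
            paste(small, collapse = ", "))
    rel <- rel[!rel$condition %in% small, , drop = FALSE]
  }
  if (length(unique(rel$condition)) < 2) {
    stop("need at least 2 conditions with >= 2 observations each")
  }
  rel$condition <- factor(rel$condition)
  alpha_adj0 <- alpha / n_families
  if (var(rel$ratio) == 0) {
    # all observations identical: no between- or within-group variance
    prs <- utils::combn(levels(rel$condition), 2)
    return(list(F_stat = 0, df = c(nlevels(rel$condition) - 1,
                                   nrow(rel) - nlevels(rel$condition)),
                p_value = 1,
                tukey = data.frame(comparison = paste(prs[2, ], prs[1, ],
                                                      sep = "-"),
                                   diff = 0, lwr = 0, upr = 0, p_adj = 1,
                                   significant = FALSE,
                                   stringsAsFactors = FALSE),
                alpha_adj = alpha_adj0,
                group_means = tapply(rel$ratio, rel$condition, mean)))
  }
  fit <- aov(ratio ~ condition, data = rel)
  tab <- summary(fit)[[1]]
  alpha_adj <- alpha / n_families
  tk <- TukeyHSD(fit, conf.level = 1 - alpha_adj)$condition
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] <= alpha_adj,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(F_stat = tab[1, "F value"],
       df = c(tab[1, "Df"], tab[2, "Df"]),
       p_value = tab[1, "Pr(>F)"], tukey = tukey, alpha_adj = alpha_adj,
       group_means = tapply(rel$ratio, rel$condition, mean))
}

#' Per-trial relative (baseline-normalized) coherence table
#'
#' For each trial and condition epoch, the band coherence averaged over the
#' supplied channel pairs is divided by the same quantity in the trial's
#' center/rest epoch. The post-session optical-stimulation block (which has
#' no trial structure) is split into pseudo-trials of the baseline epoch's
#' duration and normalized by the session-mean baseline coherence.
#'
#' @param session Session list (`lfp`, `epochs`).
#' @param chans_a,chans_b Channel id vectors; coherence is averaged across
#'   all pairings.
#' @param band Band label or range.
#' @param conditions Epoch labels to include (besides the baseline).
#' @param baseline Baseline epoch label.
#' @param freqs,time_smooth,scale_smooth Estimation settings.
#' @return Data frame with columns `trial`, `condition`, `ratio`.
#' @export
relative_coherence <- function(session, chans_a, chans_b,
                               band = "low_gamma",
                               conditions = c("cue", "decision", "approach"),
                               baseline = "center", freqs = NULL,
                               time_smooth = 4, scale_smooth = 1) {
  lfp <- session$lfp; epochs <- session$epochs
  if (is.null(freqs)) freqs <- band_freqs(band)
  rows <- list()
  tr_all <- sort(unique(epochs$trial[!is.na(epochs$trial)]))
  base_vals <- c()
  for (tr in tr_all) {
    e <- epochs[!is.na(epochs$trial) & epochs$trial == tr, ]
    if (!baseline %in% e$label) next
    brow <- e[e$label == baseline, ][1, ]
    bm <- mean(pair_coh_interval_means(lfp, chans_a, chans_b,
                                       c(brow$t_start_s, brow$t_end_s),
                                       freqs, time_smooth, scale_smooth),
               na.rm = TRUE)
    base_vals <- c(base_vals, bm)
    for (lab in intersect(conditions, e$label)) {
      crow <- e[e$label == lab, ][1, ]
      cmn <- mean(pair_coh_interval_means(lfp, chans_a, chans_b,
                                          c(crow$t_start_s, crow$t_end_s),
                                          freqs, time_smooth, scale_smooth),
                  na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(trial = tr, condition = lab, ratio = cmn / bm)
    }
  }
  opto <- epochs[epochs$label == "optostim", , drop = FALSE]
  if (nrow(opto) > 0 && "optostim" %in% conditions && length(base_vals) > 0) {
    dur <- mean(epochs$t_end_s[epochs$label == baseline] -
                  epochs$t_start_s[epochs$label == baseline])
    starts <- seq(opto$t_start_s[1], opto$t_end_s[1] - dur, by = dur)
    gmean <- mean(base_vals)
    for (k in seq_along(starts)) {
      om <- mean(pair_coh_interval_means(lfp, chans_a, chans_b,
                                         c(starts[k], starts[k] + dur),
                                         freqs, time_smooth, scale_smooth),
                 na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(trial = NA_integer_, condition = "optostim",
                   ratio = om / gmean)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heatmap of a coherence change map
#'
#' @param map A `coherence_change_map`.
#' @param file Optional PNG path; plots to the active device when `NULL`.
#' @param only_significant Zero out non-significant voxels (Fig.-5 style).
#' @return Invisibly, the plotted matrix.
#' @export
plot_change_map <- function(map, file = NULL, only_significant = FALSE) {
  z <- map$scores
  if (only_significant) z[!map$mask] <- 0
  if (!is.null(file)) {
    png(file, width = 640, height = 560)
    on.exit(dev.off())
  }
  image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(-1, 1),
        col = hcl.colors(64, "Blue-Red 3"),
        xlab = map$region_a, ylab = map$region_b,
        main = sprintf("%s coherence change, epoch '%s' (alpha=%g)",
                       map$band, map$epoch, map$alpha))
  invisible(z)
}
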