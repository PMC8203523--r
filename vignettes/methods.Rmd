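---
title: "Methods: coherence mapping and unit physiology in bfcoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence mapping and unit physiology in bfcoh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bfcoh` analyses simultaneous multichannel recordings from the basal
forebrain (BF) and two cortical targets (orbitofrontal cortex, OFC, and
visual association cortex, V2): local field potentials (LFPs) sampled at
1250 Hz after 0--300 Hz low-pass filtering and decimation, and sorted spike
units with 20 kHz mean waveforms. This vignette describes the statistical
machinery, the parameters that matter, the synthetic-data generator used to
validate every stage, and the limits of what those validations show.

## Wavelet spectrogram and coherence

Time-frequency decomposition uses the analytic complex Morlet wavelet with
center-frequency parameter `omega0 = 6` on a logarithmic grid of 8 voices
per octave spanning 1--110 Hz (`cwt_freq_grid()`). The transform is
computed by FFT with the wavelet's Fourier amplitude scaled by
`sqrt(scale)`, so white noise has a flat expected power across the grid --
a property the test suite checks directly. Samples inside the cone of
influence (closer than `sqrt(2) * scale` to a recording edge) are flagged
and excluded from band averages by default.

Wavelet coherence between two channels requires smoothing -- otherwise the
magnitude coherence is identically 1, which the suite keeps as a
degeneracy guard. We smooth cross- and auto-spectra with a Gaussian in
time whose SD is `time_smooth` wavelet scales (default 4) and a boxcar
over `scale_smooth` neighbouring grid scales (default 1), in the style of
Torrence and Webster, then form magnitude-squared coherence
`|S(Wa conj(Wb))|^2 / (S|Wa|^2 S|Wb|^2)` and average it over the band's
grid frequencies. Because the same positive smoothing weights are applied
to numerator and denominator, values stay in [0, 1] by Cauchy--Schwarz.
Whether field studies report magnitude or magnitude-squared coherence is
often ambiguous; `squared = FALSE` switches to the magnitude convention.
Larger `time_smooth` lowers the null coherence floor (about 0.15 in the
gamma bands at the default) at the cost of temporal resolution; the floor
cancels out of baseline-contrast statistics, which is why all inferential
quantities below are within-trial contrasts.

The two gamma bands are low gamma 45--75 Hz and high gamma 75--100 Hz. A
"low and high gamma (40--100 Hz)" range is treated as the union of the two
bands, not as a third band.

## Behavioral epochs and the coherence change score

Trials are divided into six epochs -- center/rest, cue presentation (4 s),
decision making, reward approach, consumption, return -- followed, at the
end of a session, by an optical-stimulation block. All interval logic uses
seconds from session start and half-open `[start, end)` intervals.

For a channel pair, the per-trial band-averaged coherence during a
behavioral epoch (`CWC of BEHAVIOR`) and during the same trial's
center/rest baseline (`CWC of RESTING`) feed the coherence change score

    score = (mean(behavior) - mean(resting)) / (mean(behavior) + mean(resting))

bounded in [-1, +1], antisymmetric under swapping the groups, and 0 when
the means agree. When both means are zero the voxel is reported missing
rather than propagating NaN.

Significance is assessed by a Monte-Carlo permutation test: the two groups
are pooled, label-permuted groups of the original sizes are redrawn
`n_perm` times (default 3000; the calibration studies scale down to 1000),
and the observed difference of means is compared to the permutation
distribution. The test is two-sided by default because maps report both
increases and decreases; a one-sided variant tests increases only, and a
`replace = TRUE` flag swaps the label permutation for a bootstrap from the
merged distribution. `alpha` is deliberately a required argument -- the
method family uses 0.05 for epoch-level tests and 0.01 for voxel maps, and
a silent default would hide that choice. The permutation statistic is the
difference of means; the change score itself is reported descriptively
alongside it. p-values use the add-one convention `(1 + #extreme) /
(n_perm + 1)`, which keeps the type-I error at or slightly below nominal;
the suite verifies calibration at alpha 0.05 and 0.01 against exact
binomial bounds.

`build_change_map()` applies this to every channel pair between two
regions (32 x 32 cortical sites give the 1024-voxel map), sharing one set
of label permutations across voxels, which is statistically valid per
voxel and much faster. No correction across voxels is applied beyond the
per-voxel alpha; this matches the mapping convention but is
anti-conservative, and downstream users should treat isolated voxels
accordingly.

Epoch-level comparisons of relative coherence (condition coherence divided
by the trial's baseline coherence, concatenated across trials) use a
one-way fixed-effects ANOVA followed by Tukey's HSD for all pairwise
comparisons, with the family alpha Bonferroni-divided across the
band/region-pair families tested. The optical-stimulation block has no
trial structure, so it is split into baseline-length pseudo-trials
normalized by the session-mean baseline coherence.

## Spike-unit physiology

*Epoch modulation.* Per-trial firing rates in an epoch versus the
center/rest baseline are compared with a two-sided Wilcoxon rank-sum test
(exact for small samples, normal approximation with tie correction
otherwise, as implemented in base R); per-trial Z-scores use the baseline
mean and SD, and min--max feature scaling over the session is emitted for
population displays. Both per-trial and trial-averaged Z-scores are
available since either convention is common.

*Optogenetic tagging.* A unit is light-responsive when its firing rate
during the 10-ms pulses deviates from the mean pre-stimulus control rate
(2000-ms windows) by more than 2 control SDs, with at least 100 stimuli
required. The response window defaults to the pulse duration but is a
parameter, since "during the light pulse" can also reasonably mean a short
post-onset latency window. The generator's default protocol delivers 2-s
trains at 20 Hz repeated 10 times (400 pulses) -- a plausible five-minute
post-session tagging block; the within-train pulse period is exposed as a
parameter because protocols differ.

*Connectivity.* Cross-correlograms use 0.5-ms bins over +/- 50 ms. The
baseline predictor is the correlogram convolved with a 10-ms SD Gaussian
(edge-renormalized); a `hollow_fraction` parameter can remove central
weight, as several correlogram methods do, but the default is the plain
Gaussian. Per bin, the smallest count whose cumulative Poisson probability
at the predicted rate reaches the 99.99th percentile forms the upper
threshold (the lower threshold is the analogous 0.01st percentile), and a
connection is declared when at least two consecutive bins within +1.5 to
+5 ms cross a threshold -- excitatory above, inhibitory below. The
thresholds are checked bin-exactly against a brute-force Poisson quantile
oracle, and the detector's false-detection rate on independent Poisson
pairs is verified to be consistent with the analytic null.

*Waveform features and classification.* Trough-to-peak (TP) latency is
measured on the channel with the largest waveform deviation, from the
global trough to the subsequent maximum. The burst index is the mean
autocorrelogram count in the 3--5 ms bins divided by the mean in the
200--300 ms bins (1-ms bins; a bin counts toward a range when it lies
entirely inside it). Waveform PCA upsamples the peak-channel waveform 5x
(cubic interpolation, 20 kHz to 100 kHz), takes the second finite
difference, and crops 0--0.8 ms after the trough before projecting onto
the first two principal axes. K-means (k = 6, seeded multi-restart) uses
TP latency, w-PCA1 and w-PCA2 after z-standardization; a preliminary
excitatory/inhibitory split uses TP > 0.485 ms or rate < 6 Hz. Cluster
labels are cross-validated with bagged decision trees (bootstrap
aggregation with all four features -- TP latency, w-PCA1, w-PCA2, mean
rate -- available to every tree) trained without the cholinergic units,
whose labels are then predicted; out-of-bag accuracy is the reported
validation metric.

*Spike-triggered gamma.* For a trigger (typically cholinergic) unit, band
power from the wavelet transform is averaged over the 500 ms before and
the 500 ms after each spike, giving one before- and one after-sample per
spike. The paired distributions are compared with a two-sample
Kolmogorov--Smirnov test (asymptotic p), the normalized difference score
`(after - before) / (after + before)` summarizes direction, and per-cell
summaries report the percentage of a probe's 32 sites with significant
changes. Triggers are thinned to non-overlapping windows by default
because the KS test assumes independent samples; per-spike window means
are used rather than pooling all power samples (a pooled mode exists
behind the `per_spike = FALSE` flag, for descriptive use only) for the
same reason. The summary alpha defaults to 0.05,
with 0.01 available where stricter mapping is wanted.

## The synthetic-data generator

No public recordings accompany this analysis family, so validation runs on
a seeded statistical generator (`synth_config()`, `generate_dataset()`)
that reproduces the features the statistics rely on, with full
ground-truth bookkeeping:

- Probe geometry: BF 64 sites on 8 shanks, OFC and V2 32 sites on 4
  shanks each, 100 um vertical pitch.
- LFP: per channel, 1/f spectrally shaped Gaussian background (exponent 1
  by default, SD 10 uV) plus an independent band-limited Gaussian
  component per gamma band (SD 5 uV). Coherence hotspots replace a
  fraction `coupling` of a pair's band component with a shared source
  during one epoch, preserving band power, so band coherence rises with
  coupling only for that pair and epoch; the shared source can be lagged,
  though coherence magnitude is insensitive to small lags for narrow-band
  signals.
- Spikes: Poisson trains with per-epoch rate multipliers; cholinergic
  units default to ~2 Hz. Excitatory couplings insert post-spikes with
  probability `efficacy` at `lag +/- jitter`; inhibitory couplings delete
  post-spikes in the lag window (thinning), which makes the correlogram
  trough analytically predictable. Light-responsive units add one spike
  per pulse with the stated probability. Waveforms come from biphasic
  wide (TP 0.6 ms) and narrow (TP 0.25 ms) templates with small seeded
  perturbations.
- Spike-triggered effects multiply a channel's band component by `gain`
  for 500 ms after each trigger spike.

The generator is statistical, not biophysical: it contains no membrane or
network dynamics, no theta or slower rhythms, no volume conduction, no
movement artifacts, and its noise is Gaussian and stationary within
epochs. Passing recovery tests therefore demonstrates that the estimators
detect the structures they claim to detect at realistic effect sizes and
trial counts -- not that real recordings satisfy the generator's
assumptions.

## Validation scale and numerical choices

The recovery studies use problem sizes chosen to exercise the statistics
at meaningful power while keeping a full validation run in minutes:
hotspot-map recovery uses 8 x 8-site probe subsets (64 voxels), 20 trials,
coupling 0.8, 1000 permutations per voxel, 20 seeds; the full 32 x 32
(1024-voxel) map shape is exercised separately. Permutation calibration
uses 500 null replications at 1000 permutations; correlogram validation
uses 1000 independent Poisson pairs and 1000 threshold-oracle rates;
optotagging uses 200 null units and 20 injected responders. The
`scripts/acceptance.R` entry point re-runs all of these from scratch for
any seed.

Numerical conventions worth knowing: FFT-based convolutions are
zero-padded and edge-renormalized rather than circular; coherence segment
extraction pads each scored interval by 0.3 s where recording exists so
cone-of-influence and smoothing margins fall outside the scored samples;
degenerate inputs (zero-variance pools, both-zero means, fewer distinct
feature points than clusters) return defined results or explicit missing
values rather than NaN; and every stochastic routine accepts a seed and
restores the caller's RNG state.

## Known limitations

- The 1/f background has no oscillatory structure outside the injected
  bands, so cross-frequency leakage is milder than in real LFPs.
- Shared hotspot sources are zero-lag by default; directed metrics are out
  of scope.
- The permutation map applies no cross-voxel multiplicity control beyond
  the per-voxel alpha.
- Optotag control windows that overlap preceding stimulation trains
  inflate the control SD slightly for strongly responsive units; this is
  conservative for tagging decisions.
- Spike sorting, drift correction, and anatomical registration are
  upstream concerns and are not modelled.
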