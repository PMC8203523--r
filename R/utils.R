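# shared internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

# derive a reproducible sub-seed (< 2^31) from a base seed and a stage tag
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}

#' Default gamma frequency bands
#'
#' Low gamma spans 45--75 Hz and high gamma 75--100 Hz, the two bands in which
#' basalo-cortical and cortico-cortical coherence is analysed.
#'
#' @return Named list of `c(f_lo, f_hi)` pairs in Hz.
#' @export
default_gamma_bands <- function() {
  list(low_gamma = c(45, 75), high_gamma = c(75, 100))
}

# Resolve a band given as a label (into `bands`) or a numeric c(lo, hi).
# Returns list(label=, range=).
resolve_band <- function(band, bands = default_gamma_bands()) {
  if (is.character(band)) {
    if (!band %in% names(bands)) {
      stop("unknown band label '", band, "'; known: ",
           paste(names(bands), collapse = ", "))
    }
    list(label = band, range = as.numeric(bands[[band]]))
  } else if (is.numeric(band) && length(band) == 2) {
    if (!(band[1] > 0 && band[2] > band[1])) {
      stop("band edges must satisfy 0 < f_lo < f_hi")
    }
    list(label = sprintf("%g-%gHz", band[1], band[2]), range = as.numeric(band))
  } else {
    stop("band must be a label or a numeric c(f_lo, f_hi)")
  }
}

#' Logarithmic wavelet frequency grid
#'
#' Dyadic grid of analysis frequencies used by the wavelet spectrogram,
#' covering 1--110 Hz by default with a fixed number of voices per octave.
#'
#' @param f_min,f_max Grid limits in Hz.
#' @param voices Voices (grid points) per octave.
#' @return Increasing numeric vector of frequencies in Hz.
#' @export
cwt_freq_grid <- function(f_min = 1, f_max = 110, voices = 8) {
  stopifnot(f_min > 0, f_max > f_min, voices >= 1)
  2^(seq(log2(f_min), log2(f_max), by = 1 / voices))
}

# frequencies of the default grid falling inside a band; guarantees >= 3
band_freqs <- function(band, freqs = cwt_freq_grid()) {
  rng <- resolve_band(band)$range
  fs <- freqs[freqs >= rng[1] & freqs <= rng[2]]
  if (length(fs) < 3) fs <- exp(seq(log(rng[1]), log(rng[2]), length.out = 4))
  fs
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' (1 = identical partitions up to label permutation, ~0 = chance). Used to
#' score cluster-recovery validations.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# simple interval intersection helper: sample indices (1-based) of [t0, t1)
# within a signal of length n at `rate`, offset by segment start time
interval_indices <- function(t0, t1, rate, seg_start = 0, n = Inf) {
  i0 <- max(1L, floor((t0 - seg_start) * rate) + 1L)
  i1 <- min(as.integer(n), ceiling((t1 - seg_start) * rate))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}
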