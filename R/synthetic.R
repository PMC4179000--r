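## Synthetic EEG cohorts. Epochs are sums of one sinusoid per frequency band
## (shared random in-band frequency per band, random phase per channel) on
## top of 1/f-shaped noise; emotional classes differ by multiplicative
## band-amplitude factors, which gives learnable band-power structure without
## asserting any neuroscientific claim about real valence/arousal signatures.

# Baseline per-band sinusoid amplitudes (microvolts), decreasing with
# frequency as in resting EEG spectra.
default_band_amplitudes <- function() {
  c(theta = 4, alpha = 5, low_beta = 3, high_beta = 2, gamma = 1.5)
}

#' Default class-effect amplitude factors
#'
#' Multiplicative band-amplitude factors applied to the high class of each
#' task: high arousal scales high beta and gamma up and alpha down; high
#' valence scales theta up and low beta down. The low class of either task
#' uses factor 1 in every band.
#'
#' @return Named list with `valence` and `arousal` factor vectors (length 5).
#' @export
default_band_effects <- function() {
  list(
    valence = c(theta = 1.5, alpha = 1, low_beta = 0.75, high_beta = 1,
                gamma = 1),
    arousal = c(theta = 1, alpha = 0.7, low_beta = 1, high_beta = 1.5,
                gamma = 1.5))
}

# 1/f-shaped noise via spectral shaping of white Gaussian noise, mixed with
# a white component, scaled to the requested total power.
pink_noise <- function(n, power) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  x <- shaped / stats::sd(shaped) + 0.25 * stats::rnorm(n)
  x * sqrt(power / mean(x^2))
}

#' Simulate one multi-channel EEG epoch
#'
#' Each band contributes a sinusoid at a random in-band frequency (drawn once
#' per band per epoch) with an independent random phase per channel and
#' amplitude `band_amps[b]`; 1/f-shaped plus white noise is added at
#' `noise_level` times the total oscillatory power (default 0.1, i.e.
#' -10 dB). Deterministic given `seed`.
#'
#' @param band_amps Named amplitude vector, one entry per band (microvolts).
#' @param n_channels Channel count (default 62).
#' @param sampling_rate Hz (default 500).
#' @param duration Seconds (default 3.5).
#' @param noise_level Noise power relative to summed sinusoid power.
#' @param bands Band definitions (default [default_bands()]).
#' @param seed Integer seed.
#' @param epoch_id,participant_id Identifiers for the record.
#' @return An [epoch_record()].
#' @export
simulate_epoch <- function(band_amps, n_channels = 62L, sampling_rate = 500,
                           duration = 3.5, noise_level = 0.1,
                           bands = default_bands(), seed = 1L,
                           epoch_id = "epoch", participant_id = "participant") {
  band_names <- vapply(bands, `[[`, character(1), "name")
  if (!all(band_names %in% names(band_amps))) {
    stop("band_amps must name every band")
  }
  n <- round(sampling_rate * duration)
  t <- (seq_len(n) - 1) / sampling_rate
  withr::with_seed(seed, {
    sig <- matrix(0, n_channels, n)
    osc_power <- 0
    freqs <- stats::setNames(rep(NA_real_, length(bands)), band_names)
    for (b in bands) {
      amp <- band_amps[[b$name]]
      if (amp <= 0) next
      width <- b$high - b$low
      freq <- stats::runif(1, b$low + 0.15 * width, b$high - 0.15 * width)
      freqs[b$name] <- freq
      phase <- stats::runif(n_channels, 0, 2 * pi)
      sig <- sig + amp * sin(outer(phase, 2 * pi * freq * t, "+"))
      osc_power <- osc_power + amp^2 / 2
    }
    if (noise_level > 0) {
      for (ch in seq_len(n_channels)) {
        sig[ch, ] <- sig[ch, ] + pink_noise(n, noise_level * osc_power)
      }
    }
    ep <- epoch_record(sig, sampling_rate, epoch_id, participant_id)
    attr(ep, "band_freqs") <- freqs   # drawn tone frequencies, for diagnostics
    ep
  })
}

# Joint high/low quadrant counts satisfying both marginals (greedy fill:
# HVHA first, then the remaining cells are forced).
quadrant_counts <- function(n_pos_valence, n_pos_arousal, total) {
  hvha <- min(n_pos_valence, n_pos_arousal)
  hvla <- n_pos_valence - hvha
  lvha <- n_pos_arousal - hvha
  lvla <- total - hvha - hvla - lvha
  if (lvla < 0) stop("inconsistent label marginals")
  c(hvha = hvha, lvha = lvha, lvla = lvla, hvla = hvla)
}

#' Simulate a labelled participant dataset
#'
#' Generates `n_trials` trials; each trial has one (valence, arousal) label
#' pair and contributes `epochs_per_trial` epochs (the two segments of one
#' recording), all sharing the trial's labels. Label counts match the
#' requested marginals exactly: trials are assigned to the four
#' valence-arousal quadrants greedily so both marginals are satisfied, then
#' shuffled deterministically. High-class epochs are generated with the
#' corresponding multiplicative band effects (the effects of the two tasks
#' combine multiplicatively).
#'
#' @param n_pos_valence,n_neg_valence,n_pos_arousal,n_neg_arousal Epoch
#'   counts per label; each pair must sum to the same total, and every count
#'   must be divisible by `epochs_per_trial`.
#' @param n_channels,sampling_rate,duration,noise_level,bands Passed to
#'   [simulate_epoch()].
#' @param band_effects Class effect factors as in [default_band_effects()].
#' @param effect_scale Exponent applied to the effect factors (0 removes all
#'   class signal, 1 is the default strength, >1 strengthens it).
#' @param epochs_per_trial Epochs per trial (default 2).
#' @param seed Integer seed.
#' @param participant_id Identifier.
#' @return List with `epochs` (list of [epoch_record()]), `labels` (data
#'   frame `epoch_id`, `valence`, `arousal`), `trial` and `segment` vectors.
#' @export
simulate_participant <- function(n_pos_valence, n_neg_valence,
                                 n_pos_arousal, n_neg_arousal,
                                 n_channels = 62L, sampling_rate = 500,
                                 duration = 3.5, noise_level = 0.1,
                                 bands = default_bands(),
                                 band_effects = default_band_effects(),
                                 effect_scale = 1,
                                 epochs_per_trial = 2L, seed = 1L,
                                 participant_id = "p1") {
  total <- n_pos_valence + n_neg_valence
  if (n_pos_arousal + n_neg_arousal != total) {
    stop("valence and arousal counts must sum to the same epoch total")
  }
  counts <- c(n_pos_valence, n_neg_valence, n_pos_arousal, n_neg_arousal)
  if (any(counts %% epochs_per_trial != 0)) {
    stop("label counts must be divisible by epochs_per_trial")
  }
  quad <- quadrant_counts(n_pos_valence, n_pos_arousal, total) %/%
    epochs_per_trial
  n_trials <- sum(quad)
  quad_v <- c(hvha = 1, lvha = -1, lvla = -1, hvla = 1)
  quad_a <- c(hvha = 1, lvha = 1, lvla = -1, hvla = -1)
  trial_v <- rep(quad_v, quad)
  trial_a <- rep(quad_a, quad)
  ord <- withr::with_seed(seed, sample.int(n_trials))
  trial_v <- trial_v[ord]; trial_a <- trial_a[ord]

  base_amps <- default_band_amplitudes()
  eff <- function(v, a) {
    f <- rep(1, length(base_amps)); names(f) <- names(base_amps)
    if (v > 0) f <- f * band_effects$valence[names(f)]^effect_scale
    if (a > 0) f <- f * band_effects$arousal[names(f)]^effect_scale
    base_amps * f
  }

  epochs <- vector("list", n_trials * epochs_per_trial)
  trial <- integer(length(epochs)); segment <- integer(length(epochs))
  ids <- character(length(epochs))
  k <- 0L
  for (tr in seq_len(n_trials)) {
    amps <- eff(trial_v[tr], trial_a[tr])
    for (s in seq_len(epochs_per_trial)) {
      k <- k + 1L
      ids[k] <- sprintf("t%03d_s%d", tr - 1L, s - 1L)
      epochs[[k]] <- simulate_epoch(
        amps, n_channels = n_channels, sampling_rate = sampling_rate,
        duration = duration, noise_level = noise_level, bands = bands,
        seed = (as.numeric(seed) * 100003 + k) %% 2147483647,
        epoch_id = ids[k], participant_id = participant_id)
      trial[k] <- tr; segment[k] <- s
    }
  }
  labels <- data.frame(
    epoch_id = ids,
    valence = rep(trial_v, each = epochs_per_trial),
    arousal = rep(trial_a, each = epochs_per_trial),
    stringsAsFactors = FALSE)
  list(epochs = epochs, labels = labels, trial = trial, segment = segment)
}

#' Simulate labelled feature-space clusters
#'
#' Two spherical Gaussian clusters in `dims` dimensions whose means are
#' `mean_separation` apart along the first axis — direct fixtures for
#' classifier tests without running the signal layers.
#'
#' @param n_pos,n_neg Points per class.
#' @param dims Dimensionality.
#' @param mean_separation Distance between class means.
#' @param spread Within-class standard deviation.
#' @param seed Integer seed.
#' @return List with `X` (matrix) and `y` (+-1 labels).
#' @export
simulate_feature_clusters <- function(n_pos, n_neg, dims = 2L,
                                      mean_separation = 2, spread = 1,
                                      seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  withr::with_seed(seed, {
    Xp <- matrix(stats::rnorm(n_pos * dims, sd = spread), n_pos, dims)
    Xn <- matrix(stats::rnorm(n_neg * dims, sd = spread), n_neg, dims)
    Xp[, 1] <- Xp[, 1] + mean_separation
    list(X = rbind(Xp, Xn), y = c(rep(1, n_pos), rep(-1, n_neg)))
  })
}

#' Simulate a multi-participant cohort with extracted features
#'
#' Convenience wrapper: simulates each profile row with
#' [simulate_participant()], extracts band-power vectors for every epoch and
#' returns the per-participant structure consumed by
#' [split_half_analysis()] and [segment_consistency_analysis()].
#'
#' @param profiles Data frame as returned by [cohort_profiles()] (any subset
#'   of rows).
#' @param seed Base seed; participant `i` uses `seed + i`.
#' @param ... Passed to [simulate_participant()].
#' @return List of participants, each with `X`, `valence`, `arousal`,
#'   `trial`, `segment`.
#' @export
simulate_cohort_features <- function(profiles = cohort_profiles(), seed = 1L,
                                     bands = default_bands(), ...) {
  lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    part <- simulate_participant(
      pr$n_pos_valence, pr$n_neg_valence, pr$n_pos_arousal, pr$n_neg_arousal,
      seed = seed + i, bands = bands,
      participant_id = paste0("p", pr$participant), ...)
    X <- t(vapply(part$epochs, extract_sp_vector, bands = bands,
                  numeric(length(bands) * nrow(part$epochs[[1]]$signal))))
    list(X = X, valence = part$labels$valence, arousal = part$labels$arousal,
         trial = part$trial, segment = part$segment)
  })
}
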