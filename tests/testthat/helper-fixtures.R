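# Shared fixtures built in code.

# Strong-effect profile: the high-arousal class scales two band amplitudes
# by a factor of 3; valence carries no signal.
strong_arousal_effects <- function() {
  list(valence = c(theta = 1, alpha = 1, low_beta = 1, high_beta = 1,
                   gamma = 1),
       arousal = c(theta = 1, alpha = 1, low_beta = 1, high_beta = 3,
                   gamma = 3))
}

# Small labelled participant with band-power features already extracted.
small_feature_participant <- function(seed = 1L, n_channels = 4L,
                                      counts = c(14, 6, 10, 10),
                                      effects = default_band_effects(),
                                      effect_scale = 1) {
  part <- simulate_participant(counts[1], counts[2], counts[3], counts[4],
                               n_channels = n_channels, seed = seed,
                               band_effects = effects,
                               effect_scale = effect_scale)
  X <- t(sapply(part$epochs, extract_sp_vector))
  list(X = X, valence = part$labels$valence, arousal = part$labels$arousal,
       trial = part$trial, segment = part$segment, part = part)
}

# Well-separated two-cluster fixture for classifier tests.
separable_clusters <- function(n_pos = 15L, n_neg = 10L, dims = 3L,
                               seed = 1L) {
  simulate_feature_clusters(n_pos, n_neg, dims = dims, mean_separation = 6,
                            spread = 1, seed = seed)
}
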