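# Shared fixtures: a compact radar setup (shorter record, smaller range
# window) keeps unit tests fast; the acceptance tests use the full defaults.

quick_config <- function(N = 600L) {
  radar_config(M = 120L, N = N)
}

# Noiseless chest-only echo for ground-truth comparisons.
chest_only_echo <- function(config, motion) {
  synthesize_echo(config,
                  radar_scene(statics = list(), dc_offset = 0, noise_sigma = 0),
                  motion)
}

# Fast-time row nearest a given range (1-based).
row_at_range <- function(config, range_m) {
  round(2 * range_m / C_LIGHT / config$delta_T) + 1L
}

# Synthetic vmd_result with pure-tone modes at given frequencies (Hz),
# for classification tests that need controlled centre frequencies.
fake_vmd_result <- function(freqs_hz, Ts = 0.05, N = 1000L, amps = NULL) {
  if (is.null(amps)) amps <- rep(1, length(freqs_hz))
  tt <- (0:(N - 1)) * Ts
  modes <- t(vapply(seq_along(freqs_hz),
                    function(i) amps[i] * sin(2 * pi * freqs_hz[i] * tt),
                    numeric(N)))
  structure(list(modes = modes, omegas = freqs_hz * Ts,
                 omegas_hz = freqs_hz, Ts = Ts),
            class = "vmd_result")
}
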