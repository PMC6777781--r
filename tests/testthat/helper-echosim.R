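# Shared fixtures built in code.

# a small, fast synthetic measurement series (reflecting only by default)
quick_series <- function(distances = seq(0.7, 3.9, by = 0.4),
                         disk_states = "reflecting", replicates = 1L,
                         prop = propagation_config(), seed = 42L) {
  synthesize_series(distances = distances, disk_states = disk_states,
                    replicates = replicates, prop = prop, seed = seed)
}

# propagation settings with the room tail and noise floor switched off
quiet_prop <- function(...) {
  propagation_config(tail_level_db = -Inf, noise_floor_db = -Inf, ...)
}
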