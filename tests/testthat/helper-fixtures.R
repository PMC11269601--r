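# Shared test fixtures, all built in code.

# Keypress frame for a single trial from explicit keys/latencies.
press_frame <- function(keys, latencies, participant = "p1", group = "M10",
                        phase = "train", trial = 1L) {
  data.frame(participant = participant, group = group, phase = phase,
             trial = trial, press_index = seq_along(keys), key = keys,
             latency_ms = latencies, stringsAsFactors = FALSE)
}

# The target sequence used throughout.
TARGET <- c(4L, 1L, 3L, 2L, 4L)

# Copy a synth_config with some fields replaced.
within_cfg <- function(config, ...) {
  utils::modifyList(config, list(...))
}

# A quiet, tiny synthetic config for structural tests; any synth_config
# argument can be overridden.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 1L, noise_cv = 0, error_prob = 0,
         warmup_inflation = 1, seed = 11L),
    list(...))
  do.call(synth_config, args)
}
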