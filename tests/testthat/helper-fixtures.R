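# Shared small fixtures built in code.

# Short default-geometry protocol: 3 full 56-frame cycles at 30 fps.
short_protocol <- function(frames = 168) {
  stimulus_protocol(frames_per_recording = frames)
}

# A trace with fully controlled angles and marker frames (single epoch).
manual_trace <- function(angles, black, fps = 30) {
  tail_trace(angles = angles, fps = fps, black_frames = black)
}

# A trace of `n_cycles` equal cycles of `fpc` frames: zero baseline plus
# per-cycle single-frame spikes of the requested heights (one spike per
# cycle, placed mid-cycle, isolated so the rolling median is unaffected).
spike_trace <- function(spikes, fpc = 40, fps = 10) {
  n <- length(spikes) * fpc
  ang <- numeric(n)
  for (i in seq_along(spikes)) {
    ang[(i - 1) * fpc + fpc %/% 2] <- spikes[i]
  }
  tail_trace(ang, fps = fps, black_frames = seq(0, n - 1, by = fpc))
}
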