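# Shared fixtures: light bench configurations so the suite stays fast.
# Audio-rate floors are dictated by the harmonic content (rate > 2 * K * f0).

test_cfg <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, audio_rate = 6300, n_harmonics = 20,
                   f0_true = 60, image_size = c(320, 260),
                   flow_steps = seq(0.6, 3.0, length.out = 5),
                   step_duration = 2)
  args <- utils::modifyList(defaults, list(...))
  do.call(bench_config, args)
}

# imaging fixture at the bench's true calibration but a cropped sensor
imaging_cfg <- function(seed = 1L, ...) {
  test_cfg(seed = seed, image_size = c(360, 300), px_per_cm = 123,
           video_rate = 1473, ...)
}
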