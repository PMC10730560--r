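# Reduction chain: plateau detection, per-step averaging, f0/SPL/HNR
# estimators and glottal resistance, validated against generator truth.

test_that("plateau detection recovers the stepped protocol", {
  cfg <- test_cfg(seed = 2)
  gp <- gen_flow_pressure(cfg)
  w <- segment_steps(gp$time, gp$flow_Ls, min_duration = 1.75)
  expect_equal(nrow(w), 5)
  for (s in seq_len(5)) {
    overlap <- min(w$t_end[s], gp$truth$t_end[s]) -
      max(w$t_start[s], gp$truth$t_start[s])
    expect_gt(overlap / cfg$step_duration, 0.9)
  }
  # windows are disjoint and ordered
  expect_true(all(diff(as.vector(rbind(w$i_start, w$i_end))) > 0))
})

test_that("constant flow gives one window, a ramp gives none", {
  tt <- seq(0, 5, by = 0.01)
  w <- segment_steps(tt, rep(2, length(tt)), min_duration = 3.5)
  expect_equal(nrow(w), 1)
  expect_lt(w$t_start, 0.2)
  expect_gt(w$t_end, 4.8)
  expect_warning(
    w0 <- segment_steps(tt, seq(0.3, 3.5, length.out = length(tt)),
                        min_duration = 3.5, tol = 0.01),
    "no quasi-steady window")
  expect_equal(nrow(w0), 0)
})

test_that("step averaging reproduces the generator law and cycle minima", {
  cfg <- test_cfg(flow_steps = 1, true_Rd = 530, true_P0 = 800,
                  noise_sd_pressure = 0, noise_sd_flow = 0, ripple_frac = 0)
  gp <- gen_flow_pressure(cfg)
  w <- segment_steps(gp$time, gp$flow_Ls, min_duration = 1.75)
  a <- average_step(w[1, ], gp$time, gp$flow_Ls, gp$pressure_Pa, f0 = 60)
  expect_equal(a$ps_mean, 1330, tolerance = 1e-9)
  expect_equal(a$phi_mean, 1, tolerance = 1e-12)

  # a 100 Pa ripple about 1330 Pa pulls the cycle minima to ~1230 Pa
  cfgr <- test_cfg(flow_steps = 1, noise_sd_pressure = 0, noise_sd_flow = 0,
                   ripple_frac = 100 / 1330)
  gpr <- gen_flow_pressure(cfgr)
  wr <- segment_steps(gpr$time, gpr$flow_Ls, min_duration = 1.75)
  ar <- average_step(wr[1, ], gpr$time, gpr$flow_Ls, gpr$pressure_Pa,
                     f0 = 60)
  expect_equal(ar$ps_min_cycle, 1230, tolerance = 5)

  expect_error(average_step(list(i_start = 10, i_end = 5), gp$time,
                            gp$flow_Ls, gp$pressure_Pa), "empty")
  # fewer than 3 cycles: minima undefined
  short <- list(i_start = 1, i_end = round(2 * cfg$audio_rate / 60))
  expect_true(is.na(average_step(short, gp$time, gp$flow_Ls,
                                 gp$pressure_Pa, f0 = 60)$ps_min_cycle))
})

test_that("YIN recovers pure and noisy fundamentals and rejects noise", {
  t <- seq(0, 1, by = 1 / 8000)
  expect_equal(estimate_f0(sin(2 * pi * 60 * t), 8000), 60, tolerance = 0.1)
  set.seed(9)
  v <- synth_voice(57, 2, 22050, hnr_db = 20)
  expect_equal(estimate_f0(v$wave, 22050), 57, tolerance = 0.5)
  expect_true(is.na(estimate_f0(rnorm(22050), 22050)))
  # gain invariance of the normalized difference
  expect_equal(estimate_f0(v$wave * 1e4, 22050),
               estimate_f0(v$wave, 22050), tolerance = 1e-9)
  expect_error(estimate_f0(v$wave, 700), "rate")
})

test_that("SPL is the calibrated RMS level re 20 uPa", {
  t <- seq(0, 1, by = 1 / 8000)
  s <- sqrt(2) * sin(2 * pi * 100 * t) # RMS 1 Pa
  expect_equal(compute_spl(s), 93.98, tolerance = 0.01)
  expect_equal(compute_spl(2 * s) - compute_spl(s), 6.02, tolerance = 0.01)
  expect_equal(compute_spl(rep(c(2e-5, -2e-5), 100)), 0, tolerance = 1e-9)
  expect_warning(expect_true(is.na(compute_spl(rep(0, 10)))), "silent")
})

test_that("HNR estimators recover known mixtures within 1 dB", {
  set.seed(12)
  for (h in c(5, 15, 30)) {
    v <- synth_voice(60, 2, 22050, hnr_db = h)
    expect_equal(compute_hnr(v$wave, 22050, 60), h, tolerance = 1)
    expect_equal(compute_hnr(v$wave, 22050, 60, method = "acf"), h,
                 tolerance = 1)
  }
  # noise-free limit: comb reports the cap, acf saturates high
  vp <- synth_voice(60, 1, 22050, hnr_db = Inf)
  expect_equal(compute_hnr(vp$wave, 22050, 60), 60)
  expect_gt(compute_hnr(vp$wave, 22050, 60, method = "acf"), 40)
  # equal harmonic and noise power: about 0 dB
  v0 <- synth_voice(60, 2, 22050, hnr_db = 0)
  expect_equal(compute_hnr(v0$wave, 22050, 60, method = "acf"), 0,
               tolerance = 1)
  expect_error(compute_hnr(v0$wave, 22050, NA), "f0")
})

test_that("glottal resistance is pressure over flow", {
  expect_equal(glottal_resistance(1000, 2), 500)
  expect_equal(glottal_resistance(0, 1.5), 0)
  expect_error(glottal_resistance(100, 0), "positive")
  # generating law: Rg(phi) = P0/phi + Rd, decreasing in phi when P0 > 0
  phi <- seq(0.4, 3.4, length.out = 10)
  rg <- glottal_resistance(530 * phi + 800, phi)
  expect_equal(rg, 800 / phi + 530, tolerance = 1e-12)
  expect_true(all(diff(rg) < 0))
})

test_that("full reduction matches generator truth on a clean round", {
  cfg <- test_cfg(seed = 5, noise_sd_pressure = 0, noise_sd_flow = 0,
                  audio_rate = 22050, flow_steps = c(0.8, 1.6, 2.4))
  gp <- gen_flow_pressure(cfg)
  set.seed(cfg$seed + 1L)
  audio <- unlist(lapply(seq_len(3), function(i)
    synth_voice(cfg$f0_true, cfg$step_duration, cfg$audio_rate,
                spl_db = cfg$spl_true, hnr_db = cfg$hnr_true,
                n_harmonics = cfg$n_harmonics)$wave))
  steps <- reduce_round(gp$time, gp$flow_Ls, gp$pressure_Pa, audio,
                        cfg$audio_rate, min_duration = 1.75)
  expect_equal(nrow(steps), 3)
  expect_equal(steps$phi_Ls, gp$truth$phi_Ls, tolerance = 1e-9)
  expect_equal(steps$f0_Hz, rep(60, 3), tolerance = 0.5)
  expect_equal(steps$spl_dB, rep(70, 3), tolerance = 0.1)
  expect_equal(steps$hnr_dB, rep(20, 3), tolerance = 1)
  expect_equal(steps$rg_PasL, steps$ps_Pa / steps$phi_Ls, tolerance = 1e-6)
  expect_true(all(diff(steps$rg_PasL) < 0))
})
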