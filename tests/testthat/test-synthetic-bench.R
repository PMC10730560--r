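# Generators: every synthetic input must carry its own ground truth and
# reproduce it exactly in the noiseless limit.

test_that("stepped flow/pressure protocol follows its linear law", {
  cfg <- test_cfg(flow_steps = 1, noise_sd_pressure = 0, noise_sd_flow = 0,
                  ripple_frac = 0, true_Rd = 530, true_P0 = 800)
  gp <- gen_flow_pressure(cfg)
  expect_equal(mean(gp$pressure_Pa), 1330, tolerance = 1e-12)
  expect_equal(unique(gp$flow_Ls), 1)

  cfg2 <- test_cfg(flow_steps = 2, true_Rd = 185, true_P0 = 0,
                   noise_sd_pressure = 0, noise_sd_flow = 0, ripple_frac = 0)
  expect_equal(mean(gen_flow_pressure(cfg2)$pressure_Pa), 370,
               tolerance = 1e-12)
})

test_that("default protocol spans 10 plateaus of 4 s from 0.3 to 3.5 L/s", {
  cfg <- bench_config(audio_rate = 4410, n_harmonics = 20)
  gp <- gen_flow_pressure(cfg)
  expect_equal(nrow(gp$truth), 10)
  expect_equal(range(gp$truth$phi_Ls), c(0.3, 3.5))
  expect_equal(max(gp$time) + 1 / cfg$audio_rate, 40, tolerance = 1e-9)
  # plateau means obey the law even with the ripple on
  cfg0 <- bench_config(audio_rate = 4410, noise_sd_pressure = 0,
                       noise_sd_flow = 0)
  gp0 <- gen_flow_pressure(cfg0)
  for (s in c(1, 5, 10)) {
    i <- gp0$time >= gp0$truth$t_start[s] & gp0$time < gp0$truth$t_end[s]
    expect_equal(mean(gp0$pressure_Pa[i]), gp0$truth$ps_mean_Pa[s],
                 tolerance = 1e-6)
  }
})

test_that("empty protocol and bad configs are rejected", {
  expect_error(bench_config(flow_steps = c(1, 0.5)), "increasing")
  expect_error(bench_config(oq_true = 0), "oq_true")
  expect_error(bench_config(audio_rate = 1000), "harmonic")
  cfg <- test_cfg()
  cfg$flow_steps <- numeric(0)
  expect_error(gen_flow_pressure(cfg), "no protocol")
})

test_that("synthesized audio hits its SPL and HNR targets by construction", {
  set.seed(1)
  v <- synth_voice(60, 1, rate = 6300, spl_db = 94, hnr_db = Inf)
  # closed form: RMS = 20 uPa * 10^(94/20) = 1.0023 Pa
  expect_equal(sqrt(mean(v$wave^2)), 1.0023, tolerance = 1e-4)
  expect_equal(v$spl_db, 94, tolerance = 1e-10)

  v0 <- synth_voice(60, 1, rate = 6300, spl_db = 70, hnr_db = 0)
  expect_equal(mean(v0$harmonic^2), mean(v0$noise^2), tolerance = 1e-10)
  expect_equal(v0$hnr_db, 0, tolerance = 1e-10)

  for (h in c(5, 20, 40)) {
    v <- synth_voice(60, 1, rate = 6300, spl_db = 70, hnr_db = h)
    expect_equal(v$hnr_db, h, tolerance = 0.5)
    expect_equal(v$spl_db, 70, tolerance = 0.1)
  }
  expect_warning(synth_voice(60, 0.5, rate = 6300, hnr_db = 65),
                 "noise floor")
})

test_that("generated pulse train is recovered by the YIN estimator", {
  cfg <- test_cfg(seed = 4, f0_true = 57, audio_rate = 22050, hnr_true = 20,
                  spl_true = 70)
  v <- gen_audio(cfg, duration = 2)
  expect_equal(estimate_f0(v$wave, cfg$audio_rate), 57, tolerance = 0.5)
})

test_that("rendered aperture area matches its analytic ground truth", {
  cfg <- imaging_cfg()
  # 10 mm^2 at 123 px/cm is 10 / (10/123)^2 = 1513 px
  st <- gen_frames(cfg, 10, n_frames = 3, noise_sd = 0,
                   t0 = 0.3 * cfg$oq_true / cfg$f0_true)
  j <- which.max(st$area_mm2)
  expect_gt(st$area_mm2[j], 5)
  apx <- dark_area_px(st$frames[[j]])
  expect_equal(apx, st$area_mm2[j] / (10 / 123)^2, tolerance = 0.02)

  # sub-pixel and binary pixel counts agree with truth across the bench span
  for (ag in c(5, 230)) {
    stk <- gen_frames(cfg, ag, n_frames = 2, noise_sd = 0,
                      t0 = 0.5 * cfg$oq_true / cfg$f0_true)
    jj <- which.max(stk$area_mm2)
    expect_equal(dark_area_px(stk$frames[[jj]]) * (10 / 123)^2,
                 stk$area_mm2[jj], tolerance = 0.02)
  }
  st30 <- gen_frames(cfg, 30, n_frames = 2, noise_sd = 0,
                     t0 = 0.5 * cfg$oq_true / cfg$f0_true)
  j30 <- which.max(st30$area_mm2)
  expect_equal(dark_area_px(st30$frames[[j30]], weighted = FALSE) *
                 (10 / 123)^2,
               st30$area_mm2[j30], tolerance = 0.02)
})

test_that("area waveform respects open quotient and period", {
  cfg <- imaging_cfg(oq_true = 0.6, f0_true = 60)
  st <- gen_frames(cfg, 50, n_frames = 123) # ~5 cycles at 1473 fps
  closed <- mean(st$area_mm2 == 0)
  expect_equal(closed, 1 - cfg$oq_true, tolerance = 0.05)
  # period of the ground-truth series: peak spacing = video_rate / f0
  pk <- pracma::findpeaks(st$area_mm2, minpeakheight = 25)
  expect_equal(mean(diff(pk[, 2])), 1473 / 60, tolerance = 0.5)
  # all-closed stack is valid
  st0 <- gen_frames(cfg, 0, n_frames = 3)
  expect_true(all(st0$area_mm2 == 0))
})

test_that("cyclic tensile records evaluate their constitutive law", {
  lin <- gen_tensile("linear", c(E = 0.02), n_cycles = 4, eps_max = 0.7)
  expect_equal(vapply(lin$cycles, function(cy) cy$peak_strain, numeric(1)),
               c(0.175, 0.35, 0.525, 0.7))
  i05 <- which.min(abs(lin$strain[seq_len(300)] - 0.5))
  expect_equal(lin$stress[i05], 0.02 * lin$strain[i05], tolerance = 1e-12)
  expect_equal(max(lin$stress), 0.02 * 0.7, tolerance = 1e-9)

  ex <- gen_tensile("exponential", c(a = 0.01, b = 2))
  i03 <- which.min(abs(ex$strain - 0.3))
  expect_equal(ex$stress[i03], 0.01 * (exp(2 * ex$strain[i03]) - 1),
               tolerance = 1e-12)
  expect_equal(0.01 * (exp(2 * 0.3) - 1), 0.00822, tolerance = 1e-3)

  expect_error(gen_tensile("plastic", c(E = 1)), "arg")
})

test_that("seeded generation is bit-reproducible", {
  cfg <- test_cfg(seed = 11)
  a <- gen_flow_pressure(cfg); b <- gen_flow_pressure(cfg)
  expect_identical(a, b)
  va <- gen_audio(cfg, 0.5); vb <- gen_audio(cfg, 0.5)
  expect_identical(va$wave, vb$wave)
  fa <- gen_frames(cfg, 20, n_frames = 2)
  fb <- gen_frames(cfg, 20, n_frames = 2)
  expect_identical(fa$frames, fb$frames)
})
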