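# Glottal imaging: region growing, calibrated areas, per-cycle maxima,
# kymograms and pre-strain.

test_that("region growing segments the rendered aperture", {
  cfg <- imaging_cfg()
  st <- gen_frames(cfg, 10, n_frames = 3, noise_sd = 0,
                   t0 = 0.4 * cfg$oq_true / cfg$f0_true)
  j <- which.max(st$area_mm2)
  mask <- segment_glottis(st$frames[[j]])
  truth_px <- st$area_mm2[j] / (10 / 123)^2
  expect_equal(sum(mask), truth_px, tolerance = 0.02)
  # all-bright frame: empty mask
  expect_false(any(segment_glottis(matrix(0.9, 50, 50), seed = c(25, 25),
                                   threshold = 0.5)))
})

test_that("region growing keeps only the seeded 8-connected component", {
  f <- matrix(1, 30, 30)
  f[5:10, 5:10] <- 0.05       # blob A
  f[11, 11] <- 0.05           # diagonal neighbour of A (8- but not 4-conn)
  f[20:25, 20:25] <- 0.05     # blob B, disconnected
  m <- segment_glottis(f, seed = c(7, 7), threshold = 0.5)
  expect_true(m[11, 11])      # diagonal pixel joins the seeded component
  expect_false(any(m[20:25, 20:25]))
  expect_equal(sum(m), 37)
  m2 <- segment_glottis(f, seed = c(22, 22), threshold = 0.5)
  expect_equal(sum(m2), 36)
})

test_that("segmented area is monotone in the threshold", {
  cfg <- imaging_cfg()
  st <- gen_frames(cfg, 40, n_frames = 2, noise_sd = 0.01,
                   t0 = 0.5 * cfg$oq_true / cfg$f0_true)
  f <- st$frames[[which.max(st$area_mm2)]]
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8),
                  function(th) sum(segment_glottis(f, threshold = th)),
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("area series calibrates px to mm^2 and tracks ground truth", {
  # calibration identity: 1513 px at 123 px/cm -> 10.0 mm^2
  expect_equal(1513 * (10 / 123)^2, 10.0, tolerance = 1e-3)
  cfg <- imaging_cfg(seed = 6)
  st <- gen_frames(cfg, 60, n_frames = 50)
  ser <- area_series(st)
  expect_s3_class(ser, "glottal_area_series")
  expect_equal(ser$area_mm2, ser$area_px * (10 / 123)^2, tolerance = 1e-12)
  expect_gt(cor(ser$area_mm2, st$area_mm2), 0.99)
  expect_true(all(ser$area_mm2 >= 0))
  expect_error(area_series(st$frames, px_per_cm = 0), "calibration")
})

test_that("manual mask overrides replace automatic segmentation", {
  cfg <- imaging_cfg()
  st <- gen_frames(cfg, 30, n_frames = 3)
  manual <- matrix(FALSE, cfg$image_size[1], cfg$image_size[2])
  manual[1:10, 1:10] <- TRUE
  ser <- area_series(st, overrides = list("2" = manual), subpixel = FALSE)
  expect_equal(ser$area_px[2], 100)
})

test_that("per-cycle maxima average to the generated peak area", {
  cfg <- imaging_cfg(seed = 8)
  st <- gen_frames(cfg, 10, n_frames = 100)
  ser <- area_series(st)
  agm <- ag_max_per_cycle(ser, cfg$f0_true, cfg$video_rate)
  expect_equal(agm, 10, tolerance = 0.2)
  expect_equal(ag_max_per_cycle(rep(7.5, 60), 60, 1473), 7.5)
  expect_equal(ag_max_per_cycle(rep(0, 60), 60, 1473), 0)
  expect_true(is.na(ag_max_per_cycle(rep(1, 5), 60, 1473)))
})

test_that("kymogram equals direct line sampling and shows the cycle", {
  cfg <- imaging_cfg(seed = 9)
  st <- gen_frames(cfg, 80, n_frames = 100)
  mid <- cfg$image_size[1] / 2
  ky <- build_kymogram(st, c(mid, 1), c(mid, cfg$image_size[2]))
  expect_equal(dim(ky$intensity), c(cfg$image_size[2], 100))
  # static stack: every column identical
  stat <- list(frames = rep(st$frames[1], 5),
               frame_times = (0:4) / cfg$video_rate)
  kys <- build_kymogram(stat, c(mid, 1), c(mid, cfg$image_size[2]))
  expect_equal(kys$intensity[, 1], kys$intensity[, 5])
  # integer line positions sample the image exactly
  direct <- st$frames[[3]][mid, ]
  expect_equal(ky$intensity[, 3], unname(direct), tolerance = 1e-12)
  # periodicity at video_rate / f0 frames
  expect_equal(kymogram_period(ky), 1473 / 60, tolerance = 0.5)
  expect_error(build_kymogram(st, c(-3, 1), c(mid, 10)), "outside")
})

test_that("margin phase delay shows up as a left-right kymogram lag", {
  delay <- 0.004 # s, about 6 frames at 1473 fps
  cfg <- imaging_cfg(seed = 10, phase_delay = delay)
  st <- gen_frames(cfg, 80, n_frames = 100)
  mid <- cfg$image_size[1] / 2
  ky <- build_kymogram(st, c(mid, 1), c(mid, cfg$image_size[2]))
  ctr <- cfg$image_size[2] / 2
  dark <- ky$intensity < mean(range(ky$intensity))
  left_w <- colSums(dark[seq_len(floor(ctr)), , drop = FALSE])
  right_w <- colSums(dark[seq(ceiling(ctr) + 1, nrow(dark)), , drop = FALSE])
  cc <- stats::ccf(left_w, right_w, lag.max = 12, plot = FALSE)
  lag_frames <- cc$lag[which.max(cc$acf)]
  expect_equal(abs(lag_frames), delay * cfg$video_rate, tolerance = 1.5)
})

test_that("pre-strain is the natural log stretch ratio", {
  expect_equal(measure_prestrain(20, 20), 0)
  expect_equal(measure_prestrain(25.42, 20), 0.2398, tolerance = 1e-3)
  e12 <- measure_prestrain(22, 20); e23 <- measure_prestrain(25, 22)
  expect_equal(e12 + e23, measure_prestrain(25, 20), tolerance = 1e-12)
  expect_error(measure_prestrain(-1, 20), "positive")
  expect_error(measure_prestrain(20, 0), "positive")
})
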