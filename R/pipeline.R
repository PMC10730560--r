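# End-to-end synthetic study: generation -> reduction -> imaging -> fits ->
# Bernoulli comparison, with per-stage error containment and a reproducible
# on-disk report.

#' Compare measured maximal glottal areas with Bernoulli predictions
#'
#' For each step, predicts the glottal area from the per-cycle minimum
#' subglottal pressure and the mean airflow via [predict_area()] (the
#' maximal area over a cycle co-occurs with the pressure minimum), and
#' reports the measured/predicted ratio.
#'
#' @param steps data.frame with `phi_Ls`, `ps_min_Pa` and `ag_max_mm2`.
#' @param params a [bernoulli_params()].
#' @return data.frame with `phi_Ls`, `ps_min_Pa`, `ag_max_mm2`,
#'   `ag_pred_mm2` and `ratio` (measured / predicted; 0 is reported, with a
#'   message, for steps whose measured area is zero). Steps without
#'   `ps_min_Pa` are skipped with a message.
#' @export
compare_model <- function(steps, params = bernoulli_params()) {
  keep <- is.finite(steps$ps_min_Pa) & is.finite(steps$phi_Ls)
  if (any(!keep))
    message(sum(!keep), " step(s) without cycle-minimum pressure skipped")
  s <- steps[keep, , drop = FALSE]
  pred <- predict_area(pmax(0, s$ps_min_Pa), s$phi_Ls, params)
  ratio <- s$ag_max_mm2 / pred
  if (any(is.finite(ratio) & ratio == 0))
    message("step(s) with zero measured area flagged (ratio 0)")
  data.frame(phi_Ls = s$phi_Ls, ps_min_Pa = s$ps_min_Pa,
             ag_max_mm2 = s$ag_max_mm2, ag_pred_mm2 = pred, ratio = ratio)
}

#' Run the full synthetic bench study
#'
#' Generates a complete synthetic round (flow/pressure protocol, audio,
#' image stacks), reduces it to per-step descriptors, fits the
#' phenomenological models, compares measured maximal areas with the
#' Bernoulli model, and writes all tables (CSV with units in the headers),
#' a kymogram, an iso-resistance abacus and a JSON run log under `out_dir`.
#' Identical seeds give identical outputs.
#'
#' Image stacks are rendered Bernoulli-consistently by default: the target
#' peak area of each filmed step is `predict_area(Ps_min, phi)` scaled by
#' `area_scale`, so `area_scale = 1` makes the measured/predicted ratio of
#' the comparison table close to 1, and larger values emulate a bench whose
#' folds open wider than the quasi-steady model predicts.
#'
#' @param cfg a [bench_config()].
#' @param params a [bernoulli_params()].
#' @param out_dir report directory (created if needed).
#' @param area_scale multiplier between rendered and Bernoulli-consistent
#'   peak areas.
#' @param n_video_steps number of steps for which image stacks are rendered
#'   (the slowest stage; counted from the top of the flow ramp).
#' @param video_frames frames per rendered stack (bench: 100).
#' @param hnr_method HNR estimator, see [compute_hnr()].
#' @param write_wav_file write the audio as a float32 WAV (set `FALSE` to
#'   keep quick runs light).
#' @return invisibly, a list with `steps`, `fits`, `comparison`, `abacus`,
#'   `stage_status` and `out_dir`.
#' @export
run_synthetic_study <- function(cfg = bench_config(),
                                params = bernoulli_params(),
                                out_dir = tempfile("phonobench_run_"),
                                area_scale = 1, n_video_steps = 2,
                                video_frames = 60, hnr_method = "comb",
                                write_wav_file = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  run <- function(name, expr) {
    tryCatch({ v <- force(expr); status[[name]] <<- "ok"; v },
             error = function(e) {
               status[[name]] <<- paste("failed:", conditionMessage(e))
               NULL
             })
  }

  sim <- run("simulate", {
    sig <- gen_flow_pressure(cfg)
    spl_steps <- if (!is.null(cfg$spl_law))
      cfg$spl_law[1] * log10(cfg$flow_steps) + cfg$spl_law[2]
    else rep(cfg$spl_true, length(cfg$flow_steps))
    set.seed(cfg$seed + 1L)
    audio <- unlist(lapply(spl_steps, function(spl)
      synth_voice(cfg$f0_true, cfg$step_duration, cfg$audio_rate,
                  spl_db = spl, hnr_db = cfg$hnr_true,
                  n_harmonics = cfg$n_harmonics)$wave))
    utils::write.csv(data.frame(time_s = sig$time, flow_Ls = sig$flow_Ls,
                                pressure_Pa = sig$pressure_Pa)[
      seq(1, length(sig$time), by = max(1, length(sig$time) %/% 20000)), ],
      file.path(out_dir, "signals_decimated.csv"), row.names = FALSE)
    if (write_wav_file)
      write_wav(audio, file.path(out_dir, "audio.wav"), cfg$audio_rate)
    list(sig = sig, audio = audio, spl_steps = spl_steps)
  })

  steps <- run("reduce", {
    stopifnot(!is.null(sim))
    reduce_round(sim$sig$time, sim$sig$flow_Ls, sim$sig$pressure_Pa,
                 sim$audio, cfg$audio_rate, hnr_method = hnr_method,
                 min_duration = 0.875 * cfg$step_duration)
  })

  steps <- run("imaging", {
    stopifnot(!is.null(steps), nrow(steps) >= 1)
    filmed <- tail(order(steps$phi_Ls), n_video_steps)
    for (s in filmed) {
      ag_target <- area_scale *
        predict_area(max(0, steps$ps_min_Pa[s]), steps$phi_Ls[s], params)
      stack <- gen_frames(cfg, ag_target, n_frames = video_frames)
      ser <- area_series(stack)
      steps$ag_max_mm2[s] <- ag_max_per_cycle(ser, steps$f0_Hz[s],
                                              cfg$video_rate)
      if (s == filmed[length(filmed)]) {
        mid <- cfg$image_size[1] / 2
        ky <- build_kymogram(stack, c(mid, 1), c(mid, cfg$image_size[2]))
        utils::write.csv(ky$intensity,
                         file.path(out_dir, "kymogram_intensity.csv"),
                         row.names = FALSE)
        png::writePNG(t(ky$intensity), file.path(out_dir, "kymogram.png"))
        utils::write.csv(data.frame(frame = seq_along(ser$area_mm2),
                                    t_s = ser$frame_times,
                                    area_px = ser$area_px,
                                    area_mm2 = ser$area_mm2),
                         file.path(out_dir, "area_series.csv"),
                         row.names = FALSE)
      }
      rm(stack); gc(verbose = FALSE)
    }
    steps
  })

  fits <- run("fits", {
    stopifnot(!is.null(steps))
    fl <- list(fit_pressure_flow(steps), fit_resistance(steps),
               fit_spl_log(steps, "flow"), fit_spl_log(steps, "pressure"))
    tab <- do.call(rbind, lapply(fl, function(f)
      data.frame(model = f$model,
                 coef = names(f$coefficients),
                 estimate = unname(f$coefficients),
                 se = unname(f$standard_errors),
                 residual_sd = f$residual_sd, n = f$n_points)))
    utils::write.csv(tab, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    fl
  })

  comparison <- run("compare", {
    stopifnot(!is.null(steps))
    cmp <- compare_model(steps[is.finite(steps$ag_max_mm2), , drop = FALSE],
                         params)
    utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    cmp
  })

  ab <- run("abacus", {
    ab <- abacus(c(50, 200, 1000, 5000, 20000, 40000),
                 seq(0.2, 3.6, by = 0.2), params)
    utils::write.csv(ab, file.path(out_dir, "abacus.csv"),
                     row.names = FALSE)
    ab
  })

  if (!is.null(steps))
    utils::write.csv(steps, file.path(out_dir, "steps.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config = cfg[setdiff(names(cfg), "flow_steps")],
         flow_steps_Ls = cfg$flow_steps,
         area_scale = area_scale,
         stage_status = status),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(steps = steps, fits = fits, comparison = comparison,
                 abacus = ab, stage_status = status, out_dir = out_dir))
}
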