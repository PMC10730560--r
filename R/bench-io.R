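# On-disk round trip of synthetic bench data in the formats a real bench
# produces: WAV audio, CSV signal tables, PNG frame sequences, a YAML config
# mirror and a JSON ground-truth sidecar.

#' Write a full synthetic bench dataset to disk
#'
#' Produces `signals.csv` (`time_s,flow_Ls,pressure_Pa`), `audio.wav`
#' (float32, calibrated Pa), a `frames/` PNG sequence
#' (`frame_000001.png`, ...), `config.yaml` mirroring the [bench_config()],
#' and `ground_truth.json` with the generator truth.
#'
#' @param cfg a [bench_config()].
#' @param dir output directory (created).
#' @param n_frames frames to render (at the peak-flow step's
#'   Bernoulli-consistent area), 0 to skip rendering.
#' @param params a [bernoulli_params()] used for the rendered-area target.
#' @param frame_format `"png"` (one file per frame) or `"tiff"` (one
#'   multi-page `frames.tiff`).
#' @return `dir`, invisibly.
#' @export
write_bench_data <- function(cfg, dir, n_frames = 25,
                             params = bernoulli_params(),
                             frame_format = c("png", "tiff")) {
  frame_format <- match.arg(frame_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- gen_flow_pressure(cfg)
  utils::write.csv(data.frame(time_s = sig$time, flow_Ls = sig$flow_Ls,
                              pressure_Pa = sig$pressure_Pa),
                   file.path(dir, "signals.csv"), row.names = FALSE)
  au <- gen_audio(cfg)
  write_wav(au$wave, file.path(dir, "audio.wav"), cfg$audio_rate)
  truth <- list(steps = sig$truth, f0_Hz = cfg$f0_true,
                spl_dB = au$spl_db, hnr_dB = au$hnr_db)
  if (n_frames > 0) {
    top <- nrow(sig$truth)
    ag <- predict_area(sig$truth$ps_min_Pa[top], sig$truth$phi_Ls[top],
                       params)
    st <- gen_frames(cfg, ag, n_frames = n_frames)
    if (frame_format == "png") {
      fdir <- file.path(dir, "frames")
      dir.create(fdir, showWarnings = FALSE)
      for (j in seq_along(st$frames))
        png::writePNG(st$frames[[j]],
                      file.path(fdir, sprintf("frame_%06d.png", j)))
    } else {
      tiff::writeTIFF(st$frames, file.path(dir, "frames.tiff"),
                      bits.per.sample = 16L)
    }
    truth$area_mm2 <- st$area_mm2
    truth$ag_max_mm2 <- st$ag_max_mm2
  }
  yaml::write_yaml(cfg[setdiff(names(cfg), "spl_law")],
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a bench signal table
#'
#' @param path a `signals.csv` with header `time_s,flow_Ls,pressure_Pa`.
#' @return data.frame with those columns.
#' @export
read_signals <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "flow_Ls", "pressure_Pa")
  if (!all(need %in% names(d)))
    stop("signals file must have columns ", paste(need, collapse = ","))
  d[need]
}

#' Read an image stack (PNG sequence or multi-page TIFF)
#'
#' @param path directory of `frame_*.png` grayscale images, or a `.tif(f)`
#'   file.
#' @return list of matrices, frame-index order.
#' @export
read_frame_stack <- function(path) {
  if (grepl("\\.tiff?$", path)) {
    frames <- tiff::readTIFF(path, all = TRUE)
    return(lapply(frames, function(img) {
      if (length(dim(img)) == 3) img[, , 1] else img
    }))
  }
  files <- sort(list.files(path, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame_*.png files in ", path)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}
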