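# Rendered high-speed image stacks of an oscillating glottis.
#
# The aperture is a lens (two circular arcs through the anterior and
# posterior commissures) or an ellipse, dark on bright folds, rendered with
# analytic per-pixel coverage (4x supersampled rows, exact column overlap)
# so edge pixels carry sub-pixel area information like real defocused video.

# raised-cosine glottal area pulse train; t in s, oq = open quotient
area_waveform <- function(t, f0, oq, ag_max) {
  phase <- (t * f0) %% 1
  open <- phase < oq
  a <- numeric(length(t))
  a[open] <- ag_max * 0.5 * (1 - cos(2 * pi * phase[open] / oq))
  a
}

# area of a circular segment with chord L and sagitta h (same length unit);
# uses R = (L^2/4 + h^2) / (2h) and sqrt(2Rh - h^2) = L/2
segment_area <- function(h, L) {
  ifelse(h <= 0, 0, {
    R <- (L^2 / 4 + h^2) / (2 * h)
    R^2 * acos(pmax(-1, pmin(1, 1 - h / R))) - (R - h) * L / 2
  })
}

# sagitta giving a half-aperture (one segment) of target area
solve_sagitta <- function(area, L) {
  if (area <= 0) return(0)
  uniroot(function(h) segment_area(h, L) - area,
          lower = 1e-9 * L, upper = 4 * L, tol = 1e-12)$root
}

# half-width profile along the chord (y in [0, L]) for sagitta h
lens_halfwidth <- function(y, h, L) {
  if (h <= 0) return(numeric(length(y)))
  R <- (L^2 / 4 + h^2) / (2 * h)
  w <- sqrt(pmax(0, R^2 - (y - L / 2)^2)) - (R - h)
  pmax(0, w)
}

ellipse_halfwidth <- function(y, h, L) {
  if (h <= 0) return(numeric(length(y)))
  pmax(0, h * sqrt(pmax(0, 1 - ((y - L / 2) / (L / 2))^2)))
}

#' Render a synthetic high-speed stack of an oscillating glottis
#'
#' Per-frame glottal area follows a raised-cosine pulse train at `f0_true`
#' with open quotient `oq_true` and peak `ag_max_mm2`; left and right halves
#' of the aperture can be lagged by `phase_delay` s to produce the
#' diamond-shaped aperture seen with a propagating mucosal wave. The
#' analytic per-frame area is returned alongside the frames as ground truth.
#'
#' @param cfg a [bench_config()]; uses `video_rate`, `image_size`,
#'   `px_per_cm`, `f0_true`, `oq_true`, `phase_delay`, `glottal_length_mm`.
#' @param ag_max_mm2 peak glottal area over a cycle, mm^2. `0` renders an
#'   all-closed stack.
#' @param n_frames number of frames (the bench records 100 per step).
#' @param shape aperture shape: `"lens"` (default) or `"ellipse"`.
#' @param bright,dark fold and aperture gray levels in \[0, 1\].
#' @param noise_sd pixel noise SD added to every frame.
#' @param t0 time of the first frame, s (sets the oscillation phase).
#' @return list with `frames` (list of row x col matrices in \[0, 1\]),
#'   `frame_times` (s), `area_mm2` (ground-truth per-frame area),
#'   `ag_max_mm2`, `px_per_cm`, `video_rate`.
#' @export
gen_frames <- function(cfg, ag_max_mm2, n_frames = 100,
                       shape = c("lens", "ellipse"), bright = 0.85,
                       dark = 0.10, noise_sd = 0.01, t0 = 0) {
  stopifnot(inherits(cfg, "bench_config"), ag_max_mm2 >= 0, n_frames >= 1)
  shape <- match.arg(shape)
  set.seed(cfg$seed + 2L)
  mm_per_px <- 10 / cfg$px_per_cm
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  L_mm <- cfg$glottal_length_mm
  L_px <- L_mm / mm_per_px
  if (L_px > nr - 4) stop("glottal length does not fit in the image")
  halfwidth_fun <- if (shape == "lens") lens_halfwidth else ellipse_halfwidth
  # sanity: peak half-aperture must fit laterally
  h_peak <- if (ag_max_mm2 > 0) solve_sagitta(ag_max_mm2 / 2, L_mm) else 0
  if (h_peak / mm_per_px > nc / 2 - 4)
    stop("ag_max_mm2 does not fit in the image at this calibration")

  times <- t0 + (seq_len(n_frames) - 1) / cfg$video_rate
  a_right <- area_waveform(times, cfg$f0_true, cfg$oq_true, ag_max_mm2) / 2
  a_left <- area_waveform(times - cfg$phase_delay, cfg$f0_true, cfg$oq_true,
                          ag_max_mm2) / 2
  truth <- a_right + a_left

  row0 <- (nr - L_px) / 2 # top of the glottis, px (0-based continuous)
  xc <- nc / 2
  sub <- 4 # row supersampling
  # continuous y (mm along the chord) at sub-row centers covering the glottis
  r_lo <- max(1L, floor(row0) + 1L)
  r_hi <- min(nr, ceiling(row0 + L_px))
  rows <- r_lo:r_hi
  ys_px <- rep(rows - 1, each = sub) + (seq_len(sub) - 0.5) / sub
  ys_mm <- (ys_px - row0) * mm_per_px
  inside <- ys_mm >= 0 & ys_mm <= L_mm
  cols_l <- 1L; cols_r <- nc
  col_edges <- seq(cols_l - 1L, cols_r) # pixel x spans [e, e+1)

  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    img <- matrix(bright, nr, nc)
    if (truth[j] > 0) {
      hr <- solve_sagitta(a_right[j], L_mm)
      hl <- solve_sagitta(a_left[j], L_mm)
      wr <- numeric(length(ys_mm)); wl <- numeric(length(ys_mm))
      wr[inside] <- halfwidth_fun(ys_mm[inside], hr, L_mm) / mm_per_px
      wl[inside] <- halfwidth_fun(ys_mm[inside], hl, L_mm) / mm_per_px
      xl <- xc - wl; xr <- xc + wr
      open_row <- which(xr - xl > 0)
      if (length(open_row)) {
        c_lo <- max(1L, floor(min(xl[open_row])) + 1L)
        c_hi <- min(nc, ceiling(max(xr[open_row])))
        cols <- c_lo:c_hi
        # coverage[subrow, col] = overlap of [col-1, col] with [xl, xr]
        e0 <- matrix(cols - 1, nrow = length(ys_mm), ncol = length(cols),
                     byrow = TRUE)
        cov <- pmin(e0 + 1, xr) - pmax(e0, xl)
        cov[cov < 0] <- 0
        # average the sub-rows of each pixel row
        grp <- rep(seq_along(rows), each = sub)
        cov_px <- rowsum(cov, grp) / sub
        img[rows, cols] <- img[rows, cols] - (bright - dark) * cov_px
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    img[img < 0] <- 0
    img[img > 1] <- 1
    frames[[j]] <- img
  }
  list(frames = frames, frame_times = times, area_mm2 = truth,
       ag_max_mm2 = ag_max_mm2, px_per_cm = cfg$px_per_cm,
       video_rate = cfg$video_rate)
}

#' Coverage-weighted pixel area of the dark region of a rendered frame
#'
#' Independent pixel-counting measure used to validate the renderer: sums the
#' darkness fraction `(bright - I) / (bright - dark)` over the frame, which
#' recovers the anti-aliased aperture area in px. With `weighted = FALSE` it
#' counts pixels darker than the mid-gray level instead (integer-px area).
#'
#' @param frame matrix in \[0, 1\].
#' @param bright,dark nominal fold/aperture gray levels used at rendering.
#' @param weighted logical; sub-pixel (default) or binary counting.
#' @return area in px (possibly fractional).
#' @export
dark_area_px <- function(frame, bright = 0.85, dark = 0.10, weighted = TRUE) {
  if (weighted) {
    f <- (bright - frame) / (bright - dark)
    sum(pmin(1, pmax(0, f)))
  } else {
    sum(frame < (bright + dark) / 2)
  }
}
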