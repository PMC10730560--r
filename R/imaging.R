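# Glottal-area extraction from high-speed image stacks: threshold-based
# region growing (8-connectivity, seeded in the dark glottal aperture),
# per-frame areas with pixel calibration, per-cycle maxima.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass over diagonal adjacencies.
label8 <- function(bw) {
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonal
  c1 <- lab[-nr, -1]; d <- lab[-1, -nc]  # down-left diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  map <- vapply(seq_len(nlab), find, integer(1))
  map <- match(map, sort(unique(map)))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Segment the glottis in one frame by threshold-based region growing
#'
#' Returns the 8-connected region of pixels with intensity at or below
#' `threshold` that contains the seed. The glottal aperture is the dark
#' region of a backlit frame; a frame whose seed pixel is brighter than the
#' threshold (closed glottis) yields an empty mask.
#'
#' @param frame grayscale matrix in \[0, 1\].
#' @param seed `c(row, col)` inside the aperture, or `NULL` to auto-seed at
#'   the darkest pixel.
#' @param threshold intensity threshold; `NULL` uses Otsu's method on the
#'   frame histogram.
#' @return logical matrix of the same size (the mask).
#' @export
segment_glottis <- function(frame, seed = NULL, threshold = NULL) {
  stopifnot(is.matrix(frame))
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
  if (is.null(seed)) {
    k <- which.min(frame)
    seed <- c((k - 1) %% nrow(frame) + 1, (k - 1) %/% nrow(frame) + 1)
  }
  stopifnot(length(seed) == 2, seed[1] >= 1, seed[1] <= nrow(frame),
            seed[2] >= 1, seed[2] <= ncol(frame))
  if (frame[seed[1], seed[2]] > threshold)
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  lab <- label8(frame <= threshold)
  lab == lab[seed[1], seed[2]]
}

#' Time-resolved glottal area of an image stack
#'
#' Segments every frame with a stack-constant threshold and converts pixel
#' areas to mm^2 with the `(10 / px_per_cm)^2` calibration. With
#' `subpixel = TRUE` (default) the area of each mask is refined by summing
#' the darkness fraction of the mask and its one-pixel boundary ring, which
#' recovers the sub-pixel aperture area encoded in anti-aliased or defocused
#' edge pixels; `FALSE` counts mask pixels.
#'
#' @param stack list of grayscale matrices, or the list returned by
#'   [gen_frames()].
#' @param px_per_cm calibration, px/cm (> 0).
#' @param video_rate frame rate, frames/s (for the time base; ignored if the
#'   stack carries `frame_times`).
#' @param threshold stack-wide intensity threshold; `NULL` applies Otsu to a
#'   pooled pixel sample. If the pooled intensity range is below
#'   `min_contrast` the stack is treated as fully closed (all areas zero).
#' @param seed fixed `c(row, col)` seed, or `NULL` to auto-seed each frame
#'   at its darkest pixel.
#' @param overrides optional manual-correction hook: a named list mapping
#'   frame index (as character) to a replacement logical mask, standing in
#'   for the manual retouching of automatic segmentations.
#' @param subpixel logical, see above.
#' @param min_contrast minimum pooled intensity range for segmentation.
#' @return object of class `glottal_area_series`: list with `frame_times`
#'   (s), `area_px`, `area_mm2`, `px_per_cm`, `threshold`.
#' @export
area_series <- function(stack, px_per_cm = 123, video_rate = 1473,
                        threshold = NULL, seed = NULL, overrides = NULL,
                        subpixel = TRUE, min_contrast = 0.2) {
  if (is.list(stack) && !is.null(stack$frames)) {
    frame_times <- stack$frame_times
    px_per_cm <- stack$px_per_cm
    frames <- stack$frames
  } else {
    frames <- stack
    frame_times <- (seq_along(frames) - 1) / video_rate
  }
  if (px_per_cm <= 0) stop("calibration px_per_cm must be positive")
  n <- length(frames)
  pooled <- unlist(lapply(frames, function(f)
    f[seq(1, length(f), length.out = min(length(f), 4096))]))
  if (is.null(threshold)) {
    if (diff(range(pooled)) < min_contrast) {
      threshold <- -Inf # no dark phase anywhere: closed stack
    } else {
      threshold <- EBImage::otsu(EBImage::Image(matrix(pooled)),
                                 range = c(0, 1))
    }
  }
  area_px <- numeric(n)
  for (j in seq_len(n)) {
    ov <- overrides[[as.character(j)]]
    mask <- if (!is.null(ov)) ov
            else if (is.infinite(threshold) && threshold < 0)
              matrix(FALSE, nrow(frames[[j]]), ncol(frames[[j]]))
            else segment_glottis(frames[[j]], seed = seed,
                                 threshold = threshold)
    if (!any(mask)) { area_px[j] <- 0; next }
    if (subpixel) {
      # gray-level reference estimated per frame: aperture level from the
      # eroded mask interior (immune to edge pixels and noise tails),
      # background level from a ring of folds just outside the mask
      grown <- EBImage::dilate(mask * 1, EBImage::makeBrush(3, "box")) > 0
      interior <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "box")) > 0
      dark_ref <- if (any(interior)) median(frames[[j]][interior])
                  else as.numeric(quantile(frames[[j]][mask], 0.1))
      outer_ring <- (EBImage::dilate(mask * 1,
                                     EBImage::makeBrush(7, "box")) > 0) &
        !grown
      bright_ref <- if (any(outer_ring)) median(frames[[j]][outer_ring])
                    else as.numeric(quantile(pooled, 0.75))
      f <- (bright_ref - frames[[j]][grown]) /
        max(bright_ref - dark_ref, 1e-6)
      area_px[j] <- sum(pmin(1, pmax(0, f)))
    } else {
      area_px[j] <- sum(mask)
    }
  }
  mm2_per_px <- (10 / px_per_cm)^2
  structure(list(frame_times = frame_times, area_px = area_px,
                 area_mm2 = area_px * mm2_per_px, px_per_cm = px_per_cm,
                 threshold = threshold),
            class = "glottal_area_series")
}

#' Maximum glottal area per cycle, averaged over a quasi-steady step
#'
#' Locates per-cycle peaks of the area series (minimum peak separation
#' `0.8 * video_rate / f0` frames), refines each peak by parabolic
#' interpolation of the three samples around it (the true maximum usually
#' falls between frames), and returns the mean of the cycle peaks. A series
#' without internal peaks (constant or monotone) returns its maximum; an
#' all-closed series returns 0.
#'
#' @param series a `glottal_area_series` (or numeric vector of mm^2 areas).
#' @param f0 oscillation fundamental, Hz.
#' @param video_rate frame rate, frames/s.
#' @return mean per-cycle maximum area, mm^2; `NA` if fewer frames than one
#'   cycle.
#' @export
ag_max_per_cycle <- function(series, f0, video_rate = 1473) {
  a <- if (inherits(series, "glottal_area_series")) series$area_mm2
       else as.numeric(series)
  stopifnot(!is.na(f0), f0 > 0)
  per <- video_rate / f0
  if (length(a) < per) return(NA_real_)
  if (all(a == 0)) return(0)
  if (diff(range(a)) == 0) return(a[1])
  pk <- pracma::findpeaks(a, minpeakdistance = max(1, floor(0.8 * per)),
                          minpeakheight = max(a) * 0.5)
  if (is.null(pk)) return(max(a))
  peaks <- vapply(pk[, 2], function(i) {
    if (i > 1 && i < length(a)) {
      y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) y2 - (y1 - y3)^2 / (8 * denom) else y2
    } else a[i]
  }, numeric(1))
  mean(peaks)
}

#' Anterior-posterior pre-strain from commissure distances
#'
#' Natural (logarithmic) strain `log(l / l0)` of the fold along its
#' anterior-posterior axis, measured between the glottal commissures on a
#' reference image.
#'
#' @param length_now current commissure distance (any unit).
#' @param length_rest rest distance (same unit; the replicas' glottis is
#'   20 mm long at rest).
#' @return dimensionless pre-strain (vectorized). Additive under
#'   composition of stretches.
#' @export
#' @examples
#' measure_prestrain(25.42, 20) # 0.240
measure_prestrain <- function(length_now, length_rest) {
  if (any(length_now <= 0) || any(length_rest <= 0))
    stop("lengths must be positive")
  log(length_now / length_rest)
}
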