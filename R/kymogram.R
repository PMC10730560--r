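# Videokymography: intensity along a fixed line across the glottis,
# stacked frame by frame.

#' Build a kymogram from an image stack
#'
#' Samples each frame by bilinear interpolation at `n_samples` points along
#' the segment from `p0` to `p1` (row, col pixel coordinates; conventionally
#' placed at mid-glottis, perpendicular to the anterior-posterior axis) and
#' stacks the samples column-wise against time.
#'
#' @param stack list of grayscale matrices, or a [gen_frames()] result.
#' @param p0,p1 line endpoints, `c(row, col)`, inside the image.
#' @param n_samples samples along the line; default one per pixel of line
#'   length.
#' @return object of class `kymogram`: list with `intensity`
#'   (n_samples x n_frames matrix), `line` (endpoints), `positions`
#'   (distance along the line, px).
#' @export
build_kymogram <- function(stack, p0, p1, n_samples = NULL) {
  frames <- if (is.list(stack) && !is.null(stack$frames)) stack$frames
            else stack
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  if (any(c(p0, p1) < 1) || p0[1] > nr || p1[1] > nr || p0[2] > nc ||
      p1[2] > nc)
    stop("kymographic line endpoints outside the image")
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(n_samples)) n_samples <- max(2L, ceiling(len) + 1L)
  s <- seq(0, 1, length.out = n_samples)
  rr <- p0[1] + s * (p1[1] - p0[1])
  cc <- p0[2] + s * (p1[2] - p0[2])
  r0 <- pmin(pmax(floor(rr), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(cc), 1L), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  intensity <- vapply(frames, function(img) {
    img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      img[cbind(r0 + 1, c0 + 1)] * fr * fc
  }, numeric(n_samples))
  structure(list(intensity = intensity, line = list(p0 = p0, p1 = p1),
                 positions = s * len),
            class = "kymogram")
}

#' Oscillation period from a kymogram
#'
#' Measures the width of the dark glottal band in every kymogram column
#' (fraction of samples below `threshold`) and estimates the dominant period
#' of that width series by autocorrelation with parabolic peak
#' interpolation, giving sub-frame resolution.
#'
#' @param kymo a `kymogram`.
#' @param threshold intensity below which a sample counts as glottal gap;
#'   `NULL` uses the mid-range of the kymogram.
#' @param min_period minimum admissible period, frames.
#' @return period in frames (`video_rate / f0`), or `NA` when no periodicity
#'   is detectable.
#' @export
kymogram_period <- function(kymo, threshold = NULL, min_period = 4) {
  stopifnot(inherits(kymo, "kymogram"))
  img <- kymo$intensity
  if (is.null(threshold)) threshold <- mean(range(img))
  width <- colSums(img < threshold)
  n <- length(width)
  w <- width - mean(width)
  if (all(w == 0)) return(NA_real_)
  r <- vapply(0:(n - 2), function(l)
    sum(w[1:(n - l)] * w[(1 + l):n]) / (n - l), numeric(1))
  r <- r / r[1]
  lo <- max(2L, as.integer(ceiling(min_period)))
  if (lo + 1 > length(r) - 1) return(NA_real_)
  # first local maximum of the autocorrelation beyond min_period
  cand <- lo:(length(r) - 2)
  locmax <- cand[r[cand + 1] > r[cand] & r[cand + 1] >= r[cand + 2]]
  if (length(locmax) == 0) return(NA_real_)
  # the fundamental period is the first strong local maximum; later maxima
  # at period multiples can edge higher through finite-sample noise
  strong <- locmax[r[locmax + 1] >= 0.8 * max(r[locmax + 1])]
  k <- strong[1]
  y1 <- r[k]; y2 <- r[k + 1]; y3 <- r[k + 2]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  k + max(-0.5, min(0.5, delta))
}
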