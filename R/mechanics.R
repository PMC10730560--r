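# Post-processing of quasi-static cyclic mechanical tests and adhesion
# traces: nominal stress / natural strain, cycle segmentation, tangent
# moduli, pull-off normalization.

#' Nominal stress and natural strain from raw machine signals
#'
#' `P = force / area0` (nominal stress, force over undeformed section) and
#' `eps = log(1 + u / length0)` (natural strain from crosshead displacement,
#' no extensometer correction).
#'
#' @param force cell force, N.
#' @param displacement crosshead displacement, mm.
#' @param area0 undeformed cross-section, mm^2.
#' @param length0 gauge length, mm (bench tensile samples: 50 mm).
#' @return list with `strain` (dimensionless) and `stress` (MPa;
#'   N/mm^2 = MPa).
#' @export
#' @examples
#' stress_strain_from_raw(1, 50, area0 = 20, length0 = 50)
#' # stress 0.05 MPa, strain log(2)
stress_strain_from_raw <- function(force, displacement, area0, length0) {
  stopifnot(area0 > 0, length0 > 0)
  if (any(displacement <= -length0))
    stop("displacement <= -length0: sample length would be non-positive")
  list(strain = log(1 + displacement / length0), stress = force / area0)
}

#' Inverse of the natural-strain transform
#'
#' Crosshead displacement reproducing a given natural strain:
#' `u = length0 * (exp(eps) - 1)`.
#'
#' @param strain natural strain.
#' @param length0 gauge length, mm.
#' @return displacement in mm.
#' @export
displacement_from_strain <- function(strain, length0) {
  stopifnot(length0 > 0)
  length0 * (exp(strain) - 1)
}

#' Segment a cyclic strain history into load/unload cycles
#'
#' Turning points are located from sign changes of the smoothed strain
#' increment; reversals smaller than `min_amplitude` (relative to the peak
#' strain) are ignored. A monotone record yields a single loading segment
#' and no unloads. A warning flags non-increasing cycle peaks (the bench
#' protocol uses increasing amplitudes).
#'
#' @param strain strain history.
#' @param smooth number of samples of the moving-average smoother applied
#'   before differentiation.
#' @param min_amplitude minimum reversal amplitude as a fraction of the
#'   maximum absolute strain (default 5%; reversals smaller than this are
#'   treated as noise).
#' @return list with `cycles` (list of `load`/`unload` index ranges and
#'   `peak_strain`), `peaks` (peak strains) and `loading_only` (logical).
#' @export
segment_cycles <- function(strain, smooth = 5, min_amplitude = 0.05) {
  s <- as.numeric(strain)
  n <- length(s)
  stopifnot(n >= 3)
  if (smooth > 1) {
    k <- min(smooth, n)
    sm <- as.numeric(stats::filter(s, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- s[is.na(sm)]
  } else sm <- s
  amp_min <- min_amplitude * max(abs(s))
  # turning points by zigzag extremum search with amplitude hysteresis
  turns <- integer(0)
  dir <- 0 # +1 rising, -1 falling, 0 undecided
  max_v <- min_v <- sm[1]
  max_i <- min_i <- 1L
  for (i in 2:n) {
    if (sm[i] > max_v) { max_v <- sm[i]; max_i <- i }
    if (sm[i] < min_v) { min_v <- sm[i]; min_i <- i }
    if (dir >= 0 && max_v - sm[i] > amp_min) {
      turns <- c(turns, max_i)
      dir <- -1; min_v <- sm[i]; min_i <- i
    } else if (dir <= 0 && sm[i] - min_v > amp_min) {
      if (dir != 0) turns <- c(turns, min_i) # skip the flat start
      dir <- 1; max_v <- sm[i]; max_i <- i
    }
  }
  if (length(turns) == 0)
    return(list(cycles = list(), peaks = numeric(0), loading_only = TRUE))
  # refine each turning point on the raw signal near the smoothed extremum
  half <- max(2L, smooth)
  turns <- vapply(seq_along(turns), function(j) {
    i <- turns[j]
    win <- max(1L, i - half):min(n, i + half)
    is_max <- j %% 2 == 1 # first turn is a peak (record starts near 0)
    win[if (is_max) which.max(s[win]) else which.min(s[win])]
  }, integer(1))
  odd <- seq_along(turns) %% 2 == 1
  peaks_idx <- turns[odd]
  valleys_idx <- c(turns[!odd], if (length(turns) %% 2 == 1) n)
  cycles <- list()
  start <- 1L
  for (i in seq_along(peaks_idx)) {
    cycles[[i]] <- list(load = c(start, peaks_idx[i]),
                        unload = c(peaks_idx[i], valleys_idx[i]),
                        peak_strain = s[peaks_idx[i]])
    start <- valleys_idx[i]
  }
  peaks <- vapply(cycles, function(cy) cy$peak_strain, numeric(1))
  if (length(peaks) > 1 && any(diff(peaks) < 0))
    warning("cycle peak strains are not non-decreasing")
  list(cycles = cycles, peaks = peaks, loading_only = FALSE)
}

#' Tangent modulus along a stress-strain path
#'
#' `Et = dP/deps` estimated by local linear regression of stress on strain
#' in a sliding strain window, evaluated on a uniform strain grid spanning
#' the chosen segment (by convention the last unloading path, where the
#' material response is stabilized).
#'
#' @param record a `stress_strain_record` from [gen_tensile()], or any list
#'   with `strain`, `stress` and optionally `cycles`.
#' @param path `"last_unload"`, `"last_load"`, or an explicit index range
#'   `c(i0, i1)`.
#' @param window width of the sliding strain window (strain units,
#'   default 0.05).
#' @param n_grid grid points.
#' @return list of class `tangent_modulus_curve` with `strain` (grid), `Et`
#'   (MPa) and `path`.
#' @export
tangent_modulus <- function(record, path = "last_unload", window = 0.05,
                            n_grid = 50) {
  cycles <- record$cycles
  if (is.null(cycles) && is.character(path))
    cycles <- segment_cycles(record$strain)$cycles
  idx <- if (is.numeric(path)) {
    seq(path[1], path[2])
  } else {
    if (length(cycles) == 0) stop("no cycles found in record")
    last <- cycles[[length(cycles)]]
    rng <- if (path == "last_unload") last$unload else last$load
    seq(rng[1], rng[2])
  }
  eps <- record$strain[idx]
  sig <- record$stress[idx]
  if (length(eps) < 10) stop("chosen segment has fewer than 10 samples")
  span <- range(eps)
  if (window > diff(span)) stop("window larger than the segment strain span")
  grid <- seq(span[1] + window / 2, span[2] - window / 2,
              length.out = n_grid)
  et <- vapply(grid, function(e0) {
    sel <- abs(eps - e0) <= window / 2
    if (sum(sel) < 2) return(NA_real_)
    unname(coef(lm(sig[sel] ~ eps[sel]))[2])
  }, numeric(1))
  structure(list(strain = grid, Et = et,
                 path = if (is.numeric(path)) "explicit" else path),
            class = "tangent_modulus_curve")
}

#' Normalize an adhesion pull-off trace
#'
#' Divides the force by `f_relax`, the mean absolute force over the
#' relaxation window (the settled contact force), and locates the
#' separation time: the first time after the post-pull force peak at which
#' the normalized force decays to 5% of that peak.
#'
#' @param force force trace, N.
#' @param time sample times, s.
#' @param relax_window `c(start, end)` of the relaxation hold, s, inside the
#'   trace.
#' @param sep_frac separation threshold as a fraction of the post-pull peak.
#' @return list of class `adhesion_trace` with `time`, `normalized_force`
#'   (`f / f_relax`, = 1 in magnitude at the end of relaxation by
#'   construction), `f_relax` (N), `separation_time` (s, `NA` if the force
#'   never decays below threshold).
#' @export
adhesion_normalize <- function(force, time, relax_window, sep_frac = 0.05) {
  stopifnot(length(force) == length(time))
  if (relax_window[1] < min(time) || relax_window[2] > max(time) ||
      relax_window[1] >= relax_window[2])
    stop("relax_window must lie inside the trace")
  in_relax <- time >= relax_window[1] & time <= relax_window[2]
  f_relax <- mean(abs(force[in_relax]))
  if (f_relax <= 0 || f_relax < 1e-9 * max(abs(force)))
    stop("no contact established: relaxation force is zero")
  nf <- force / f_relax
  after <- which(time > relax_window[2])
  separation_time <- NA_real_
  if (length(after) > 2) {
    ipk <- after[which.max(nf[after])]
    pk <- nf[ipk]
    if (pk > 0) {
      drop <- which(time > time[ipk] & nf <= sep_frac * pk)
      if (length(drop)) separation_time <- time[drop[1]]
    }
  }
  structure(list(time = time, normalized_force = nf, f_relax = f_relax,
                 separation_time = separation_time),
            class = "adhesion_trace")
}
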