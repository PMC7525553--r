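#' Instrument geometry
#'
#' Holds the constants mapping detector pixels to scattering vector q: the
#' sample-to-detector distance, X-ray wavelength, physical pixel size and
#' the resolution enhancement factor f (the effective pixel is l/f).
#'
#' @param d_s sample-detector distance, mm.
#' @param wavelength X-ray wavelength, Angstrom.
#' @param pixel_size physical detector pixel size l, micrometers.
#' @param f integer enhancement factor (effective pixel l/f).
#' @param beam_center optional `c(row, col)` beam center, pixels.
#' @return object of class `instrument_geometry`.
#' @export
instrument_geometry <- function(d_s = 117, wavelength = 1.54,
                                pixel_size = 172, f = 1L,
                                beam_center = NULL) {
  if (d_s <= 0 || wavelength <= 0 || pixel_size <= 0)
    stop("geometry constants must be positive")
  f <- as.integer(f)
  if (f < 1L) stop("f must be a positive integer")
  structure(list(d_s = d_s, wavelength = wavelength, pixel_size = pixel_size,
                 f = f, beam_center = beam_center),
            class = "instrument_geometry")
}

#' Map a radial pixel distance to scattering vector modulus q
#'
#' `tan(2 theta) = delta_r / d_s` with `delta_r = radius * (l/f)`, and
#' `q = 4 pi sin(theta) / lambda`. Strictly increasing in radius.
#'
#' @param radius_px radial distance from the beam center in effective (l/f)
#'   pixels; non-negative.
#' @param geom an [instrument_geometry()].
#' @return q in inverse Angstrom.
#' @export
pixel_to_q <- function(radius_px, geom) {
  stopifnot(inherits(geom, "instrument_geometry"))
  if (any(radius_px < 0)) stop("radius must be non-negative")
  dr_mm <- radius_px * (geom$pixel_size / geom$f) * 1e-3
  theta <- 0.5 * atan(dr_mm / geom$d_s)
  4 * pi * sin(theta) / geom$wavelength
}

#' 1D azimuthal integration
#'
#' Averages an isotropic 2D pattern over annuli around the beam center:
#' per bin of radial width `bin_width`, the mean and standard deviation of
#' the valid-pixel intensities. Bins containing no valid pixel are dropped.
#'
#' @param image intensity matrix.
#' @param center `c(row, col)` beam center; defaults to the grid center.
#' @param mask logical matrix of valid pixels (TRUE = valid), or `NULL`.
#' @param bin_width annulus width in pixels (default one pixel, i.e. one
#'   effective pixel on whatever grid `image` lives).
#' @param geom optional [instrument_geometry()]; when given, a `q` column
#'   (computed at `radius_px`) is included.
#' @param radius_scale multiply pixel radii by this factor before binning is
#'   reported (used to place low-resolution profiles on the l/f axis).
#' @return `radial_profile` data.frame with columns `radius_px`, `intensity`,
#'   `spread`, `n_pixels` (and `q` if `geom` given).
#' @export
azimuthal_integrate <- function(image, center = NULL, mask = NULL,
                                bin_width = 1, geom = NULL,
                                radius_scale = 1) {
  d <- dim(image)
  if (is.null(center)) center <- default_center(d)
  if (center[1] < 1 || center[1] > d[1] || center[2] < 1 || center[2] > d[2])
    stop("center outside image")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!all(dim(mask) == d)) stop("mask shape mismatch")
  if (!any(mask)) stop("all pixels masked")
  rho <- rho_matrix(d, center)
  v <- image[mask]
  r <- rho[mask]
  # bins centered on integer multiples of bin_width, so a ring at an integer
  # pixel radius falls mid-bin rather than on a bin edge
  bin <- round(r / bin_width)
  n <- tapply(v, bin, length)
  mu <- tapply(v, bin, mean)
  sdv <- tapply(v, bin, stats::sd)
  sdv[is.na(sdv)] <- 0
  centers <- as.numeric(names(n)) * bin_width * radius_scale
  ord <- order(centers)
  out <- data.frame(radius_px = centers[ord], intensity = as.numeric(mu)[ord],
                    spread = as.numeric(sdv)[ord],
                    n_pixels = as.integer(n)[ord])
  if (!is.null(geom)) out$q <- pixel_to_q(out$radius_px, geom)
  attr(out, "bin_width") <- bin_width * radius_scale
  class(out) <- c("radial_profile", "data.frame")
  out
}

# interior local maxima of y with their topographic prominence inside the
# window (boundary points are not peaks; runs of equal values count once)
local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  # keep only strict rises on the left to avoid double-counting plateaus
  idx[y[idx] > y[pmax(idx - 1L, 1L)] | y[idx] > y[pmin(idx + 1L, n)]]
}

peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    lefts <- y[seq_len(i - 1)]
    rights <- y[seq(i + 1, length(y))]
    hl <- which(lefts > y[i])
    hr <- which(rights > y[i])
    lmin <- if (length(hl)) min(lefts[seq(max(hl), i - 1)]) else min(lefts)
    rmin <- if (length(hr)) min(rights[seq_len(min(hr))]) else min(rights)
    y[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Peak-separation criterion delta for a close doublet
#'
#' Detects the two most intense local maxima inside `window` and the valley
#' between them, and scores the separation as
#' `delta = (I_p - I_v) / delta_q`, where `I_p` is the intensity of the
#' LOWER of the two peaks, `I_v` the valley intensity, and `delta_q` by
#' default the axis distance between the lower peak and the valley
#' (`peak_to_peak = TRUE` uses the peak-to-peak distance instead). When
#' fewer than two peaks, or no interior valley, are found the doublet is
#' unresolved and `delta = 0`.
#'
#' Peaks must have topographic prominence of at least three times the median
#' standard error of the bin means (`spread / sqrt(n_pixels)`) inside the
#' window (ties broken toward smaller radius), so that noise wiggles on a
#' merged doublet do not count as separation.
#'
#' @param profile a `radial_profile` (from [azimuthal_integrate()]) or a
#'   data.frame with an axis column and `intensity`.
#' @param window `c(lo, hi)` axis interval holding the candidate doublet;
#'   `NULL` uses the full profile.
#' @param axis which column is the abscissa: `"radius_px"` (default) or
#'   `"q"`.
#' @param peak_to_peak use the peak-to-peak distance as `delta_q`.
#' @param min_prominence override the noise-scaled prominence threshold.
#' @return object of class `separation_result` with fields `delta`, `I_p`,
#'   `I_v`, `dq`, `peaks`, `valley`.
#' @export
separation_delta <- function(profile, window = NULL, axis = "radius_px",
                             peak_to_peak = FALSE, min_prominence = NULL) {
  x <- profile[[axis]]
  y <- profile$intensity
  if (is.null(window)) window <- range(x)
  keep <- x >= window[1] & x <= window[2]
  if (!any(keep)) stop("empty window")
  x <- x[keep]; y <- y[keep]
  se <- profile$spread[keep]
  if (!is.null(profile$n_pixels)) se <- se / sqrt(pmax(profile$n_pixels[keep], 1))
  none <- structure(list(delta = 0, I_p = NA_real_, I_v = NA_real_,
                         dq = NA_real_, peaks = numeric(0),
                         valley = NA_real_),
                    class = "separation_result")
  if (length(x) < 3) return(none)
  if (is.null(min_prominence)) {
    s <- stats::median(se, na.rm = TRUE)
    min_prominence <- if (is.finite(s)) 3 * s else 0
  }
  idx <- local_peaks(y)
  if (length(idx) >= 1) {
    prom <- peak_prominence(y, idx)
    idx <- idx[prom >= min_prominence]
  }
  if (length(idx) < 2) return(none)
  # two most intense peaks; ties toward smaller axis value
  ord <- order(-y[idx], x[idx])
  two <- sort(idx[ord[1:2]])
  seg <- seq(two[1], two[2])
  vi <- seg[which.min(y[seg])]
  if (vi == two[1] || vi == two[2]) return(none)
  if (y[vi] >= min(y[two])) return(none)
  lower <- two[which.min(y[two])]
  I_p <- y[lower]
  I_v <- y[vi]
  dq <- if (peak_to_peak) abs(x[two[2]] - x[two[1]]) else abs(x[lower] - x[vi])
  structure(list(delta = (I_p - I_v) / dq, I_p = I_p, I_v = I_v, dq = dq,
                 peaks = x[two], valley = x[vi]),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  if (length(x$peaks) == 2)
    cat(sprintf("delta = %.4g (I_p=%.4g, I_v=%.4g, dq=%.4g, peaks at %.3g/%.3g)\n",
                x$delta, x$I_p, x$I_v, x$dq, x$peaks[1], x$peaks[2]))
  else cat("delta = 0 (no distinction of close peaks observed)\n")
  invisible(x)
}

#' Scale a radial profile to unit maximum
#'
#' SAXS profiles are reported in arbitrary units; before comparing
#' separation statistics across acquisitions the intensity axis is scaled to
#' a unit maximum over the analysis window (spread scales along), which is
#' the scale on which the delta criterion is quoted.
#'
#' @param profile a `radial_profile`.
#' @param window optional `c(lo, hi)` axis interval over which the maximum
#'   is taken; default the whole profile.
#' @param axis abscissa column name.
#' @return the rescaled profile.
#' @export
profile_normalize <- function(profile, window = NULL, axis = "radius_px") {
  x <- profile[[axis]]
  keep <- if (is.null(window)) rep(TRUE, length(x))
          else x >= window[1] & x <= window[2]
  top <- max(profile$intensity[keep])
  if (top <= 0) return(profile)
  profile$intensity <- profile$intensity / top
  profile$spread <- profile$spread / top
  profile
}

#' Repeat-based uncertainty of the separation criterion
#'
#' Runs the full simulate-retrieve-score chain `n_repeats` times with
#' distinct child seeds and returns the sample mean and standard deviation
#' of delta. A repeat whose peak detection fails contributes delta = 0 (with
#' a message), not an exception.
#'
#' @param experiment function of one argument (an integer seed) returning a
#'   numeric delta or a `separation_result`.
#' @param n_repeats number of repeats (default 40).
#' @param seed root seed for the child-seed stream.
#' @return list with `mean`, `sd` and the vector `deltas`.
#' @export
delta_uncertainty <- function(experiment, n_repeats = 40, seed = 1L) {
  seeds <- child_seeds(seed, n_repeats)
  deltas <- vapply(seeds, function(s) {
    out <- tryCatch(experiment(s), error = function(e) {
      message("repeat failed (", conditionMessage(e), "); delta = 0")
      0
    })
    if (inherits(out, "separation_result")) out$delta else as.numeric(out)
  }, numeric(1))
  if (n_repeats < 2) {
    warning("fewer than 2 repeats: std reported as 0")
    return(list(mean = mean(deltas), sd = 0, deltas = deltas))
  }
  list(mean = mean(deltas), sd = stats::sd(deltas), deltas = deltas)
}

#' Frobenius retrieval error against the ground truth
#'
#' `||Xhat - GT||_F` after (by default) scaling both images to unit total
#' intensity, so retrievals at different flux scales are comparable. When
#' the ground truth lives on a finer grid whose dimensions are an integer
#' multiple of the retrieval grid, it is box-summed down first (counts are
#' additive).
#'
#' @param xhat retrieved intensity matrix.
#' @param gt ground-truth intensity matrix.
#' @param normalize scale both to unit total first (default TRUE).
#' @return scalar Frobenius error.
#' @export
retrieval_error <- function(xhat, gt, normalize = TRUE) {
  if (!all(dim(xhat) == dim(gt))) {
    rat <- dim(gt) / dim(xhat)
    if (all(rat == rat[1]) && rat[1] == round(rat[1]) && rat[1] >= 1)
      gt <- box_sum(gt, as.integer(rat[1]))
    else stop("shape mismatch after alignment")
  }
  if (normalize) {
    xhat <- xhat / sum(xhat)
    gt <- gt / sum(gt)
  }
  sqrt(sum((xhat - gt)^2))
}
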