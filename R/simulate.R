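#' Ground-truth scattering pattern
#'
#' Describes an isotropic SAXS ground truth on the high-resolution (l/f)
#' grid: a set of concentric Lorentzian rings, a spurious background falling
#' off as the reciprocal of the distance from the beam center (I_bkg
#' proportional to 1/q), and a central beamstop masking the direct-beam
#' singularity.
#'
#' Each ring has peak value `amplitude` at distance `radius` from the center
#' (the Lorentzian is used unnormalized, so amplitudes are directly the peak
#' intensities in counts per unit exposure time).
#'
#' @param rings data.frame (or coercible) with columns `radius`, `width`,
#'   `amplitude`, all in high-resolution pixels / counts per unit time.
#' @param background_coeff scale of the reciprocal background, counts per
#'   unit time at unit radius.
#' @param beamstop_radius radius (pixels) inside which intensity is zero.
#' @param center `c(row, col)` beam center in pixel coordinates; defaults to
#'   the grid center.
#' @param grid_shape `c(rows, cols)` of the high-resolution grid.
#' @return object of class `saxs_pattern`.
#' @export
saxs_pattern <- function(rings, background_coeff = 0, beamstop_radius = 0,
                         center = NULL, grid_shape = c(255L, 255L)) {
  rings <- as.data.frame(rings)
  stopifnot(all(c("radius", "width", "amplitude") %in% names(rings)))
  if (nrow(rings) > 0 &&
      any(rings$radius <= 0 | rings$width <= 0 | rings$amplitude <= 0))
    stop("ring radii, widths and amplitudes must be positive")
  if (background_coeff < 0 || beamstop_radius < 0)
    stop("background_coeff and beamstop_radius must be non-negative")
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 1L)) stop("grid_shape must be positive")
  if (is.null(center)) center <- default_center(grid_shape)
  structure(list(rings = rings, background_coeff = background_coeff,
                 beamstop_radius = beamstop_radius, center = center,
                 grid_shape = grid_shape),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat("SAXS ground-truth pattern:", nrow(x$rings), "ring(s) on",
      paste(x$grid_shape, collapse = "x"), "grid\n")
  if (nrow(x$rings)) print(x$rings)
  cat("background_coeff:", x$background_coeff,
      " beamstop_radius:", x$beamstop_radius, "\n")
  invisible(x)
}

#' Render a ground-truth pattern to a high-resolution intensity image
#'
#' Evaluates, at every pixel with distance rho from the beam center,
#' `sum_rings A * gamma^2 / ((rho - R)^2 + gamma^2) + background_coeff / rho`
#' for `rho > beamstop_radius`, and 0 under the beamstop. Deterministic.
#'
#' @param pattern a [saxs_pattern()].
#' @return non-negative intensity matrix (counts per unit exposure time).
#' @export
render_ground_truth <- function(pattern) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  rho <- rho_matrix(pattern$grid_shape, pattern$center)
  if (nrow(pattern$rings) > 0 && any(pattern$rings$radius > max(rho)))
    warning("ring radius beyond grid; ring truncated")
  img <- matrix(0, pattern$grid_shape[1], pattern$grid_shape[2])
  for (i in seq_len(nrow(pattern$rings))) {
    R <- pattern$rings$radius[i]
    g <- pattern$rings$width[i]
    A <- pattern$rings$amplitude[i]
    img <- img + A * g^2 / ((rho - R)^2 + g^2)
  }
  if (pattern$background_coeff > 0)
    img <- img + pattern$background_coeff / pmax(rho, .Machine$double.eps)
  img[rho <= pattern$beamstop_radius] <- 0
  img
}

#' Analytic radial intensity of a pattern
#'
#' The closed-form 1D curve underlying [render_ground_truth()]; used as the
#' noise-free reference when evaluating separation statistics against the
#' ground truth.
#'
#' @param pattern a [saxs_pattern()].
#' @param radius numeric vector of radii (high-resolution pixels).
#' @return intensity vector.
#' @export
analytic_profile <- function(pattern, radius) {
  y <- numeric(length(radius))
  for (i in seq_len(nrow(pattern$rings))) {
    R <- pattern$rings$radius[i]
    g <- pattern$rings$width[i]
    A <- pattern$rings$amplitude[i]
    y <- y + A * g^2 / ((radius - R)^2 + g^2)
  }
  if (pattern$background_coeff > 0)
    y <- y + pattern$background_coeff / pmax(radius, .Machine$double.eps)
  y[radius <= pattern$beamstop_radius] <- 0
  y
}

#' Beam-profile point-spread function model
#'
#' The direct-beam PSF of a slit-collimated source: a rectangular scatterless
#' slit aperture convolved with a Gaussian source profile, separable in x and
#' y. The convolution of a rectangle and a Gaussian is a difference of error
#' functions, which is the closed form used when rasterizing.
#'
#' @param width_x,width_y slit openings (full widths); same length unit as
#'   `pitch`.
#' @param sigma Gaussian source standard deviation; same unit.
#' @param pitch rendering pixel pitch (length unit per high-resolution
#'   pixel); widths are divided by `pitch` at rasterization. Default 1, i.e.
#'   widths given directly in pixels.
#' @param flux_scale kernel sum relative to the reference PSF of a set;
#'   larger slits pass more flux, see [default_psf_set()].
#' @param id optional label used to group detector frames by PSF.
#' @return object of class `psf_model`.
#' @export
psf_model <- function(width_x, width_y = width_x, sigma = 1, pitch = 1,
                      flux_scale = 1, id = NULL) {
  if (width_x < 0 || width_y < 0 || sigma < 0)
    stop("widths and sigma must be non-negative")
  if (pitch <= 0 || flux_scale <= 0) stop("pitch and flux_scale must be positive")
  if (is.null(id)) id <- sprintf("psf_%gx%g_s%g", width_x, width_y, sigma)
  structure(list(width_x = width_x, width_y = width_y, sigma = sigma,
                 pitch = pitch, flux_scale = flux_scale, id = id),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("PSF '%s': slit %g x %g, source sigma %g (pitch %g), flux %.3g\n",
              x$id, x$width_x, x$width_y, x$sigma, x$pitch, x$flux_scale))
  invisible(x)
}

# Per-pixel mass of a width-w rectangle (height 1) convolved with a sigma-s
# Gaussian, integrated over [u - 1/2, u + 1/2]. Uses the exact antiderivative
# H(x) = x*pnorm(x/s) + s*dnorm(x/s) of the erf-difference profile, so kernel
# sums are exact and the s -> 0 limit is the fractional pixel coverage of the
# rectangle.
psf_axis_mass <- function(u, w, s) {
  M <- function(x) {
    if (w == 0 && s == 0) return(as.numeric(x >= 0))
    if (w == 0) return(stats::pnorm(x / s))        # unit-mass Gaussian limit
    H <- if (s == 0) function(z) pmax(z, 0)
         else function(z) z * stats::pnorm(z / s) + s * stats::dnorm(z / s)
    (H(x + w / 2) - H(x - w / 2)) / w              # unit total mass
  }
  M(u + 0.5) - M(u - 0.5)
}

#' Rasterize a PSF model to a kernel image
#'
#' Produces the separable kernel `k(x) k(y)` on an odd `support` x `support`
#' pixel grid, each axis profile being the pixel-integrated mass of the
#' slit-rectangle-times-Gaussian beam profile. The kernel sum is scaled to
#' the model's `flux_scale`.
#'
#' @param model a [psf_model()].
#' @param support odd kernel side length (pixels); if `NULL` a support
#'   holding at least `1 - 1e-4` of the analytic mass is chosen.
#' @return `support` x `support` kernel matrix with attribute `flux_scale`.
#' @export
render_psf <- function(model, support = NULL) {
  stopifnot(inherits(model, "psf_model"))
  wx <- model$width_x / model$pitch
  wy <- model$width_y / model$pitch
  s <- model$sigma / model$pitch
  if (is.null(support)) {
    h <- ceiling(max(wx, wy) / 2 + 4 * s + 1)
    support <- 2L * as.integer(h) + 1L
  }
  support <- as.integer(support)
  if (support < 3L || !is_odd(support)) stop("support must be odd and >= 3")
  h <- (support - 1L) %/% 2L
  u <- (-h):h
  # the analytic mass is non-negative; clear floating-point dust in the tails
  kx <- pmax(psf_axis_mass(u, wx, s), 0)
  ky <- pmax(psf_axis_mass(u, wy, s), 0)
  if (sum(kx) < 1 - 1e-4 || sum(ky) < 1 - 1e-4)
    stop(sprintf("support %d too small: axis masses %.6f / %.6f < %.4f",
                 support, sum(kx), sum(ky), 1 - 1e-4))
  k <- outer(ky, kx)
  k <- k * (model$flux_scale / sum(k))
  attr(k, "flux_scale") <- model$flux_scale
  k
}

#' Blur an image with a PSF kernel
#'
#' The smearing forward model: measured intensity is the convolution of the
#' sample scattering intensity with the system PSF. Reflective boundary
#' handling (see [conv2()]).
#'
#' @param image high-resolution intensity matrix.
#' @param psf kernel matrix (from [render_psf()]) or a [psf_model()].
#' @param boundary passed to [conv2()].
#' @return blurred intensity matrix; total intensity is `flux_scale` times
#'   the input total for interior-dominated patterns.
#' @export
blur <- function(image, psf, boundary = "reflect") {
  if (inherits(psf, "psf_model")) psf <- render_psf(psf)
  conv2(image, psf, boundary = boundary)
}

#' Sample one detector frame from a blurred high-resolution intensity
#'
#' Models detector readout at a subpixel stage translation: the
#' high-resolution intensity is cropped at the integer subpixel offset
#' `shift` (in l/f units), summed over disjoint `f` x `f` cells (counts are
#' additive photon tallies), scaled by the exposure `t`, and passed through a
#' Poisson process.
#'
#' @param image_hr high-resolution intensity matrix (counts per unit time).
#' @param shift `c(drow, dcol)` integer offsets in high-resolution pixels,
#'   each in `[0, f)`.
#' @param f integer resolution enhancement factor.
#' @param t exposure time (time units).
#' @param seed optional integer seed for reproducible sampling.
#' @param psf_id optional PSF label carried in the frame.
#' @param pixel_size physical pixel size l (micrometers), metadata only.
#' @return object of class `detector_frame` with integer `counts`.
#' @export
sample_frame <- function(image_hr, shift = c(0L, 0L), f = 1L, t = 1,
                         seed = NULL, psf_id = NULL, pixel_size = 172) {
  f <- as.integer(f)
  shift <- as.integer(round(shift))
  if (f < 1L) stop("f must be >= 1")
  if (any(shift < 0L) || any(shift >= f)) stop("shift must lie in [0, f)")
  if (t < 0) stop("exposure must be non-negative")
  d <- dim(image_hr)
  n_lr <- (d - (f - 1L)) %/% f
  if (any(n_lr < 1L)) stop("image too small for enhancement factor f")
  sub <- image_hr[shift[1] + seq_len(n_lr[1] * f),
                  shift[2] + seq_len(n_lr[2] * f), drop = FALSE]
  lam <- t * box_sum(sub, f)
  # tolerate FFT dust from upstream convolutions, reject real negatives
  floor_tol <- -1e-9 * max(abs(lam), 1)
  if (any(lam < floor_tol))
    stop("negative intensity: cannot sample Poisson counts")
  lam <- pmax(lam, 0)
  counts <- with_seed(seed, matrix(stats::rpois(length(lam), lam),
                                   nrow(lam), ncol(lam)))
  structure(list(counts = counts, exposure = t, shift = shift, f = f,
                 psf_id = psf_id, pixel_size = pixel_size,
                 mask = matrix(TRUE, nrow(counts), ncol(counts)),
                 seed = seed),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("detector frame %dx%d, t=%g, shift=(%d,%d), f=%d, psf=%s\n",
              nrow(x$counts), ncol(x$counts), x$exposure, x$shift[1],
              x$shift[2], x$f, x$psf_id %||% "<none>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The default six-PSF set built from three square slit sizes
#'
#' From a given smallest square slit of side `s` (in effective l/f pixels)
#' and the two larger sizes `s + 1` and `s + 2`, six distinct PSFs are
#' formed: the three squares and the three rectangular combinations. Flux
#' scales are proportional to slit area, normalized so the smallest PSF has
#' `flux_scale = 1` (larger slits pass more photons per unit time).
#'
#' @param s smallest slit side, in high-resolution (l/f) pixels.
#' @param sigma Gaussian source sigma (same units), default 1.
#' @return list of six [psf_model()] objects, smallest first.
#' @export
default_psf_set <- function(s = 2, sigma = 1) {
  sizes <- list(c(s, s), c(s + 1, s + 1), c(s + 2, s + 2),
                c(s, s + 1), c(s, s + 2), c(s + 1, s + 2))
  areas <- vapply(sizes, prod, numeric(1))
  models <- lapply(seq_along(sizes), function(i)
    psf_model(width_x = sizes[[i]][1], width_y = sizes[[i]][2], sigma = sigma,
              flux_scale = areas[i] / areas[1],
              id = sprintf("psf%d_%gx%g", i, sizes[[i]][1], sizes[[i]][2])))
  models
}

#' Effective PSF of an SPS-fused image on the l/f grid
#'
#' A detector pixel integrates over its full `f` x `f` footprint of l/f
#' cells, so a fused high-resolution image is blurred by the beam PSF *and*
#' the pixel footprint — exactly as a direct-beam PSF measured through the
#' same SPS acquisition would be. This composes the rasterized beam kernel
#' with the discrete footprint box at the placement convention of
#' [fuse_sps()] (centered for odd `f`).
#'
#' @param model a [psf_model()] or an already-rendered kernel matrix.
#' @param f enhancement factor.
#' @return kernel matrix on the l/f grid including the pixel footprint.
#' @export
effective_hr_psf <- function(model, f) {
  k <- if (inherits(model, "psf_model")) render_psf(model) else model
  f <- as.integer(f)
  if (f == 1L) return(k)
  c0 <- (f - 1L) %/% 2L
  u <- c0 - (0:(f - 1L))            # convolution offsets of the footprint
  hb <- max(abs(u))
  bx <- numeric(2L * hb + 1L)
  bx[u + hb + 1L] <- 1 / f
  box2 <- outer(bx, bx)
  S <- nrow(k)
  n <- S + 2L * hb
  pad <- matrix(0, n, n)
  o <- hb
  pad[o + seq_len(S), o + seq_len(ncol(k))] <- k
  conv2(pad, box2, boundary = "circular")
}

#' The full 3x3 subpixel shift grid for enhancement factor f
#' @param f integer enhancement factor.
#' @return list of `f^2` integer shift pairs `c(drow, dcol)`.
#' @export
shift_grid <- function(f) {
  f <- as.integer(f)
  unlist(lapply(0:(f - 1L), function(r) lapply(0:(f - 1L), function(c)
    c(r, c))), recursive = FALSE)
}

#' Simulate a full acquisition: render, blur, translate, count
#'
#' Renders the ground truth once, blurs it with each PSF of the set, and
#' Poisson-samples one detector frame per (PSF, subpixel shift) pair with
#' per-frame child seeds derived from the root seed.
#'
#' @param pattern a [saxs_pattern()].
#' @param psf_models list of [psf_model()] (e.g. [default_psf_set()]).
#' @param f enhancement factor.
#' @param shifts list of integer `c(drow, dcol)` shifts (e.g.
#'   [shift_grid()]).
#' @param t_per_frame exposure per frame.
#' @param seed root seed.
#' @param protocol optional protocol label; inferred from the geometry of
#'   the set when `NULL` (plain / SPS / CMD / SrSAXS).
#' @return object of class `frame_set`.
#' @export
simulate_acquisition <- function(pattern, psf_models, f, shifts, t_per_frame,
                                 seed = NULL, protocol = NULL) {
  if (length(psf_models) == 0 || length(shifts) == 0)
    stop("need at least one PSF model and one shift")
  if (inherits(psf_models, "psf_model")) psf_models <- list(psf_models)
  gt <- render_ground_truth(pattern)
  m <- length(psf_models)
  nshift <- length(shifts)
  seeds <- child_seeds(seed %||% 1L, m * nshift)
  frames <- vector("list", m * nshift)
  k <- 0L
  for (i in seq_len(m)) {
    blurred <- blur(gt, psf_models[[i]])
    for (j in seq_len(nshift)) {
      k <- k + 1L
      frames[[k]] <- sample_frame(blurred, shift = shifts[[j]], f = f,
                                  t = t_per_frame, seed = seeds[k],
                                  psf_id = psf_models[[i]]$id)
    }
  }
  if (is.null(protocol)) {
    protocol <- if (m == 1 && nshift == 1) "plain"
    else if (m == 1) "SPS"
    else if (nshift == 1) "CMD"
    else "SrSAXS"
  }
  frame_set(frames, f = f, psf_models = psf_models, protocol = protocol,
            pattern = pattern)
}

#' Construct a frame set
#'
#' @param frames list of [sample_frame()] results sharing shape and f.
#' @param f enhancement factor.
#' @param psf_models list of the PSF models referenced by the frames.
#' @param protocol label: plain, SPS, CMD or SrSAXS.
#' @param pattern optional generating [saxs_pattern()] (simulations only).
#' @return object of class `frame_set`.
#' @export
frame_set <- function(frames, f, psf_models = list(), protocol = "plain",
                      pattern = NULL) {
  stopifnot(length(frames) > 0)
  dims <- vapply(frames, function(fr) dim(fr$counts), integer(2))
  if (any(dims != dims[, 1])) stop("frames must share shape")
  ids <- vapply(frames, function(fr) fr$psf_id %||% "<none>", character(1))
  structure(list(frames = frames, f = as.integer(f),
                 psf_models = psf_models, m = length(unique(ids)),
                 protocol = protocol, pattern = pattern),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame set: %d frame(s), m=%d PSF(s), f=%d, protocol %s\n",
              length(x$frames), x$m, x$f, x$protocol))
  invisible(x)
}
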