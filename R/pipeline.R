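#' Combined super-resolution retrieval: SPS fusion then CMD
#'
#' The full two-stage retrieval. Subpixel sampling runs first — the blur
#' happens physically before the detector decimates the signal, and running
#' the deconvolution first would corrupt the subpixel translations that the
#' registration step relies on. Per PSF group: Lucas-Kanade registration and
#' median shift-and-add fusion onto the l/f lattice; then Constrained
#' Multi-Deconvolution across the m fused images with the PSFs rasterized at
#' the l/f pitch.
#'
#' @param frameset a [frame_set()] containing all `f^2` shift positions for
#'   each PSF.
#' @param nu ridge coefficient for the CMD stage.
#' @param weight_mode weight profile for [compute_weights()].
#' @param register run Lucas-Kanade registration (default) or trust the
#'   nominal shifts.
#' @param model_footprint include the detector pixel footprint in the
#'   deconvolution kernels (default TRUE; see [effective_hr_psf()]).
#' @param ... further arguments to [cmd_solve()].
#' @return object of class `srsaxs_result`: `xhat` (high-resolution
#'   intensity per unit exposure time), `fused` (per-PSF
#'   [fuse_sps()] outputs), `shifts`, `cmd` (the `cmd_result`).
#' @export
srsaxs_retrieve <- function(frameset, nu = 0.1, weight_mode = "balanced",
                            register = TRUE, model_footprint = TRUE, ...) {
  stopifnot(inherits(frameset, "frame_set"))
  f <- frameset$f
  groups <- group_frames(frameset)
  models <- psf_models_by_id(frameset)
  fused <- list(); shifts <- list(); kernels <- list()
  scales <- numeric(0); raw <- numeric(0)
  for (g in names(groups)) {
    fr <- groups[[g]]
    nominal <- unique(t(vapply(fr, function(x) as.numeric(x$shift),
                               numeric(2))))
    if (nrow(nominal) < f^2)
      stop(sprintf("PSF '%s': %d of %d required shift positions present",
                   g, nrow(nominal), f^2))
    sub <- frame_set(fr, f = f, psf_models = models[g],
                     protocol = "SPS")
    est <- if (register) estimate_shifts(sub) else NULL
    fus <- fuse_sps(sub, shifts = est)
    fused[[g]] <- fus
    shifts[[g]] <- est
    model <- models[[g]]
    # beam kernel composed with the detector pixel footprint, as a
    # direct-beam PSF measured through the same SPS acquisition would be;
    # shape only — slit flux gain is carried by `scales`
    k <- if (model_footprint) effective_hr_psf(model, f)
         else render_psf(model)
    kernels[[g]] <- k / sum(k)
    t_mean <- mean(vapply(fr, function(x) x$exposure, numeric(1)))
    scales <- c(scales, t_mean * model$flux_scale)
    raw <- c(raw, sum(fus$intensity))
  }
  w <- compute_weights(raw, mode = weight_mode)
  cmd <- cmd_solve(lapply(fused, function(x) x$intensity), kernels, nu = nu,
                   sigma = w, scales = scales, ...)
  structure(list(xhat = cmd$xhat, fused = fused, shifts = shifts, cmd = cmd,
                 weights = w, f = f),
            class = "srsaxs_result")
}

#' @export
print.srsaxs_result <- function(x, ...) {
  cat(sprintf("SrSAXS retrieval %dx%d (f=%d, m=%d fused PSF groups)\n",
              nrow(x$xhat), ncol(x$xhat), x$f, length(x$fused)))
  invisible(x)
}

#' Frame allocation of the four equal-budget protocols
#'
#' For `m` PSFs and enhancement factor `f` (total budget `m * f^2 * t`):
#' plain takes one long exposure with the smallest PSF; SPS spends the
#' budget on the `f^2` subpixel positions with the smallest PSF; CMD on one
#' position with all `m` PSFs; SrSAXS on all `m * f^2` combinations.
#'
#' @param method one of `"plain"`, `"SPS"`, `"CMD"`, `"SrSAXS"`.
#' @param t base exposure unit.
#' @param f enhancement factor.
#' @param m number of PSFs.
#' @return list with `n_frames`, `t_per_frame`, `n_psf`, `shifts`
#'   (list of subpixel offsets) and `total_time`.
#' @export
protocol_spec <- function(method = c("plain", "SPS", "CMD", "SrSAXS"),
                          t = 1, f = 3L, m = 6L) {
  method <- match.arg(method)
  f <- as.integer(f); m <- as.integer(m)
  out <- switch(method,
    plain  = list(n_psf = 1L, shifts = list(c(0L, 0L)), t_per_frame = m * f^2 * t),
    SPS    = list(n_psf = 1L, shifts = shift_grid(f), t_per_frame = m * t),
    CMD    = list(n_psf = m, shifts = list(c(0L, 0L)), t_per_frame = f^2 * t),
    SrSAXS = list(n_psf = m, shifts = shift_grid(f), t_per_frame = t))
  out$method <- method
  out$n_frames <- out$n_psf * length(out$shifts)
  out$total_time <- out$n_frames * out$t_per_frame
  out
}

#' Simulate one protocol and score the retrieved doublet separation
#'
#' Simulates the acquisition prescribed by [protocol_spec()], runs the
#' protocol's retrieval, azimuthally integrates on the common l/f radial
#' axis (bin width one effective pixel) with intensities in counts per unit
#' exposure per l/f pixel, and evaluates the separation criterion.
#'
#' @param pattern ground-truth [saxs_pattern()] on the l/f grid.
#' @param method protocol name (see [protocol_spec()]).
#' @param t base exposure unit of the budget `m * f^2 * t`.
#' @param f enhancement factor.
#' @param psf_models list of PSF models, smallest first (e.g.
#'   [default_psf_set()]).
#' @param seed root seed for the acquisition.
#' @param nu,weight_mode CMD-stage parameters.
#' @param window axis window (l/f pixels) for the separation statistic;
#'   defaults to a band around the pattern's rings.
#' @param register run registration in SPS-containing protocols.
#' @param delta_bin radial bin width for the separation profile, in l/f
#'   pixels, shared by every protocol so all profiles are compared at the
#'   same radial resolution; azimuthal integration of an isotropic pattern
#'   samples radii continuously, so the profile resolves below the pixel
#'   pitch (default 1/3).
#' @return list with `delta` (a `separation_result`), `profile`, `image`,
#'   `method`, `spec`.
#' @export
run_protocol <- function(pattern, method, t = 1, f = 3L,
                         psf_models = default_psf_set(), seed = 1L,
                         nu = 0.1, weight_mode = "balanced", window = NULL,
                         register = TRUE, delta_bin = 1 / 3) {
  spec <- protocol_spec(method, t = t, f = f, m = length(psf_models))
  models <- if (spec$n_psf == 1L) psf_models[1] else psf_models
  fs <- simulate_acquisition(pattern, models, f = f, shifts = spec$shifts,
                             t_per_frame = spec$t_per_frame, seed = seed,
                             protocol = spec$method)
  if (is.null(window)) window <- default_ring_window(pattern)
  ctr_hr <- pattern$center
  switch(spec$method,
    plain = {
      fr <- fs$frames[[1]]
      img <- fr$counts / (fr$exposure * f^2)
      prof <- azimuthal_integrate(img, center = lr_center(ctr_hr, f),
                                  bin_width = delta_bin / f,
                                  radius_scale = f)
      image <- img
    },
    SPS = {
      est <- if (register) estimate_shifts(fs) else NULL
      fus <- fuse_sps(fs, shifts = est)
      img <- fus$intensity / (spec$t_per_frame *
                                psf_models[[1]]$flux_scale)
      prof <- azimuthal_integrate(img, center = ctr_hr,
                                  bin_width = delta_bin)
      image <- img
    },
    CMD = {
      res <- cmd_retrieve(fs, nu = nu, weight_mode = weight_mode)
      img <- pmax(res$xhat, 0) / f^2
      prof <- azimuthal_integrate(img, center = lr_center(ctr_hr, f),
                                  bin_width = delta_bin / f,
                                  radius_scale = f)
      image <- img
    },
    SrSAXS = {
      res <- srsaxs_retrieve(fs, nu = nu, weight_mode = weight_mode,
                             register = register)
      img <- pmax(res$xhat, 0)
      prof <- azimuthal_integrate(img, center = ctr_hr,
                                  bin_width = delta_bin)
      image <- img
    })
  prof <- profile_normalize(prof, window = window)
  delta <- separation_delta(prof, window = window)
  list(delta = delta, profile = prof, image = image, method = spec$method,
       spec = spec)
}

default_ring_window <- function(pattern) {
  r <- pattern$rings$radius
  if (length(r) < 2) return(NULL)
  r <- sort(r)
  pad <- max(2, diff(range(r)))
  c(max(pattern$beamstop_radius + 1, min(r) - pad), max(r) + pad)
}

# beam center of the decimated grid corresponding to a high-res center
lr_center <- function(center_hr, f) (center_hr - 0.5) / f + 0.5

#' Equal-exposure comparison of the four retrieval protocols
#'
#' For every cell of a (smallest PSF size) x (base exposure) grid, runs each
#' protocol with identical total exposure time over paired seeds, scores the
#' doublet separation delta, and reports per-cell means, standard deviations
#' and the winning method (ties reported, not hidden).
#'
#' @param pattern ground-truth [saxs_pattern()].
#' @param s_values smallest square slit sizes (l/f pixels).
#' @param t_values base exposure units.
#' @param methods protocols to compare.
#' @param f,m enhancement factor and PSF count.
#' @param seeds integer seeds (each seed paired across methods of a cell).
#' @param nu,weight_mode,window as in [run_protocol()].
#' @param sigma_source Gaussian source sigma of the PSF sets.
#' @return object of class `comparison_report`: `results` (long
#'   data.frame) and `winners` (one row per cell).
#' @export
compare_protocols <- function(pattern, s_values, t_values,
                              methods = c("plain", "SPS", "CMD", "SrSAXS"),
                              f = 3L, m = 6L, seeds = 1:5, nu = 0.1,
                              weight_mode = "balanced", window = NULL,
                              sigma_source = 1) {
  rows <- list()
  for (s in s_values) {
    psfs <- default_psf_set(s, sigma = sigma_source)[seq_len(m)]
    for (t in t_values) {
      for (method in methods) {
        deltas <- vapply(seeds, function(sd) {
          out <- tryCatch(
            run_protocol(pattern, method, t = t, f = f, psf_models = psfs,
                         seed = sd, nu = nu, weight_mode = weight_mode,
                         window = window)$delta$delta,
            error = function(e) {
              message(sprintf("cell (s=%g, t=%g, %s, seed %d) failed: %s",
                              s, t, method, sd, conditionMessage(e)))
              0
            })
          out
        }, numeric(1))
        rows[[length(rows) + 1L]] <-
          data.frame(s = s, t = t, method = method,
                     delta_mean = mean(deltas),
                     delta_sd = if (length(seeds) > 1) stats::sd(deltas) else 0,
                     n_seeds = length(seeds))
      }
    }
  }
  results <- do.call(rbind, rows)
  winners <- do.call(rbind, lapply(split(results,
                                         interaction(results$s, results$t,
                                                     drop = TRUE)),
    function(df) {
      best <- df$delta_mean == max(df$delta_mean)
      data.frame(s = df$s[1], t = df$t[1],
                 winner = paste(df$method[best], collapse = "/"),
                 best_delta = max(df$delta_mean))
    }))
  rownames(winners) <- NULL
  structure(list(results = results, winners = winners, seeds = seeds),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Equal-exposure protocol comparison (winner = largest mean delta):\n")
  print(x$winners)
  invisible(x)
}
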