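test_that("pixel-to-q mapping follows the scattering geometry", {
  geom <- instrument_geometry(d_s = 117, wavelength = 1.54, pixel_size = 172,
                              f = 1)
  expect_equal(pixel_to_q(0, geom), 0)

  # delta_r = d_s gives 2 theta = 45 degrees
  g45 <- instrument_geometry(d_s = 100, wavelength = 2, pixel_size = 1e5,
                             f = 1)
  expect_equal(pixel_to_q(1, g45), 4 * pi * sin(pi / 8) / 2)

  # independent hand evaluation of the two formulas at one detector pixel
  q1 <- (4 * pi / 1.54) * sin(0.5 * atan(0.172 / 117))
  expect_equal(pixel_to_q(1, geom), q1, tolerance = 1e-12)

  # strictly increasing, and f rescales radii exactly
  r <- seq(0, 400, by = 7)
  expect_true(all(diff(pixel_to_q(r, geom)) > 0))
  g3 <- instrument_geometry(d_s = 117, wavelength = 1.54, pixel_size = 172,
                            f = 3)
  expect_equal(pixel_to_q(r, g3), pixel_to_q(r / 3, geom))
  expect_error(instrument_geometry(d_s = -1), "positive")
})

test_that("azimuthal integration averages annuli of valid pixels", {
  const <- matrix(7, 61, 61)
  prof <- azimuthal_integrate(const)
  expect_true(all(prof$intensity == 7))
  expect_true(all(prof$spread == 0))
  expect_true(all(diff(prof$radius_px) > 0))

  pat <- two_ring_pattern(radii = c(30, 40), widths = 1, amplitudes = c(1, 1),
                          background = 0, beamstop = 0, grid = 95)
  img <- render_ground_truth(pat)
  p1 <- azimuthal_integrate(img, center = pat$center)
  expect_equal(p1$radius_px[which.max(p1$intensity)], 30, tolerance = 0.51)

  # linearity in the image intensity
  p2 <- azimuthal_integrate(3 * img, center = pat$center)
  expect_equal(p2$intensity, 3 * p1$intensity)
  expect_equal(p2$spread, 3 * p1$spread)

  # masking one quadrant of an isotropic image leaves the means unchanged
  # within the annulus spread
  mask <- matrix(TRUE, 95, 95); mask[1:47, 1:47] <- FALSE
  p3 <- azimuthal_integrate(img, center = pat$center, mask = mask)
  shared <- intersect(p1$radius_px, p3$radius_px)
  i1 <- match(shared, p1$radius_px); i3 <- match(shared, p3$radius_px)
  tol <- 4 * p1$spread[i1] / sqrt(pmax(p3$n_pixels[i3], 1)) + 1e-12
  expect_true(all(abs(p1$intensity[i1] - p3$intensity[i3]) <= tol))

  expect_error(azimuthal_integrate(img, mask = matrix(FALSE, 95, 95)),
               "masked")
  expect_error(azimuthal_integrate(img, center = c(-5, 2)), "center")
})

test_that("q column appears when instrument geometry is supplied", {
  geom <- instrument_geometry(f = 3)
  prof <- azimuthal_integrate(matrix(1, 31, 31), geom = geom)
  expect_true("q" %in% names(prof))
  expect_equal(prof$q, pixel_to_q(prof$radius_px, geom))
})

test_that("separation criterion scores doublets per its definition", {
  # synthetic doublet: lower peak 0.6, valley 0.2 at distance 4
  x <- seq(10, 34, by = 1)
  y <- rep(0.05, length(x))
  y[x == 18] <- 1.0
  y[x > 18 & x < 26] <- 0.35
  y[x == 22] <- 0.2
  y[x == 26] <- 0.6
  prof <- data.frame(radius_px = x, intensity = y, spread = 0,
                     n_pixels = 100L)
  class(prof) <- c("radial_profile", "data.frame")
  d <- separation_delta(prof)
  expect_equal(d$delta, (0.6 - 0.2) / 4)
  expect_equal(d$I_p, 0.6)
  expect_equal(d$I_v, 0.2)
  expect_equal(d$peaks, c(18, 26))
  # alternative referent: peak-to-peak distance
  d2 <- separation_delta(prof, peak_to_peak = TRUE)
  expect_equal(d2$delta, (0.6 - 0.2) / 8)

  # merged single peak: no distinction of close peaks
  ym <- dnorm(x, 22, 3)
  pm <- data.frame(radius_px = x, intensity = ym, spread = 0,
                   n_pixels = 100L)
  class(pm) <- c("radial_profile", "data.frame")
  expect_equal(separation_delta(pm)$delta, 0)

  expect_error(separation_delta(prof, window = c(100, 200)), "window")
})

test_that("noise-scaled prominence suppresses spurious doublets", {
  x <- seq(1, 40)
  set.seed(4)
  y <- dnorm(x, 20, 4) + rnorm(40, 0, 0.002)
  prof <- data.frame(radius_px = x, intensity = y,
                     spread = rep(0.02, 40), n_pixels = rep(100L, 40))
  class(prof) <- c("radial_profile", "data.frame")
  # wiggles of ~0.002 are below 3x the standard error 0.02/sqrt(100)
  expect_equal(separation_delta(prof)$delta, 0)
  # but are picked up when the threshold is disabled
  expect_gt(length(srsaxs:::local_peaks(y)), 1)
})

test_that("separation matches a dense brute-force search on analytic curves", {
  pat <- two_ring_pattern(grid = 95)
  x <- seq(24, 42, by = 0.005)
  prof <- data.frame(radius_px = x, intensity = analytic_profile(pat, x),
                     spread = 0, n_pixels = 1L)
  class(prof) <- c("radial_profile", "data.frame")
  d <- separation_delta(prof, window = c(24, 42))
  expect_equal(d$delta, brute_force_delta(pat, 24, 42), tolerance = 1e-9)
  d2 <- separation_delta(prof, window = c(24, 42), peak_to_peak = TRUE)
  expect_equal(d2$delta, brute_force_delta(pat, 24, 42, peak_to_peak = TRUE),
               tolerance = 1e-9)
})

test_that("delta scales linearly with profile intensity", {
  pat <- two_ring_pattern(grid = 95)
  x <- seq(24, 42, by = 0.01)
  mk <- function(c) {
    p <- data.frame(radius_px = x, intensity = c * analytic_profile(pat, x),
                    spread = 0, n_pixels = 1L)
    class(p) <- c("radial_profile", "data.frame")
    p
  }
  d1 <- separation_delta(mk(1))$delta
  d5 <- separation_delta(mk(5))$delta
  expect_equal(d5, 5 * d1, tolerance = 1e-12)
})

test_that("repeat-based uncertainty behaves at its degenerate limits", {
  expect_equal(delta_uncertainty(function(s) 0.5, n_repeats = 5)$sd, 0)
  expect_warning(out <- delta_uncertainty(function(s) 0.5, n_repeats = 1),
                 "repeats")
  expect_equal(out$sd, 0)
  # failing repeats contribute zero, not an exception
  res <- delta_uncertainty(function(s) if (s %% 2 == 0) stop("boom") else 1,
                           n_repeats = 10, seed = 2)
  expect_true(all(res$deltas %in% c(0, 1)))
})

test_that("repeat mean is consistent with a larger-repeat oracle", {
  pat <- two_ring_pattern(radii = c(10, 13), widths = 0.8,
                          amplitudes = c(1, 0.7), background = 0.5,
                          beamstop = 2, grid = 43)
  gt <- render_ground_truth(pat)
  experiment <- function(seed) {
    fr <- sample_frame(gt, c(0, 0), f = 1, t = 5, seed = seed)
    prof <- azimuthal_integrate(fr$counts / 5, center = pat$center,
                                bin_width = 1 / 2)
    separation_delta(prof, window = c(6, 18))
  }
  small <- delta_uncertainty(experiment, n_repeats = 40, seed = 7)
  big <- delta_uncertainty(experiment, n_repeats = 400, seed = 8)
  expect_gt(small$sd, 0)
  expect_lt(abs(small$mean - big$mean),
            3 * small$sd / sqrt(40) + 3 * big$sd / sqrt(400))
})

test_that("retrieval error is the Frobenius distance with stated alignment", {
  set.seed(21)
  gt <- matrix(runif(16), 4, 4)
  expect_equal(retrieval_error(gt, gt), 0)
  pert <- gt; pert[2, 3] <- pert[2, 3] + 1
  expect_equal(retrieval_error(pert, gt, normalize = FALSE), 1)
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_equal(retrieval_error(a, b, normalize = FALSE),
               sqrt(sum((a - b)^2)))
  # normalization makes flux scales comparable
  expect_equal(retrieval_error(2 * a, b), retrieval_error(a, b))
  # finer ground truth is box-summed to the retrieval grid
  hr <- matrix(runif(64), 8, 8)
  expect_equal(retrieval_error(box_sum(hr, 2), hr, normalize = FALSE), 0)
  expect_error(retrieval_error(matrix(0, 3, 3), matrix(0, 5, 5)), "shape")
})
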