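test_that("ground-truth rendering follows the ring + background closed form", {
  # single Lorentzian ring peaks at its own amplitude on the ring
  p1 <- saxs_pattern(data.frame(radius = 30, width = 0.7, amplitude = 1),
                     center = c(51, 51), grid_shape = c(101, 101))
  img <- render_ground_truth(p1)
  expect_equal(img[51, 81], 1.0)   # pixel exactly at rho = 30

  # background + beamstop: direct evaluation of the stated closed form
  p2 <- saxs_pattern(data.frame(radius = 30, width = 0.7, amplitude = 1),
                     background_coeff = 1, beamstop_radius = 5,
                     center = c(51, 51), grid_shape = c(101, 101))
  img2 <- render_ground_truth(p2)
  rho <- 10
  expected <- 1 * 0.7^2 / ((rho - 30)^2 + 0.7^2) + 1 / rho
  expect_equal(img2[51, 61], expected)
  expect_equal(img2[51, 53], 0)    # rho = 2 under the beamstop
  expect_true(all(is.finite(img2)) && all(img2 >= 0))
})

test_that("degenerate patterns are rejected or flagged", {
  expect_error(saxs_pattern(data.frame(radius = -1, width = 1, amplitude = 1)),
               "positive")
  expect_error(saxs_pattern(data.frame(radius = 1, width = 1, amplitude = 1),
                            grid_shape = c(0, 0)), "grid_shape")
  p <- saxs_pattern(data.frame(radius = 500, width = 1, amplitude = 1),
                    grid_shape = c(51, 51))
  expect_warning(render_ground_truth(p), "truncated")
})

test_that("two-ring pattern shows radial maxima near both ring radii", {
  pat <- two_ring_pattern(grid = 95)
  prof <- azimuthal_integrate(render_ground_truth(pat), center = pat$center)
  w <- prof$radius_px >= 26 & prof$radius_px <= 38
  y <- prof$intensity[w]; x <- prof$radius_px[w]
  pk <- x[which(diff(sign(diff(y))) < 0) + 1]
  expect_length(pk, 2)
  expect_lt(abs(pk[1] - 30), 1)
  expect_lt(abs(pk[2] - 34), 1)
})

test_that("PSF rasterization matches its analytic limits", {
  # zero slit width: pixel-integrated Gaussian (pnorm cell masses)
  k <- render_psf(psf_model(0, 0, sigma = 1.5), 13)
  u <- (-6):6
  kg <- pnorm((u + 0.5) / 1.5) - pnorm((u - 0.5) / 1.5)
  expect_equal(k, outer(kg, kg) / sum(outer(kg, kg)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # zero source width: exact fractional pixel coverage of the slit
  kr <- render_psf(psf_model(4, 4, sigma = 0), 9)
  cov <- c(0, 0, 0.5, 1, 1, 1, 0.5, 0, 0) / 4
  expect_equal(kr, outer(cov, cov), tolerance = 1e-12, ignore_attr = TRUE)

  # degenerate delta
  kd <- render_psf(psf_model(0, 0, sigma = 0), 3)
  expect_equal(kd[2, 2], 1)
  expect_equal(sum(kd), 1)
})

test_that("PSF kernel equals brute-force rectangle x Gaussian convolution", {
  # fine-grid numerical convolution of a sampled rectangle and Gaussian,
  # aggregated to pixel masses: independent of the closed-form path
  brute_axis <- function(w, s, h, step = 1 / 400) {
    lim <- h + 0.5 + 6 * s + w
    x <- seq(-lim, lim, by = step)
    rect <- as.numeric(abs(x) < w / 2) + 0.5 * (abs(x) == w / 2)
    gauss <- dnorm(x, 0, s)
    conv <- convolve(rect, rev(gauss), type = "open") * step^2
    xc <- 2 * min(x) + (seq_along(conv) - 1) * step
    vapply((-h):h, function(u) {
      inside <- abs(xc - u) < 0.5
      edge <- abs(abs(xc - u) - 0.5) < step / 4
      sum(conv[inside]) + 0.5 * sum(conv[edge])
    }, numeric(1))
  }
  for (case in list(c(4, 1), c(2, 0.5), c(1, 1.5), c(0.5, 0.8))) {
    w <- case[1]; s <- case[2]
    h <- ceiling(w / 2 + 5 * s) + 1
    ka <- srsaxs:::psf_axis_mass((-h):h, w, s)
    kb <- brute_axis(w, s, h)
    ka <- ka / sum(ka); kb <- kb / sum(kb)
    expect_lt(max(abs(ka - kb)), 1e-6)
  }
})

test_that("undersized PSF support is rejected with the deficit named", {
  expect_error(render_psf(psf_model(10, 10, sigma = 2), 5), "support")
})

test_that("blur is a linear, flux-scaled convolution", {
  pat <- two_ring_pattern(grid = 95)
  gt <- render_ground_truth(pat)
  dk <- matrix(0, 3, 3); dk[2, 2] <- 1
  expect_equal(blur(gt, dk), gt, tolerance = 1e-12)

  k2 <- render_psf(psf_model(3, 3, sigma = 1, flux_scale = 2))
  const <- matrix(5, 40, 40)
  expect_equal(blur(const, k2), matrix(10, 40, 40), tolerance = 1e-9)

  set.seed(11)
  a <- matrix(runif(40 * 40), 40, 40)
  b <- matrix(runif(40 * 40), 40, 40)
  k <- render_psf(psf_model(2, 2, sigma = 0.8))
  expect_equal(blur(2 * a + 3 * b, k), 2 * blur(a, k) + 3 * blur(b, k),
               tolerance = 1e-10)
  expect_error(blur(matrix(c(1, NA, 1, 1), 2), dk), "NaN")

  # smearing is monotone: the blurred doublet valley is shallower
  prof0 <- azimuthal_integrate(gt, center = pat$center)
  prof1 <- azimuthal_integrate(blur(gt, render_psf(psf_model(4, 4, sigma = 1))),
                               center = pat$center)
  vr <- function(p) {
    w <- p$radius_px >= 28 & p$radius_px <= 36
    (max(p$intensity[w]) - min(p$intensity[p$radius_px >= 31 &
                                             p$radius_px <= 33])) /
      max(p$intensity[w])
  }
  expect_lt(vr(prof1), vr(prof0))
})

test_that("detector sampling is Poisson with the box-summed mean", {
  hr <- matrix(2, 90, 90)
  # (90 - (f-1)) %/% f = 29 low-res pixels so every shift keeps the shape
  expect_equal(sample_frame(hr, c(0, 0), f = 3, t = 0)$counts,
               matrix(0L, 29, 29), ignore_attr = TRUE)
  f1 <- sample_frame(hr, c(1, 2), f = 3, t = 2, seed = 42)
  f2 <- sample_frame(hr, c(1, 2), f = 3, t = 2, seed = 42)
  expect_identical(f1$counts, f2$counts)
  expect_error(sample_frame(hr, c(3, 0), f = 3, t = 1), "shift")

  # constant image c = 2, f = 3, t = 2: Poisson mean 18c = 36 per pixel
  big <- sample_frame(matrix(2, 330, 330), c(0, 0), f = 3, t = 2, seed = 9)
  n <- length(big$counts)
  se <- sqrt(36 / n)
  expect_lt(abs(mean(big$counts) - 36), 4 * se)
})

test_that("expected frame totals conserve photons", {
  pat <- two_ring_pattern(grid = 93)
  gt <- render_ground_truth(pat)
  model <- psf_model(2, 2, sigma = 1, flux_scale = 1.5)
  b <- blur(gt, model)
  t <- 3
  sums <- vapply(child_seeds(5, 25), function(s)
    sum(sample_frame(b, c(0, 0), f = 3, t = t, seed = s)$counts), numeric(1))
  # the frame covers the first 30*3 = 90 high-res rows/cols at shift (0,0)
  lam <- t * sum(b[seq_len(90), seq_len(90)])
  expect_lt(abs(mean(sums) - lam), 4 * sqrt(lam / 25))
  # flux scale raises the expected total by 1.5 over the unscaled blur
  expect_equal(sum(b) / sum(gt), 1.5, tolerance = 1e-3)
})

test_that("long exposures converge to the ground truth pointwise", {
  pat <- two_ring_pattern(grid = 63, beamstop = 3, radii = c(15, 19))
  gt <- render_ground_truth(pat)
  sel <- gt > 0.1
  rel_err <- vapply(c(1, 100, 1e4), function(t) {
    fr <- sample_frame(gt, c(0, 0), f = 1, t = t, seed = 3)
    mean(abs(fr$counts[sel] / t - gt[sel]) / gt[sel])
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 0.02)
})

test_that("acquisition simulation assembles the protocol frame sets", {
  pat <- two_ring_pattern(grid = 63, radii = c(15, 19), beamstop = 3)
  psfs <- default_psf_set(1, sigma = 0.4)
  fs <- simulate_acquisition(pat, psfs, f = 3, shifts = shift_grid(3),
                             t_per_frame = 1, seed = 1)
  expect_length(fs$frames, 54)
  expect_equal(fs$m, 6)
  expect_equal(fs$protocol, "SrSAXS")

  fs2 <- simulate_acquisition(pat, psfs, f = 3, shifts = list(c(0L, 0L)),
                              t_per_frame = 9, seed = 1)
  expect_length(fs2$frames, 6)
  expect_equal(fs2$protocol, "CMD")

  fs3 <- simulate_acquisition(pat, psfs[1], f = 3, shifts = list(c(0L, 0L)),
                              t_per_frame = 1, seed = 1)
  expect_equal(fs3$protocol, "plain")
  expect_error(simulate_acquisition(pat, list(), f = 3,
                                    shifts = shift_grid(3), t_per_frame = 1),
               "at least one")
})

test_that("default PSF set couples flux to slit area", {
  psfs <- default_psf_set(2, sigma = 1)
  expect_length(psfs, 6)
  areas <- vapply(psfs, function(m) m$width_x * m$width_y, numeric(1))
  flux <- vapply(psfs, function(m) m$flux_scale, numeric(1))
  expect_equal(flux, areas / areas[1])
  expect_equal(flux[1], 1)
  ids <- vapply(psfs, function(m) m$id, character(1))
  expect_length(unique(ids), 6)
})
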