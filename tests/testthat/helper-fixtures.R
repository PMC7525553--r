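# shared fixtures, all generated in code

# the two-ring doublet used throughout the resolution studies
two_ring_pattern <- function(radii = c(30, 34), widths = 0.9,
                             amplitudes = c(1, 0.6), background = 1,
                             beamstop = 5, grid = 95L) {
  saxs_pattern(data.frame(radius = radii, width = widths,
                          amplitude = amplitudes),
               background_coeff = background, beamstop_radius = beamstop,
               grid_shape = c(grid, grid))
}

# exact decimation of a high-res image at the fuse_sps placement convention
decimate <- function(hr, f, off) {
  c0 <- (f - 1L) %/% 2L
  d <- dim(hr) %/% f
  hr[off[1] + c0 + seq(1L, by = f, length.out = d[1]),
     off[2] + c0 + seq(1L, by = f, length.out = d[2])]
}

# wrap plain matrices as a one-PSF frame set
as_frame_set <- function(mats, f, offs, psf = psf_model(1, 1, 0, id = "p")) {
  frames <- lapply(seq_along(mats), function(i)
    structure(list(counts = mats[[i]], exposure = 1, shift = offs[[i]],
                   f = f, psf_id = "p",
                   mask = matrix(TRUE, nrow(mats[[i]]), ncol(mats[[i]])),
                   seed = i),
              class = "detector_frame"))
  frame_set(frames, f = f, psf_models = list(psf))
}

# dense circulant operator for one kernel under periodic convolution
dense_circulant <- function(k, n) {
  A <- matrix(0, n * n, n * n)
  e <- matrix(0, n, n)
  for (j in seq_len(n * n)) {
    e[j] <- 1
    A[, j] <- as.vector(conv2(e, k, boundary = "circular"))
    e[j] <- 0
  }
  A
}

# dense analytic doublet separation by exhaustive grid search, independent
# of the package's peak finder
brute_force_delta <- function(pattern, lo, hi, step = 0.005,
                              peak_to_peak = FALSE) {
  x <- seq(lo, hi, by = step)
  y <- analytic_profile(pattern, x)
  n <- length(y)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (length(peaks) < 2) return(0)
  top <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  top <- sort(top)
  seg <- top[1]:top[2]
  vi <- seg[which.min(y[seg])]
  if (vi %in% top) return(0)
  lower <- top[which.min(y[top])]
  dq <- if (peak_to_peak) abs(x[top[2]] - x[top[1]]) else abs(x[lower] - x[vi])
  (y[lower] - y[vi]) / dq
}
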