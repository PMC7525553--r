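#' Estimate inter-frame translations by Lucas-Kanade registration
#'
#' Translation-only Lucas-Kanade with Gauss-Newton refinement on a 2-level
#' pyramid. Frames are registered within one PSF group against a reference
#' frame, on `log(1 + counts)` images (compressing the ring dynamic range so
#' gradients are not dominated by the beamstop region) after light Gaussian
#' smoothing.
#'
#' The estimated shift `(dy, dx)` of frame j is defined so that
#' `frame_j(x) = frame_ref(x + v)`, in low-resolution pixel units: a frame
#' acquired at subpixel stage offset `d` (in l/f units) has `v = d / f`
#' relative to the reference.
#'
#' @param frames a [frame_set()] or list of count matrices.
#' @param reference index of the reference frame (default 1).
#' @param init optional n x 2 matrix of initial `(dy, dx)` guesses in
#'   low-resolution pixels; for simulated frames the nominal shifts are used
#'   when available.
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @param smooth_sigma pre-smoothing Gaussian sigma in pixels.
#' @param pyramid number of pyramid levels (default 2).
#' @return data.frame with columns `frame`, `dy`, `dx`, `residual`,
#'   `converged`; the reference row has shift (0, 0).
#' @export
estimate_shifts <- function(frames, reference = 1L, init = NULL,
                            max_iter = 50L, tol = 1e-4, smooth_sigma = 1,
                            pyramid = 2L) {
  fs <- NULL
  if (inherits(frames, "frame_set")) {
    fs <- frames
    frames <- lapply(fs$frames, function(fr) fr$counts)
  }
  if (length(frames) < 1) stop("need at least one frame")
  n <- length(frames)
  if (is.null(init)) {
    init <- matrix(0, n, 2)
    if (!is.null(fs)) {
      sh <- t(vapply(fs$frames, function(fr) fr$shift, numeric(2)))
      init <- sweep(sh, 2, sh[reference, ]) / fs$f
    }
  }
  sm <- gaussian_kernel(smooth_sigma)
  prep <- lapply(frames, function(m) {
    m <- log1p(m)
    m <- m / max(mean(m), .Machine$double.eps)
    conv2(m, sm)
  })
  ref <- prep[[reference]]
  out <- data.frame(frame = seq_len(n), dy = 0, dx = 0, residual = 0,
                    converged = TRUE)
  for (j in seq_len(n)) {
    if (j == reference) next
    est <- lk_translation(ref, prep[[j]], init = init[j, ],
                          max_iter = max_iter, tol = tol, pyramid = pyramid)
    if (!est$converged) {
      # fall back to the nominal shift for this frame
      message(sprintf("frame %d: registration did not converge; using nominal shift",
                      j))
      est$v <- init[j, ]
    }
    out$dy[j] <- est$v[1]
    out$dx[j] <- est$v[2]
    out$residual[j] <- est$residual
    out$converged[j] <- est$converged
  }
  attr(out, "reference") <- reference
  out
}

# translation-only Lucas-Kanade, Gauss-Newton on the reference gradients;
# v solves  mov(x) ~ ref(x + v)
lk_translation <- function(ref, mov, init = c(0, 0), max_iter = 50L,
                           tol = 1e-4, pyramid = 2L) {
  v <- init
  if (pyramid > 1L && all(dim(ref) >= 32L)) {
    est <- lk_translation(halve(ref), halve(mov), init = init / 2,
                          max_iter = max_iter, tol = tol,
                          pyramid = pyramid - 1L)
    v <- est$v * 2
  }
  d <- dim(ref)
  m <- max(3L, ceiling(max(abs(v)) + 2))
  ri <- seq(m + 1L, d[1] - m)
  ci <- seq(m + 1L, d[2] - m)
  if (length(ri) < 4 || length(ci) < 4)
    return(list(v = v, residual = Inf, converged = FALSE))
  gy <- (rbind(ref[-1, ], ref[d[1], ]) - rbind(ref[1, ], ref[-d[1], ])) / 2
  gx <- (cbind(ref[, -1], ref[, d[2]]) - cbind(ref[, 1], ref[, -d[2]])) / 2
  converged <- FALSE
  res <- Inf
  for (it in seq_len(max_iter)) {
    rw <- bilinear_shift(ref, v[1], v[2])[ri, ci]
    jy <- bilinear_shift(gy, v[1], v[2])[ri, ci]
    jx <- bilinear_shift(gx, v[1], v[2])[ri, ci]
    e <- mov[ri, ci] - rw
    res <- sqrt(mean(e^2))
    a11 <- sum(jy * jy); a12 <- sum(jy * jx); a22 <- sum(jx * jx)
    b1 <- sum(jy * e); b2 <- sum(jx * e)
    det <- a11 * a22 - a12^2
    if (!is.finite(det) || det <= .Machine$double.eps * a11 * a22)
      return(list(v = v, residual = res, converged = FALSE))
    dv <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det
    v <- v + dv
    if (sqrt(sum(dv^2)) < tol) { converged <- TRUE; break }
  }
  list(v = v, residual = res, converged = converged)
}

halve <- function(x) {
  d <- dim(x) %/% 2L * 2L
  box_sum(x[seq_len(d[1]), seq_len(d[2]), drop = FALSE], 2L) / 4
}

#' Fuse subpixel-shifted frames into a high-resolution image
#'
#' Robust interlacing (median shift-and-add): each low-resolution pixel is
#' placed onto the l/f lattice at its estimated shift rounded to the nearest
#' 1/f, coincident samples are combined by median (robust to hot pixels and
#' cosmic counts), and unfilled lattice cells are interpolated from filled
#' neighbors and flagged. No deconvolution happens here: deblurring belongs
#' to the CMD stage (or to the full Farsiu baseline).
#'
#' @param frames a [frame_set()] (one PSF group) or list of count matrices.
#' @param shifts data.frame from [estimate_shifts()] (low-res pixel units),
#'   or `NULL` to use the frames' nominal shifts.
#' @param f integer enhancement factor; taken from the frame set if `NULL`.
#' @return object of class `high_res_image`: `intensity` (flux-normalized to
#'   the mean per-frame flux), `fill_map`, `offsets`, `f`.
#' @export
fuse_sps <- function(frames, shifts = NULL, f = NULL) {
  fs <- NULL
  if (inherits(frames, "frame_set")) {
    fs <- frames
    f <- f %||% fs$f
    mats <- lapply(fs$frames, function(fr) fr$counts)
  } else mats <- frames
  f <- as.integer(f)
  n <- length(mats)
  d <- dim(mats[[1]])
  # absolute lattice offsets in high-res pixels: anchor at the reference
  # frame's nominal offset (if known) plus estimated relative shifts
  if (is.null(shifts)) {
    offs <- if (!is.null(fs))
      t(vapply(fs$frames, function(fr) as.numeric(fr$shift), numeric(2)))
    else matrix(0, n, 2)
  } else {
    refi <- attr(shifts, "reference") %||% 1L
    anchor <- if (!is.null(fs)) as.numeric(fs$frames[[refi]]$shift) else c(0, 0)
    offs <- cbind(anchor[1] + shifts$dy * f, anchor[2] + shifts$dx * f)
  }
  offs <- round(offs)
  storage.mode(offs) <- "integer"
  if (n > 1 && nrow(unique(offs)) == 1)
    warning("all frames land on one sub-grid position; degenerate fusion")
  out_d <- d * f
  # each low-res value estimates the mean of its f x f footprint, so it is
  # placed at the footprint's central cell (for odd f; the residual footprint
  # smear is part of the effective PSF, see effective_hr_psf)
  c0 <- (f - 1L) %/% 2L
  distinct <- nrow(unique(offs)) == n
  if (distinct) {
    acc <- matrix(NA_real_, out_d[1], out_d[2])
    for (k in seq_len(n)) {
      rr <- offs[k, 1] + c0 + seq(1L, by = f, length.out = d[1])
      cc <- offs[k, 2] + c0 + seq(1L, by = f, length.out = d[2])
      ok_r <- rr >= 1L & rr <= out_d[1]
      ok_c <- cc >= 1L & cc <= out_d[2]
      acc[rr[ok_r], cc[ok_c]] <- mats[[k]][ok_r, ok_c]
    }
  } else {
    stack <- array(NA_real_, c(out_d[1], out_d[2], n))
    for (k in seq_len(n)) {
      rr <- offs[k, 1] + c0 + seq(1L, by = f, length.out = d[1])
      cc <- offs[k, 2] + c0 + seq(1L, by = f, length.out = d[2])
      ok_r <- rr >= 1L & rr <= out_d[1]
      ok_c <- cc >= 1L & cc <= out_d[2]
      sl <- matrix(NA_real_, out_d[1], out_d[2])
      sl[rr[ok_r], cc[ok_c]] <- mats[[k]][ok_r, ok_c]
      stack[, , k] <- sl
    }
    acc <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
    acc[is.nan(acc)] <- NA_real_
  }
  fill_map <- !is.na(acc)
  # neighbor-mean infill of unsampled lattice cells
  guard <- 0L
  while (anyNA(acc) && guard < 2L * f) {
    guard <- guard + 1L
    filled <- acc
    filled[is.na(filled)] <- 0
    cnt <- conv2(matrix(as.numeric(!is.na(acc)), out_d[1], out_d[2]),
                 matrix(1, 3, 3), boundary = "reflect")
    sm <- conv2(filled, matrix(1, 3, 3), boundary = "reflect")
    est <- sm / pmax(cnt, .Machine$double.eps)
    acc[is.na(acc) & cnt > 0.5] <- est[is.na(acc) & cnt > 0.5]
  }
  if (anyNA(acc)) acc[is.na(acc)] <- 0
  target <- mean(vapply(mats, sum, numeric(1)))
  s <- sum(acc)
  if (s > 0) acc <- acc * (target / s)
  structure(list(intensity = acc, f = f, fill_map = fill_map,
                 offsets = offs,
                 provenance = list(n_frames = n, frame_dim = d)),
            class = "high_res_image")
}

#' @export
print.high_res_image <- function(x, ...) {
  cat(sprintf("high-res image %dx%d (f=%d, %d frame(s), %.1f%% cells sampled)\n",
              nrow(x$intensity), ncol(x$intensity), x$f,
              x$provenance$n_frames, 100 * mean(x$fill_map)))
  invisible(x)
}
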