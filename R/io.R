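#' Write a frame set to a directory of TIFFs with JSON sidecars
#'
#' One 32-bit float TIFF per frame (counts divided by the recorded `scale`
#' so values fit the TIFF unit range losslessly) plus a JSON sidecar with
#' exposure, subpixel shift, enhancement factor, PSF id, seed and scale;
#' masks are written as 8-bit TIFFs (0 invalid / 1 valid).
#'
#' @param frameset a [frame_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frameset <- function(frameset, dir) {
  stopifnot(inherits(frameset, "frame_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(f = frameset$f, protocol = frameset$protocol,
               n_frames = length(frameset$frames),
               psf_models = lapply(frameset$psf_models, unclass))
  jsonlite::write_json(meta, file.path(dir, "frameset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(frameset$frames)) {
    fr <- frameset$frames[[i]]
    scale <- max(1, max(fr$counts))
    base <- sprintf("frame_%03d", i)
    tiff::writeTIFF(fr$counts / scale, file.path(dir, paste0(base, ".tif")),
                    bits.per.sample = 32)
    tiff::writeTIFF(matrix(as.numeric(fr$mask), nrow(fr$mask)),
                    file.path(dir, paste0(base, "_mask.tif")),
                    bits.per.sample = 8)
    side <- list(t = fr$exposure, dy = fr$shift[1], dx = fr$shift[2],
                 f = fr$f, psf_id = fr$psf_id, seed = fr$seed,
                 scale = scale, pixel_size = fr$pixel_size)
    jsonlite::write_json(side, file.path(dir, paste0(base, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a frame set written by [write_frameset()]
#'
#' @param dir directory containing `frame_*.tif` and sidecars.
#' @return a [frame_set()].
#' @export
read_frameset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frameset.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.tif$",
                           full.names = TRUE))
  frames <- lapply(files, function(fp) {
    side <- jsonlite::read_json(sub("\\.tif$", ".json", fp),
                                simplifyVector = TRUE)
    counts <- round(tiff::readTIFF(fp) * side$scale)
    maskf <- sub("\\.tif$", "_mask.tif", fp)
    mask <- if (file.exists(maskf)) tiff::readTIFF(maskf) > 0.5
            else matrix(TRUE, nrow(counts), ncol(counts))
    structure(list(counts = counts, exposure = side$t,
                   shift = c(side$dy, side$dx), f = side$f,
                   psf_id = side$psf_id, pixel_size = side$pixel_size,
                   mask = mask, seed = side$seed),
              class = "detector_frame")
  })
  fields <- c("width_x", "width_y", "sigma", "pitch", "flux_scale", "id")
  pm <- meta$psf_models
  models <- if (is.data.frame(pm))
    lapply(seq_len(nrow(pm)), function(i) do.call(psf_model,
                                                  as.list(pm[i, fields])))
  else lapply(pm, function(m) do.call(psf_model, m[fields]))
  frame_set(frames, f = meta$f, psf_models = models,
            protocol = meta$protocol)
}

#' Write a radial profile as CSV
#'
#' Columns: `radius_px`, `q` (if present), `intensity`, `spread`,
#' `n_pixels`.
#'
#' @param profile a `radial_profile`.
#' @param path output CSV path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
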