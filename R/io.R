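#' Write a kymograph to TIFF with a JSON calibration sidecar
#'
#' The image is stored as a single-channel float TIFF (intensities clipped
#' to `[0, 1]`); the line period, pixel size and mode go into a JSON sidecar
#' next to it, since baseline TIFF tags cannot carry them portably.
#'
#' @param k A [kymograph()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(k, path) {
  stopifnot(inherits(k, "nvc_kymograph"))
  img <- pmin(pmax(k$image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  jsonlite::write_json(list(dt_line = k$dt_line, dx = k$dx, mode = k$mode),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph from TIFF plus its calibration sidecar
#'
#' @param path TIFF path written by [write_kymograph_tiff()], or any
#'   single-channel TIFF if `dt_line`, `dx` and `mode` are given explicitly.
#' @param dt_line,dx,mode Calibration overrides; defaults come from the
#'   `<path>.json` sidecar.
#' @return A [kymograph()].
#' @export
read_kymograph_tiff <- function(path, dt_line = NULL, dx = NULL,
                                mode = NULL) {
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  kymograph(img,
            dt_line = dt_line %||% side$dt_line,
            dx = dx %||% side$dx,
            mode = mode %||% side$mode)
}

#' Write an activation-map mask to TIFF
#'
#' @param map A list with a logical `mask`, as returned by
#'   [activation_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(map, path) {
  tiff::writeTIFF(map$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
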