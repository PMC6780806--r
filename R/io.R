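#' Write and read images as TIFF
#'
#' Images are stored as 8-bit (or 16-bit) TIFF; grey levels are mapped to
#' the unit range on disk and restored on read.
#'
#' @param img `favf_image` array or grayscale matrix (grey levels).
#' @param path File path.
#' @param bits 8 or 16.
#' @param max_gray Grey-level ceiling used for scaling.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a `favf_image` (3-channel) or matrix.
#' @export
write_image_tiff <- function(img, path, bits = 8, max_gray = 255) {
  x <- unclass(img)
  attr(x, "pixel_size") <- NULL; attr(x, "z_plane") <- NULL
  tiff::writeTIFF(x / max_gray, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pixel_size,z_plane Metadata restored onto the image.
#' @export
read_image_tiff <- function(path, max_gray = 255, pixel_size = NA_real_,
                            z_plane = NA_real_) {
  x <- tiff::readTIFF(path)
  x <- round(x * max_gray)
  structure(x, pixel_size = pixel_size, z_plane = z_plane,
            class = "favf_image")
}

#' Write detections to CSV
#'
#' @param detections Detections data frame (see [rough_locate()]).
#' @param path File path.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
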