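#' Read an 8-bit RGB tile from PNG or TIFF
#'
#' @param path File path; format chosen by extension (`.png`, `.tif[f]`).
#' @return H x W x 3 array on the 0-255 scale.
#' @export
read_tile <- function(path) {
  assert_string(path, "path")
  if (!file.exists(path)) stop_not_found("no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_state("the 'tiff' package is required to read %s", path)
    tiff::readTIFF(path)
  } else stop_invalid("unsupported image extension: %s", ext)
  if (length(dim(img)) == 2L)
    stop_invalid("%s is grayscale; tiles must be 3-channel RGB", path)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

#' Write an 8-bit RGB tile as PNG
#'
#' PNG is lossless: a written tile reads back bit-identically.
#'
#' @param tile H x W x 3 array on the 0-255 scale.
#' @param path Output path ending in `.png`.
#' @export
write_tile <- function(tile, path) {
  assert_tile(tile)
  png::writePNG(round(tile) / 255, path)
  invisible(path)
}

#' Read a binary annotation mask from a single-channel PNG
#'
#' @param path PNG with values \{0, 255\} (or \{0, 1\} after scaling).
#' @return Logical H x W matrix.
#' @export
read_mask <- function(path) {
  assert_string(path, "path")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  u <- unique(as.vector(img))
  if (!all(u %in% c(0, 1)))
    stop_format("mask %s is not strictly binary", path)
  img == 1
}

#' Write a binary mask as a single-channel PNG with values \{0, 255\}
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stop_invalid("`mask` must be a matrix")
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
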