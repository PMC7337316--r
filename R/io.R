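# Reading photographs into 0-255 integer RGB arrays and writing masks.

#' Read an 8-bit RGB image
#'
#' PNG, JPEG and TIFF are supported (by file extension). Grayscale images
#' are rejected; an alpha channel, if present, is dropped.
#'
#' @param path Image file path.
#' @return H x W x 3 integer array, values 0-255.
#' @export
read_leaf_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(raw)) != 3L || dim(raw)[3L] < 3L)
    abort("image must have 3 colour channels (8-bit RGB)")
  arr <- raw[, , 1:3, drop = FALSE]
  array(as.integer(round(arr * 255)), dim = dim(arr))
}

#' Write a binary mask as a PNG for visual inspection
#'
#' @param mask 0/1 matrix; foreground becomes white (255).
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
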