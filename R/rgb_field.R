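#' Construct an RGB field of view
#'
#' An `rgb_field` holds one acquired 8-bit RGB field of view together with
#' its acquisition identifiers. Pixels are stored as an `H x W x 3` numeric
#' array with values in `[0, 255]` (`[row, col, channel]`, channels ordered
#' R, G, B).
#'
#' @param pixels `H x W x 3` numeric array of 8-bit intensities.
#' @param sample_id Sample identifier (one tissue specimen).
#' @param roi_id Region-of-interest identifier (one analyzed field).
#' @param pixel_size Optional pixel size in micrometres per pixel.
#'
#' @return An object of class `rgb_field`.
#' @export
rgb_field <- function(pixels, sample_id = "sample", roi_id = "roi",
                      pixel_size = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, sample_id = sample_id, roi_id = roi_id,
         pixel_size = pixel_size),
    class = "rgb_field"
  )
}

#' @export
print.rgb_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_field> %d x %d px, sample '%s', roi '%s'\n",
              d[1], d[2], x$sample_id, x$roi_id))
  invisible(x)
}

#' @export
dim.rgb_field <- function(x) dim(x$pixels)

#' Read an RGB field from a PNG or TIFF file
#'
#' @param path Path to an 8-bit RGB PNG or TIFF image.
#' @param sample_id,roi_id Identifiers attached to the field; default to the
#'   file name.
#' @return An [rgb_field()].
#' @export
read_rgb_field <- function(path, sample_id = NULL, roi_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  id <- tools::file_path_sans_ext(basename(path))
  rgb_field(round(img * 255),
            sample_id = sample_id %||% id,
            roi_id = roi_id %||% id)
}

#' Write an RGB field to a PNG or TIFF file
#'
#' @param field An [rgb_field()].
#' @param path Output path; format chosen from the extension (.png/.tif).
#' @return `path`, invisibly.
#' @export
write_rgb_field <- function(field, path) {
  stopifnot(inherits(field, "rgb_field"))
  img <- field$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, target = path),
    tif = ,
    tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero, the 8-bit quantisation used throughout
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)
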