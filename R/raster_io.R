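#' Read an RGB raster image
#'
#' Reads an 8-bit PNG or TIFF image into the package's canonical in-memory
#' form: a numeric array of dimension `height x width x channels` with values
#' in `[0, 1]`. An alpha channel, if present, is dropped. Grayscale images are
#' returned as a single-channel array; use [promote_channels()] to replicate
#' to three channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array `H x W x C`, values in `[0, 1]`.
#' @seealso [write_raster()], [write_probability()]
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '.", ext, "' (use PNG or TIFF): ", path)
  )
  if (is.list(img)) img <- img[[1L]]
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  storage.mode(img) <- "double"
  img
}

#' Write an RGB raster image
#'
#' Writes a `[0, 1]`-valued array to an 8-bit PNG or TIFF file.
#'
#' @param image Numeric array `H x W x C` (or `H x W`), values in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png`/`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported raster format '.", ext, "'")
  )
  invisible(path)
}

#' Write a per-pixel probability field
#'
#' TIFF output stores the field as 32-bit float, preserving probabilities
#' exactly; PNG output quantises to 8 bits by scaling with 255 (value
#' `round(p * 255) / 255` on re-read).
#'
#' @param field Numeric matrix of probabilities in `[0, 1]`.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_probability <- function(field, path) {
  stopifnot(is.matrix(field), all(field >= 0 & field <= 1))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(field, path),
    tif = ,
    tiff = tiff::writeTIFF(field, path, bits.per.sample = 32L,
                           compression = "none"),
    stop("unsupported raster format '.", ext, "'")
  )
  invisible(path)
}

#' Replicate a grayscale raster to three channels
#'
#' @param image Array `H x W` or `H x W x 1` (passed through unchanged if it
#'   already has three channels).
#' @return Array `H x W x 3`.
#' @export
promote_channels <- function(image) {
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  nc <- dim(image)[3L]
  if (nc == 3L) return(image)
  if (nc != 1L) stop("expected 1 or 3 channels, got ", nc)
  array(rep(image, 3L), c(dim(image)[1:2], 3L))
}
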