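#' Plan square crops with overlap over a raster
#'
#' Computes the windows of a sliding square crop of side `tile_size` with a
#' given overlap fraction between adjacent windows. Start positions along each
#' axis are `0, stride, 2*stride, ...` with
#' `stride = round(tile_size * (1 - overlap_fraction))`; if the last regular
#' start does not place a window flush with the far edge, one extra window
#' starting at `dimension - tile_size` is appended (shift-to-fit), so every
#' pixel is covered and coverage maps have no blind margins. Windows are listed
#' row-major and use 0-based, half-open pixel coordinates.
#'
#' @param height,width Raster dimensions in pixels.
#' @param tile_size Side of the square crop in pixels.
#' @param overlap_fraction Shared proportion of adjacent windows along an
#'   axis, in `[0, 1)`. The default 0.5 gives fifty-percent overlap both
#'   vertically and horizontally.
#' @return An object of class `tile_plan`: list with `image_height`,
#'   `image_width`, `tile_size`, `overlap_fraction`, `stride` and `windows`,
#'   a data frame with columns `tile_id`, `row0`, `col0`, `size`.
#' @examples
#' plan <- plan_tiles(64, 64, 32, 0.5)
#' nrow(plan$windows) # 9
#' @export
plan_tiles <- function(height, width, tile_size, overlap_fraction = 0.5) {
  stopifnot(length(height) == 1L, length(width) == 1L, length(tile_size) == 1L)
  height <- as.integer(height); width <- as.integer(width)
  tile_size <- as.integer(tile_size)
  if (tile_size < 2L) stop("tile_size must be at least 2 pixels")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (height < tile_size || width < tile_size)
    stop("raster (", height, "x", width, ") is too small to tile at size ",
         tile_size, ": both dimensions must be >= tile_size")
  stride <- as.integer(round(tile_size * (1 - overlap_fraction)))
  if (stride < 1L)
    stop("overlap_fraction ", overlap_fraction, " at tile_size ", tile_size,
         " gives stride < 1")
  starts <- function(extent) {
    s <- seq.int(0L, extent - tile_size, by = stride)
    last <- extent - tile_size
    if (s[length(s)] != last) s <- c(s, last)
    s
  }
  r0 <- starts(height)
  c0 <- starts(width)
  windows <- data.frame(
    tile_id = sprintf("t%04d", seq_len(length(r0) * length(c0))),
    row0 = rep(r0, each = length(c0)),
    col0 = rep(c0, times = length(r0)),
    size = tile_size,
    stringsAsFactors = FALSE
  )
  structure(
    list(image_height = height, image_width = width, tile_size = tile_size,
         overlap_fraction = overlap_fraction, stride = stride,
         windows = windows),
    class = "tile_plan"
  )
}

#' @export
print.tile_plan <- function(x, ...) {
  cat("Tile plan:", nrow(x$windows), "windows of", x$tile_size, "x",
      x$tile_size, "px over a", x$image_height, "x", x$image_width,
      "raster (overlap ", x$overlap_fraction, ", stride ", x$stride, ")\n",
      sep = " ")
  invisible(x)
}

#' Extract the planned crops from a raster
#'
#' @param image Numeric array `H x W x C` (or `H x W`).
#' @param plan A `tile_plan` built for this image's dimensions.
#' @return List of `size x size x C` arrays, in plan order; pixel values are
#'   copied unmodified.
#' @export
extract_tiles <- function(image, plan) {
  stopifnot(inherits(plan, "tile_plan"))
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (d[1L] != plan$image_height || d[2L] != plan$image_width)
    stop("plan was built for ", plan$image_height, "x", plan$image_width,
         " but image is ", d[1L], "x", d[2L])
  w <- plan$windows
  lapply(seq_len(nrow(w)), function(i) {
    image[w$row0[i] + seq_len(w$size[i]), w$col0[i] + seq_len(w$size[i]), ,
          drop = FALSE]
  })
}

#' Stitch per-tile probabilities into a per-pixel field
#'
#' Each pixel's value is the arithmetic mean of the reed probabilities of all
#' windows covering it, so a pixel covered by k windows averages exactly k
#' values and a uniform input stitches to a uniform field.
#'
#' @param plan A `tile_plan`.
#' @param tile_probs Numeric vector of per-tile probabilities in `[0, 1]`,
#'   one per window, in plan order.
#' @return Numeric matrix `image_height x image_width` with values in `[0, 1]`.
#' @export
stitch_probabilities <- function(plan, tile_probs) {
  stopifnot(inherits(plan, "tile_plan"))
  w <- plan$windows
  if (length(tile_probs) != nrow(w))
    stop("expected ", nrow(w), " tile probabilities, got ", length(tile_probs))
  if (any(tile_probs < 0 | tile_probs > 1))
    stop("tile probabilities must lie in [0, 1]")
  acc <- matrix(0, plan$image_height, plan$image_width)
  cnt <- matrix(0L, plan$image_height, plan$image_width)
  for (i in seq_len(nrow(w))) {
    ri <- w$row0[i] + seq_len(w$size[i])
    ci <- w$col0[i] + seq_len(w$size[i])
    acc[ri, ci] <- acc[ri, ci] + tile_probs[i]
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  if (any(cnt == 0L)) stop("plan does not cover every pixel")
  acc / cnt
}

#' Serialize or read a tile plan as CSV
#'
#' The CSV holds one row per window with columns
#' `tile_id,row0,col0,size`; plan-level fields travel as a header comment.
#'
#' @param plan A `tile_plan`.
#' @param path Output CSV path.
#' @return `path` invisibly (`write_tile_plan`); a `tile_plan`
#'   (`read_tile_plan`).
#' @export
write_tile_plan <- function(plan, path) {
  stopifnot(inherits(plan, "tile_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# image_height=%d image_width=%d tile_size=%d overlap_fraction=%g",
                     plan$image_height, plan$image_width, plan$tile_size,
                     plan$overlap_fraction), con)
  utils::write.csv(plan$windows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_plan
#' @export
read_tile_plan <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1L]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  windows <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  plan <- plan_tiles(vals[["image_height"]], vals[["image_width"]],
                     vals[["tile_size"]], vals[["overlap_fraction"]])
  if (!identical(plan$windows[c("row0", "col0", "size")],
                 windows[c("row0", "col0", "size")]))
    stop("tile plan CSV is inconsistent with its header parameters")
  plan
}
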