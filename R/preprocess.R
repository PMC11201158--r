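#' Image containers and intensity preprocessing
#'
#' An *image grid* is a plain numeric matrix whose rows index image height
#' and whose columns index width, with intensities normalized to `[0, 1]`
#' after any normalization step. All preprocessing is deterministic:
#' identical inputs give bitwise-identical outputs.
#'
#' @name preprocess
NULL

assert_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix (height x width)", call. = FALSE)
  if (any(!is.finite(x)))
    stop(arg, " contains non-finite pixel values", call. = FALSE)
  invisible(x)
}

#' Min-max intensity normalization
#'
#' Affinely rescales intensities to `[0, 1]`. A constant image maps to all
#' zeros (the degenerate-range convention), so the operation is always
#' defined and idempotent.
#'
#' @param image numeric matrix of pixel intensities.
#' @return numeric matrix with `min >= 0`, `max <= 1`.
#' @export
#' @examples
#' minmax_normalize(matrix(c(10, 20, 30), 1))
minmax_normalize <- function(image) {
  assert_image(image)
  rng <- range(image)
  if (rng[1] == rng[2]) return(array(0, dim(image)))
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement used before lung-field segmentation. Thin
#' wrapper around [EBImage::clahe()] with the output clamped back to
#' `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param clip_limit contrast clipping limit (default 2).
#' @param tile_grid integer vector of length 2, number of tiles along
#'   height and width (default `c(8, 8)`).
#' @return numeric matrix in `[0, 1]`.
#' @export
clahe <- function(image, clip_limit = 2, tile_grid = c(8L, 8L)) {
  assert_image(image)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("clahe() expects an image normalized to [0, 1]", call. = FALSE)
  tile_grid <- rep(as.integer(tile_grid), length.out = 2)
  if (tile_grid[1] > nrow(image) || tile_grid[2] > ncol(image))
    stop("tile grid larger than image", call. = FALSE)
  if (min(image) == max(image)) return(image)  # flat histogram: no-op
  # EBImage's first array dimension is x; our rows are height, so nx pairs
  # with rows.
  out <- EBImage::clahe(EBImage::Image(image),
                        nx = tile_grid[1], ny = tile_grid[2],
                        limit = clip_limit, keep.range = TRUE)
  out <- as.matrix(EBImage::imageData(out))
  pmin(pmax(out, 0), 1)
}

#' Letterbox an image to a square frame
#'
#' Aspect-preserving bilinear resize so the longest side equals
#' `target_size`, followed by centered zero padding to a square frame.
#' The exact geometry is returned so results can be mapped back to the
#' source frame with [unletterbox()].
#'
#' @param image numeric matrix, normalized.
#' @param target_size side length of the square output frame in pixels.
#' @return list with elements `image` (the `target_size` x `target_size`
#'   raster) and `geometry` (a `geometry_record`).
#' @export
letterbox <- function(image, target_size) {
  assert_image(image)
  target_size <- as.integer(target_size)
  if (target_size < 16L) stop("target_size must be at least 16", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  scale <- target_size / max(h, w)
  nh <- as.integer(round(h * scale)); nw <- as.integer(round(w * scale))
  content <- resize_bilinear(image, nh, nw)
  pad_top <- (target_size - nh) %/% 2L
  pad_left <- (target_size - nw) %/% 2L
  out <- matrix(0, target_size, target_size)
  out[pad_top + seq_len(nh), pad_left + seq_len(nw)] <- content
  geom <- geometry_record(source_height = h, source_width = w, scale = scale,
                          pad_top = pad_top,
                          pad_bottom = target_size - nh - pad_top,
                          pad_left = pad_left,
                          pad_right = target_size - nw - pad_left,
                          target_size = target_size)
  list(image = out, geometry = geom)
}

#' @rdname letterbox
#' @param source_height,source_width source frame in pixels.
#' @param scale resize ratio applied to the source.
#' @param pad_top,pad_bottom,pad_left,pad_right zero-pad widths in pixels.
#' @export
geometry_record <- function(source_height, source_width, scale,
                            pad_top, pad_bottom, pad_left, pad_right,
                            target_size) {
  g <- list(source_height = source_height, source_width = source_width,
            scale = scale, pad_top = pad_top, pad_bottom = pad_bottom,
            pad_left = pad_left, pad_right = pad_right,
            target_size = target_size)
  stopifnot(scale > 0, pad_top >= 0, pad_bottom >= 0, pad_left >= 0,
            pad_right >= 0)
  ch <- target_size - pad_top - pad_bottom
  cw <- target_size - pad_left - pad_right
  stopifnot(ch == round(source_height * scale), cw == round(source_width * scale))
  structure(g, class = "geometry_record")
}

#' Invert a letterbox transform
#'
#' Crops the content region recorded in `geom` and bilinearly resamples it
#' back to the source dimensions.
#'
#' @param raster `target_size` x `target_size` matrix.
#' @param geom a `geometry_record` from [letterbox()].
#' @return numeric matrix of the source dimensions.
#' @export
unletterbox <- function(raster, geom) {
  assert_image(raster)
  stopifnot(inherits(geom, "geometry_record"))
  if (nrow(raster) != geom$target_size || ncol(raster) != geom$target_size)
    stop("raster does not match geometry target_size", call. = FALSE)
  nh <- geom$target_size - geom$pad_top - geom$pad_bottom
  nw <- geom$target_size - geom$pad_left - geom$pad_right
  content <- raster[geom$pad_top + seq_len(nh), geom$pad_left + seq_len(nw),
                    drop = FALSE]
  if (nh == geom$source_height && nw == geom$source_width) return(content)
  resize_bilinear(content, geom$source_height, geom$source_width)
}

#' Map coordinates between the source and letterboxed frames
#'
#' @param geom a `geometry_record`.
#' @param rc two-column matrix (or length-2 vector) of (row, col)
#'   coordinates, 1-based.
#' @return matrix of mapped coordinates (not rounded).
#' @export
source_to_letterbox <- function(geom, rc) {
  rc <- rbind(rc)
  cbind((rc[, 1] - 0.5) * geom$scale + 0.5 + geom$pad_top,
        (rc[, 2] - 0.5) * geom$scale + 0.5 + geom$pad_left)
}

#' @rdname source_to_letterbox
#' @export
letterbox_to_source <- function(geom, rc) {
  rc <- rbind(rc)
  cbind((rc[, 1] - geom$pad_top - 0.5) / geom$scale + 0.5,
        (rc[, 2] - geom$pad_left - 0.5) / geom$scale + 0.5)
}

# bilinear resize via EBImage; EBImage's first dimension is x, which here
# carries image rows, so w/h are passed in row-major order
resize_bilinear <- function(image, target_h, target_w) {
  if (nrow(image) == target_h && ncol(image) == target_w) return(image)
  out <- EBImage::resize(EBImage::Image(image), w = target_h, h = target_w,
                         filter = "bilinear")
  as.matrix(EBImage::imageData(out))
}

#' Read and write grayscale radiograph rasters
#'
#' PNG and TIFF, 8- or 16-bit; intensities are scaled by bit depth to
#' `[0, 1]` on read. Color images are rejected (radiographs are
#' single-channel). PNG is written 8-bit; TIFF may be written 8- or 16-bit.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 2)
      stop("color images are not supported; supply grayscale input",
           call. = FALSE)
    img <- img[, , 1]  # gray + alpha: keep gray
  }
  img
}

#' @rdname read_image
#' @param image numeric matrix in `[0, 1]`.
#' @param bits bit depth for TIFF output (8 or 16).
#' @export
write_image <- function(image, path, bits = 8L) {
  assert_image(image)
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits)),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}
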