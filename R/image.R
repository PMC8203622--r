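#' Image with a physical pixel size
#'
#' A single-channel 2D intensity array with its physical pixel size attached.
#' The coordinate convention is 0-based: the centre of pixel `[row i, col j]`
#' (1-based matrix indices) is at `x = (j - 1) * pixel_size_nm`,
#' `y = (i - 1) * pixel_size_nm`.
#'
#' @param data numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size_nm physical size of one pixel in nanometres (> 0).
#' @return An `image_with_scale` object (matrix with a `pixel_size_nm`
#'   attribute).
#' @export
image_with_scale <- function(data, pixel_size_nm) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix", call. = FALSE)
  stopifnot_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(data, pixel_size_nm = as.numeric(pixel_size_nm),
            class = c("image_with_scale", "matrix", "array"))
}

#' @export
print.image_with_scale <- function(x, ...) {
  cat(sprintf("<image_with_scale> %d x %d px, %.4g nm/px\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm")))
  invisible(x)
}

#' @rdname image_with_scale
#' @param x object to query.
#' @export
pixel_size_nm <- function(x) {
  p <- attr(x, "pixel_size_nm")
  if (is.null(p)) stop("object carries no pixel size", call. = FALSE)
  p
}

# Vectorised bilinear interpolation at fractional 0-based pixel coordinates.
# xpx runs along columns, ypx along rows. Points must lie inside the image.
bilinear_interp <- function(img, xpx, ypx) {
  nx <- ncol(img); ny <- nrow(img)
  if (any(xpx < 0 | xpx > nx - 1 | ypx < 0 | ypx > ny - 1))
    stop("interpolation point outside image", call. = FALSE)
  x0 <- pmin(floor(xpx), nx - 2); y0 <- pmin(floor(ypx), ny - 2)
  fx <- xpx - x0; fy <- ypx - y0
  i <- y0 + 1L; j <- x0 + 1L
  img[cbind(i, j)]         * (1 - fx) * (1 - fy) +
    img[cbind(i, j + 1)]     * fx       * (1 - fy) +
    img[cbind(i + 1, j)]     * (1 - fx) * fy +
    img[cbind(i + 1, j + 1)] * fx       * fy
}
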