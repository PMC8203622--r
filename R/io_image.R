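#' Read and write scaled images
#'
#' Two on-disk formats are supported. `TIFF`: 32-bit samples via the tiff
#' package; because that codec stores values scaled into `[0, 1]` and keeps
#' no physical metadata, the writer emits a JSON sidecar
#' (`<path>.json`) holding the pixel size and the affine intensity scale,
#' and the reader applies it (round trip accurate to ~1e-9 of the dynamic
#' range). `MRC`: a minimal mode-2 (float32) MRC2014 implementation; the
#' pixel size travels in the cell dimensions and data are bit-exact
#' float32.
#'
#' @param image an [image_with_scale()].
#' @param path file path (`.tif`/`.tiff` or `.mrc`).
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   an [image_with_scale()].
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_image <- function(image, path) {
  if (grepl("\\.mrc$", path, ignore.case = TRUE)) write_image_mrc(image, path)
  else write_image_tiff(image, path)
}

#' @rdname image_io
#' @param pixel_size_nm override/supply the pixel size when the file (or
#'   sidecar) does not provide one.
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (grepl("\\.mrc$", path, ignore.case = TRUE))
    read_image_mrc(path, pixel_size_nm)
  else read_image_tiff(path, pixel_size_nm)
}

write_image_tiff <- function(image, path) {
  m <- unclass(image)
  attr(m, "pixel_size_nm") <- NULL
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((m - lo) / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(pixel_size_nm = pixel_size_nm(image),
                            offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_image_tiff <- function(path, pixel_size_nm = NULL) {
  arr <- tiff::readTIFF(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  sidecar <- paste0(path, ".json")
  offset <- 0; scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    offset <- meta$offset; scale <- meta$scale
    if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  }
  if (is.null(pixel_size_nm))
    stop("no pixel size: TIFF has no sidecar and no override was given",
         call. = FALSE)
  image_with_scale(arr * scale + offset, pixel_size_nm)
}

write_image_mrc <- function(image, path) {
  m <- unclass(image)
  px_ang <- pixel_size_nm(image) * 10     # MRC cell lengths are in Angstrom
  nx <- ncol(m); ny <- nrow(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L))                       # nx ny nz
  wi(2L)                                  # mode 2 = float32
  wi(c(0L, 0L, 0L))                       # nxstart..
  wi(c(nx, ny, 1L))                       # mx my mz
  wf(c(nx * px_ang, ny * px_ang, px_ang)) # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1L, 2L, 3L))                       # mapc mapr maps
  wf(c(min(m), max(m), mean(m)))          # dmin dmax dmean
  wi(c(0L, 0L))                           # ispg, nsymbt
  wi(rep(0L, 25L))                        # extra
  wf(c(0, 0, 0))                          # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(m))                               # rms
  wi(0L)                                  # nlabl
  writeBin(raw(800L), con)                # labels
  # data: x fastest, then y (row y of the matrix is a constant-y line)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

read_image_mrc <- function(path, pixel_size_nm = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("only mode-2 (float32) MRC supported", call. = FALSE)
  ri(3L); ri(3L)
  cella <- rf(3L)
  seek(con, 1024L)
  vals <- rf(dims[1] * dims[2])
  m <- t(matrix(vals, dims[1], dims[2]))
  if (is.null(pixel_size_nm)) {
    if (cella[1] <= 0) stop("MRC carries no pixel size and no override given",
                            call. = FALSE)
    pixel_size_nm <- cella[1] / dims[1] / 10
  }
  image_with_scale(m, pixel_size_nm)
}
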