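#' Intensity profile along a line or radius
#'
#' A 1D sampled intensity trace with physical positions. Positions must be
#' uniformly spaced and monotone increasing; profiles shorter than 8 samples
#' are rejected (too short to carry two headgroup peaks).
#'
#' @param positions_nm numeric vector of sample positions (nm).
#' @param intensity numeric vector of intensities (arbitrary units).
#' @param provenance list describing how the profile was extracted.
#' @return An `intensity_profile` object.
#' @export
intensity_profile <- function(positions_nm, intensity, provenance = list()) {
  if (length(positions_nm) != length(intensity))
    stop("positions and intensities differ in length", call. = FALSE)
  if (length(positions_nm) < 8L)
    stop("profile needs at least 8 samples", call. = FALSE)
  d <- diff(positions_nm)
  if (any(d <= 0)) stop("positions must be strictly increasing", call. = FALSE)
  if (diff(range(d)) > 1e-9 * max(d))
    stop("positions must be uniformly spaced", call. = FALSE)
  structure(list(positions_nm = as.numeric(positions_nm),
                 intensity = as.numeric(intensity),
                 provenance = provenance),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples, %.4g-%.4g nm (spacing %.4g nm)\n",
              length(x$intensity), min(x$positions_nm), max(x$positions_nm),
              x$positions_nm[2] - x$positions_nm[1]))
  invisible(x)
}

profile_spacing <- function(profile) profile$positions_nm[2] - profile$positions_nm[1]

#' Line intensity profile across an image
#'
#' Samples the image along a straight segment by bilinear interpolation,
#' averaging over `width_px` parallel lines centred on the segment. This is
#' the line-scan used to measure thickness across docking interfaces and
#' protein depletion/enrichment at membrane contacts.
#'
#' @param image an [image_with_scale()].
#' @param start_nm,end_nm segment endpoints, `c(x, y)` in nm.
#' @param width_px odd integer; number of parallel 1-px-spaced lines averaged.
#' @return An [intensity_profile()] with positions measured from `start_nm`.
#' @export
line_profile <- function(image, start_nm, end_nm, width_px = 1L) {
  px <- pixel_size_nm(image)
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L)
    stop("'width_px' must be a positive odd integer", call. = FALSE)
  v <- c(end_nm[1] - start_nm[1], end_nm[2] - start_nm[2])
  len <- sqrt(sum(v^2))
  if (len < .Machine$double.eps)
    stop("degenerate zero-length segment", call. = FALSE)
  u <- v / len
  perp <- c(-u[2], u[1])
  n <- max(8L, floor(len / px) + 1L)
  s <- seq(0, len, length.out = n)
  offs <- (seq_len(width_px) - (width_px + 1L) / 2L) * px
  acc <- numeric(n)
  for (o in offs) {
    xn <- start_nm[1] + s * u[1] + o * perp[1]
    yn <- start_nm[2] + s * u[2] + o * perp[2]
    acc <- acc + bilinear_interp(image, xn / px, yn / px)
  }
  intensity_profile(s, acc / width_px,
                    provenance = list(type = "line", start_nm = start_nm,
                                      end_nm = end_nm, width_px = width_px))
}

#' Radial intensity profile around a centre
#'
#' Mean intensity per radial bin over all pixels whose centre falls in the
#' bin — the azimuthal average used to measure thickness of free (undocked)
#' vesicle membranes.
#'
#' @param image an [image_with_scale()].
#' @param center_nm circle centre `c(x, y)` in nm; must lie inside the image.
#' @param r_max_nm outer radius of the profile (nm).
#' @param bin_width_px radial bin width in pixels.
#' @return An [intensity_profile()] whose positions are bin centres (nm).
#'   Bins containing no pixel get `NA` intensity and are listed in the
#'   `empty_bins` field of the provenance.
#' @export
radial_profile <- function(image, center_nm, r_max_nm, bin_width_px = 1) {
  px <- pixel_size_nm(image)
  stopifnot_scalar(r_max_nm, "r_max_nm", positive = TRUE)
  stopifnot_scalar(bin_width_px, "bin_width_px", positive = TRUE)
  nx <- ncol(image); ny <- nrow(image)
  if (center_nm[1] < 0 || center_nm[1] > (nx - 1) * px ||
      center_nm[2] < 0 || center_nm[2] > (ny - 1) * px)
    stop("centre outside image", call. = FALSE)
  bw <- bin_width_px * px
  xs <- (seq_len(nx) - 1) * px - center_nm[1]
  ys <- (seq_len(ny) - 1) * px - center_nm[2]
  R <- sqrt(outer(ys^2, xs^2, `+`))
  keep <- R <= r_max_nm
  bin <- pmin(floor(R[keep] / bw), ceiling(r_max_nm / bw) - 1)
  n_bins <- ceiling(r_max_nm / bw)
  sums <- tapply(as.numeric(image)[keep], factor(bin, levels = 0:(n_bins - 1)),
                 mean)
  vals <- as.numeric(sums)
  centers <- (seq_len(n_bins) - 0.5) * bw
  empty <- which(is.na(vals))
  intensity_profile(centers, vals,
                    provenance = list(type = "radial", center_nm = center_nm,
                                      bin_width_px = bin_width_px,
                                      empty_bins = empty))
}
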