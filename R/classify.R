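#' Classify a docking interface as loose or tight
#'
#' Docked vesicle pairs are classified from the labelled-protein channel:
#' the background-subtracted peak protein signal on a line scan across the
#' docking interface is divided by the same quantity on a scan across free
#' membrane of the same pair. Tight docking depletes protein from the
#' contact site (low ratio); loose docking retains or enriches it.
#'
#' @param protein_image protein-channel [image_with_scale()].
#' @param interface_segment,free_segment lists with `start` and `end`
#'   (`c(x, y)` nm) and optionally `width_px`, as produced in the generator's
#'   ground-truth `segments`.
#' @param threshold calls are `tight` when `interface_ratio < threshold`.
#'   The default 0.6 encodes "signal decreased or absent"; a ratio exactly at
#'   the threshold is called loose (conservative toward the loose call).
#' @param background background intensity; default is the median over a
#'   5-px border frame of the image.
#' @return A `docking_call` list: `label` (`"loose"`/`"tight"`),
#'   `interface_ratio`, `threshold`, `interface_signal`, `free_signal`,
#'   `background`.
#' @export
classify_interface <- function(protein_image, interface_segment, free_segment,
                               threshold = 0.6, background = NULL) {
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  if (is.null(background)) background <- border_background(protein_image)
  sig <- function(seg) {
    w <- if (is.null(seg$width_px)) 1L else seg$width_px
    pr <- line_profile(protein_image, seg$start, seg$end, width_px = w)
    max(pr$intensity) - background
  }
  s_int <- sig(interface_segment)
  s_free <- sig(free_segment)
  if (s_free <= 0)
    stop("free-membrane signal does not exceed background; ratio undefined",
         call. = FALSE)
  ratio <- s_int / s_free
  structure(list(label = if (ratio < threshold) "tight" else "loose",
                 interface_ratio = ratio, threshold = threshold,
                 interface_signal = s_int, free_signal = s_free,
                 background = background),
            class = "docking_call")
}

#' @export
print.docking_call <- function(x, ...) {
  cat(sprintf("<docking_call> %s (interface/free protein ratio %.3f, threshold %.2f)\n",
              x$label, x$interface_ratio, x$threshold))
  invisible(x)
}

# Median intensity over a border frame of the image (background estimate).
border_background <- function(image, frame_px = 5L) {
  n <- nrow(image); m <- ncol(image)
  f <- min(frame_px, floor(min(n, m) / 2))
  median(image[row(image) <= f | row(image) > n - f |
               col(image) <= f | col(image) > m - f])
}
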