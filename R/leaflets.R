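#' Assign lipids to membranes and leaflets
#'
#' Lipids are clustered by the z-coordinate of their P particle into
#' `2 * n_membranes` groups (1D k-means with ordered, largest-gap
#' initialisation); consecutive groups are paired into membranes. The
#' outward normal is +z for the upper leaflet of each membrane and -z for
#' the lower. In double systems the two gap-facing leaflets are classed
#' `inner`, the solvent-facing ones `outer`.
#'
#' @param frame a [bilayer_frame()].
#' @param n_membranes 1 or 2.
#' @return A `leaflet_assignment` data.frame (one row per lipid): `lipid`,
#'   `membrane`, `leaflet` (numbered bottom-up), `side`
#'   (`"lower"`/`"upper"` within the membrane), `class`
#'   (`"outer"`/`"inner"`), `normal` (+1/-1). Leaflet mean P heights are in
#'   `attr(, "leaflet_mean_z")`.
#' @export
assign_leaflets <- function(frame, n_membranes = 1L) {
  n_membranes <- as.integer(n_membranes)
  if (!n_membranes %in% c(1L, 2L)) stop("n_membranes must be 1 or 2", call. = FALSE)
  p <- frame[frame$role == "P", ]
  k <- 2L * n_membranes
  if (nrow(p) < k) stop("fewer P particles than leaflets", call. = FALSE)
  z <- p$z
  if (length(unique(z)) < k)
    stop("P z-coordinates do not separate into ", k,
         " leaflets (degenerate layers)", call. = FALSE)

  ord <- order(z)
  zs <- z[ord]
  gaps <- diff(zs)
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1L)])
  grp_sorted <- rep(seq_len(k), times = diff(c(0L, cuts, length(zs))))
  centers <- tapply(zs, grp_sorted, mean)
  leaflet <- integer(length(z))
  leaflet[ord] <- grp_sorted
  # k-means refinement of the ordered split (a no-op for well-separated
  # layers; degenerate tiny groups keep the split itself)
  km <- try(suppressWarnings(kmeans(z, centers = matrix(centers, ncol = 1))),
            silent = TRUE)
  if (!inherits(km, "try-error")) {
    cl_order <- order(km$centers)
    leaflet <- match(km$cluster, cl_order)
  }

  # separability: the gap between adjacent leaflets must clearly exceed the
  # point spacing inside them
  for (lf in seq_len(k - 1L)) {
    hi <- max(z[leaflet == lf]); lo <- min(z[leaflet == lf + 1L])
    gap <- lo - hi
    within <- max(c(0, diff(sort(z[leaflet == lf]))),
                  c(0, diff(sort(z[leaflet == lf + 1L]))))
    if (gap <= 0 || (within > 0 && gap < within)) {
      amb <- p$lipid[abs(z - (hi + lo) / 2) <= max(within, abs(gap))]
      stop("leaflet z-distributions overlap between leaflets ", lf, " and ",
           lf + 1L, "; ambiguous lipids: ",
           paste(utils::head(sort(amb), 10L), collapse = ", "), call. = FALSE)
    }
  }

  membrane <- (leaflet + 1L) %/% 2L
  side <- ifelse(leaflet %% 2L == 1L, "lower", "upper")
  cls <- if (n_membranes == 1L) rep("outer", k) else c("outer", "inner", "inner", "outer")
  out <- data.frame(lipid = p$lipid, membrane = membrane, leaflet = leaflet,
                    side = side, class = cls[leaflet],
                    normal = ifelse(side == "upper", 1, -1))
  out <- out[order(out$lipid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_membranes") <- n_membranes
  attr(out, "leaflet_mean_z") <- as.numeric(tapply(z, leaflet, mean))
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}
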