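#' Specification for a synthetic vesicle image
#'
#' Describes a micrograph-like specimen: either a single free vesicle or a
#' docked vesicle pair sharing a flat contact zone. Each membrane is rendered
#' as two Gaussian ridges (one per headgroup layer) separated by the local
#' membrane thickness; at a docked interface both membranes flatten onto a
#' chord of half-width `contact_halfwidth_nm`. Tight interfaces add
#' `interface_thickening_nm` to the membrane thickness inside the contact
#' zone and deplete the protein channel there; loose interfaces enrich it.
#'
#' @param image_size_px image size in pixels, length 1 or 2 `(nx, ny)`.
#' @param pixel_size_nm physical pixel size (nm/px). The default 0.5 nm/px is
#'   a free parameter of the generator, typical of intermediate-magnification
#'   cryo-EM of liposomes.
#' @param docking_type `"free"`, `"loose"` or `"tight"`.
#' @param radii_nm vesicle mid-membrane radius (free: length 1; docked pairs:
#'   length 2).
#' @param center_nm for `"free"`, the vesicle centre; for docked pairs, the
#'   midpoint of the contact zone. Default: image centre.
#' @param membrane_thickness_nm true headgroup peak-to-peak thickness of each
#'   membrane away from the interface (nm).
#' @param interface_thickening_nm extra thickness inside the contact zone
#'   (tight interfaces only; nm, >= 0).
#' @param interface_gap_nm separation between the two proximal headgroup
#'   ridges across the contact zone. Defaults: 2.2 nm (tight), 3.0 nm
#'   (loose). The tight default is kept above the two-ridge merging limit so
#'   per-membrane thickness remains measurable; sub-resolution separations
#'   render as a single blended line.
#' @param contact_halfwidth_nm half-width of the flat contact chord (nm).
#' @param headgroup_ridge_sigma_nm Gaussian width of a headgroup ridge (nm);
#'   stands in for the point-spread/defocus blur.
#' @param protein_interface_ratio protein signal inside the contact zone
#'   divided by the signal on free membrane. Defaults: 0.15 (tight,
#'   depleted), 1.6 (loose, enriched), 1 (free).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (ridge amplitude is 1).
#' @param seed integer seed; identical specs with the same seed render
#'   bit-identical images.
#' @return A `vesicle_image_spec` list.
#' @export
vesicle_image_spec <- function(image_size_px = 256L,
                               pixel_size_nm = 0.5,
                               docking_type = c("free", "loose", "tight"),
                               radii_nm = NULL,
                               center_nm = NULL,
                               membrane_thickness_nm = 4.0,
                               interface_thickening_nm = NULL,
                               interface_gap_nm = NULL,
                               contact_halfwidth_nm = 15,
                               headgroup_ridge_sigma_nm = 0.6,
                               protein_interface_ratio = NULL,
                               noise_sigma = 0.05,
                               seed = NULL) {
  docking_type <- match.arg(docking_type)
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  image_size_px <- as.integer(image_size_px)
  if (any(image_size_px < 16L)) stop("image too small", call. = FALSE)
  stopifnot_scalar(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  stopifnot_scalar(membrane_thickness_nm, "membrane_thickness_nm", positive = TRUE)
  stopifnot_scalar(headgroup_ridge_sigma_nm, "headgroup_ridge_sigma_nm", positive = TRUE)
  stopifnot_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)

  if (is.null(radii_nm))
    radii_nm <- if (docking_type == "free") 45 else c(45, 45)
  n_ves <- if (docking_type == "free") 1L else 2L
  if (length(radii_nm) != n_ves)
    stop(sprintf("docking_type '%s' needs %d radius value(s)", docking_type, n_ves),
         call. = FALSE)
  if (any(radii_nm <= membrane_thickness_nm))
    stop("vesicle radii must exceed the membrane thickness", call. = FALSE)

  if (is.null(interface_thickening_nm))
    interface_thickening_nm <- if (docking_type == "tight") 0.6 else 0
  stopifnot_scalar(interface_thickening_nm, "interface_thickening_nm", nonneg = TRUE)
  if (is.null(interface_gap_nm))
    interface_gap_nm <- switch(docking_type, tight = 2.2, loose = 3.0, free = NA_real_)
  if (is.null(protein_interface_ratio))
    protein_interface_ratio <- switch(docking_type, tight = 0.15, loose = 1.6, free = 1)
  stopifnot_scalar(protein_interface_ratio, "protein_interface_ratio", nonneg = TRUE)

  if (is.null(center_nm))
    center_nm <- (image_size_px - 1L) / 2 * pixel_size_nm
  if (docking_type != "free") {
    stopifnot_scalar(contact_halfwidth_nm, "contact_halfwidth_nm", positive = TRUE)
    stopifnot_scalar(interface_gap_nm, "interface_gap_nm", positive = TRUE)
    if (contact_halfwidth_nm >= min(radii_nm) - membrane_thickness_nm)
      stop("contact half-width too large for the vesicle radii ",
           "(vesicles would overlap beyond the contact geometry)", call. = FALSE)
  }

  structure(list(image_size_px = image_size_px,
                 pixel_size_nm = pixel_size_nm,
                 docking_type = docking_type,
                 radii_nm = radii_nm,
                 center_nm = as.numeric(center_nm),
                 membrane_thickness_nm = membrane_thickness_nm,
                 interface_thickening_nm = interface_thickening_nm,
                 interface_gap_nm = interface_gap_nm,
                 contact_halfwidth_nm = contact_halfwidth_nm,
                 headgroup_ridge_sigma_nm = headgroup_ridge_sigma_nm,
                 protein_interface_ratio = protein_interface_ratio,
                 noise_sigma = noise_sigma,
                 seed = seed),
            class = "vesicle_image_spec")
}

#' Render a synthetic vesicle (pair) image with ground truth
#'
#' Renders the density channel (headgroup ridges), the protein fluorescence
#' channel (membrane contour, scaled by `protein_interface_ratio` inside the
#' contact zone), and returns the ground truth needed to score every
#' downstream measurement: true thickness in and out of the contact zone,
#' the docking label, ridge geometry, and ready-made line-scan segments.
#'
#' @param spec a [vesicle_image_spec()].
#' @return list with elements `density` and `protein` (both
#'   [image_with_scale()]) and `truth` (list; see Details).
#' @details `truth` carries `docking_type`, `thickness_free_nm`,
#'   `thickness_interface_nm`, `protein_interface_ratio`, the vesicle
#'   `centers_nm`/`radii_nm`, interface geometry (`interface_x_nm`,
#'   `interface_y_nm`, `gap_nm`, `contact_halfwidth_nm`,
#'   `interface_ridge_x_nm`, the four headgroup ridge x-positions across a
#'   docked interface), `ridge_radii_nm` for free vesicles, and `segments`,
#'   a list of `interface` and `free` line-scan endpoints.
#' @export
generate_vesicle_pair_image <- function(spec) {
  if (!inherits(spec, "vesicle_image_spec"))
    stop("'spec' must be a vesicle_image_spec", call. = FALSE)
  px <- spec$pixel_size_nm
  nx <- spec$image_size_px[1]; ny <- spec$image_size_px[2]
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  sg <- spec$headgroup_ridge_sigma_nm
  t0 <- spec$membrane_thickness_nm

  ridge <- function(u, t_loc)
    exp(-(u - t_loc / 2)^2 / (2 * sg^2)) + exp(-(u + t_loc / 2)^2 / (2 * sg^2))

  density <- matrix(0, ny, nx)
  protein <- matrix(0, ny, nx)

  if (spec$docking_type == "free") {
    cx <- spec$center_nm[1]; cy <- spec$center_nm[2]
    R <- spec$radii_nm[1]
    u <- sqrt((X - cx)^2 + (Y - cy)^2) - R
    density <- ridge(u, t0)
    protein <- exp(-u^2 / (2 * sg^2))
    truth <- list(
      docking_type = "free",
      thickness_free_nm = t0,
      thickness_interface_nm = NA_real_,
      protein_interface_ratio = 1,
      centers_nm = matrix(c(cx, cy), 1, 2,
                          dimnames = list(NULL, c("x", "y"))),
      radii_nm = R,
      ridge_radii_nm = c(R - t0 / 2, R + t0 / 2),
      segments = list(
        free = list(start = c(cx, cy), end = c(cx + R + 4 * t0, cy)))
    )
  } else {
    xc <- spec$center_nm[1]; yc <- spec$center_nm[2]
    g <- spec$interface_gap_nm
    w <- spec$contact_halfwidth_nm
    thick <- if (spec$docking_type == "tight") spec$interface_thickening_nm else 0
    ti <- t0 + thick                       # interface-zone thickness
    R1 <- spec$radii_nm[1]; R2 <- spec$radii_nm[2]
    m1 <- xc - g / 2 - ti / 2              # facet mid-plane, left membrane
    m2 <- xc + g / 2 + ti / 2
    d1 <- sqrt(R1^2 - w^2); d2 <- sqrt(R2^2 - w^2)
    cx1 <- m1 - d1; cx2 <- m2 + d2

    for (m in list(list(c = cx1, R = R1, uf = X - m1),
                   list(c = cx2, R = R2, uf = m2 - X))) {
      uc <- sqrt((X - m$c)^2 + (Y - yc)^2) - m$R
      facet <- m$uf > uc                  # flat chord replaces the cap
      u <- ifelse(facet, m$uf, uc)
      t_loc <- ifelse(facet, ti, t0)
      density <- density + ridge(u, t_loc)
      amp <- ifelse(facet, spec$protein_interface_ratio, 1)
      protein <- protein + amp * exp(-u^2 / (2 * sg^2))
    }
    truth <- list(
      docking_type = spec$docking_type,
      thickness_free_nm = t0,
      thickness_interface_nm = ti,
      protein_interface_ratio = spec$protein_interface_ratio,
      centers_nm = matrix(c(cx1, yc, cx2, yc), 2, 2, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y"))),
      radii_nm = c(R1, R2),
      interface_x_nm = xc, interface_y_nm = yc,
      gap_nm = g, contact_halfwidth_nm = w,
      interface_ridge_x_nm = c(m1 - ti / 2, xc - g / 2, xc + g / 2, m2 + ti / 2),
      segments = list(
        interface = list(start = c(m1 - ti / 2 - 4 * t0, yc),
                         end   = c(m2 + ti / 2 + 4 * t0, yc)),
        free = list(start = c(cx1, yc + R1 - 4 * t0),
                    end   = c(cx1, yc + R1 + 4 * t0)))
    )
  }

  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed, list(
      d = matrix(rnorm(nx * ny, 0, spec$noise_sigma), ny, nx),
      p = matrix(rnorm(nx * ny, 0, spec$noise_sigma), ny, nx)))
    density <- density + noise$d
    protein <- protein + noise$p
  }

  list(density = image_with_scale(density, px),
       protein = image_with_scale(protein, px),
       truth = truth)
}
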