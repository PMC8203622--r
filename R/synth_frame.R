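#' Construct a bilayer frame from particle data
#'
#' A frame is a data.frame of labelled particles: positions in nm, a role
#' per particle (`P` phosphate, `N` headgroup nitrogen, `C` chain bead, `W`
#' water oxygen), the owning lipid index (`NA` for waters), and optional
#' ground-truth `membrane`/`leaflet` columns. Box lengths are orthorhombic;
#' x and y are wrapped into the box on ingest (z is not wrapped: bilayer
#' stacks are assumed not to straddle the z boundary).
#'
#' @param particles data.frame with columns `x`, `y`, `z`, `role`, `lipid`
#'   (and optionally `membrane`, `leaflet`).
#' @param box_nm numeric length-3 box lengths (nm).
#' @param time_ns frame time stamp (ns).
#' @return A `bilayer_frame` data.frame with `box_nm` and `time_ns`
#'   attributes.
#' @export
bilayer_frame <- function(particles, box_nm, time_ns = 0) {
  need <- c("x", "y", "z", "role", "lipid")
  if (!all(need %in% names(particles)))
    stop("particles need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (length(box_nm) != 3L || any(!is.finite(box_nm)) || any(box_nm <= 0))
    stop("box lengths must be three positive numbers", call. = FALSE)
  if (!all(particles$role %in% c("P", "N", "C", "W")))
    stop("roles must be P, N, C or W", call. = FALSE)
  lip <- particles$lipid[particles$role != "W"]
  if (anyNA(lip)) stop("lipid particles must carry a lipid index", call. = FALSE)
  for (r in c("P", "N")) {
    cnt <- table(particles$lipid[particles$role == r])
    if (length(cnt) != length(unique(lip)) || any(cnt != 1L))
      stop(sprintf("each lipid must have exactly one %s particle", r), call. = FALSE)
  }
  particles$x <- particles$x %% box_nm[1]
  particles$y <- particles$y %% box_nm[2]
  structure(as.data.frame(particles),
            box_nm = as.numeric(box_nm), time_ns = as.numeric(time_ns),
            class = c("bilayer_frame", "data.frame"))
}

box_nm <- function(frame) attr(frame, "box_nm")

#' @export
`[.bilayer_frame` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("box_nm", "time_ns", "spec", "truth"))
      attr(out, a) <- attr(x, a)
    class(out) <- class(x)
  }
  out
}

#' Specification for a synthetic bilayer frame
#'
#' Lipids sit on a jittered square lattice; each lipid is a P particle, an N
#' particle placed at a fixed bond length with polar angle
#' `acos(mean_tilt_cos)` from the leaflet outward normal and uniformly
#' random azimuth (so the per-lipid tilt cosine realises the target
#' exactly), and a straight-ish chain of beads descending towards the
#' membrane midplane with fixed bond polar angle `acos(chain_bond_cos)`.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (default 100, a typical
#'   small atomistic patch).
#' @param n_membranes 1 (single bilayer) or 2 (docked double-membrane
#'   stack).
#' @param intermembrane_distance_nm P-layer to P-layer distance between the
#'   two gap-facing leaflets (double systems; the regime of interest spans
#'   roughly 0.4-4.7 nm).
#' @param thickness_nm P-layer to P-layer thickness within each membrane.
#' @param mean_tilt_cos length-2 numeric `c(outer, inner)` in `[0, 1]`:
#'   target mean headgroup tilt cosine for outer (solvent-facing) and inner
#'   (gap-facing) leaflets. Single membranes use the `outer` value for both
#'   leaflets.
#' @param chain_beads_per_lipid beads per acyl-chain stand-in.
#' @param chain_bond_cos cosine of every chain bond's angle to the leaflet
#'   normal, so the chain order parameter is exactly
#'   `(3 * chain_bond_cos^2 - 1) / 2`.
#' @param box_xy_nm lateral box edge (nm); default 8.1.
#' @param box_z_nm box height; default sized to hold the stack plus solvent
#'   margins.
#' @param positional_noise_nm isotropic Gaussian jitter applied to each
#'   lipid anchor (P) position; N and chain positions ride on the jittered
#'   anchor so tilt and order recovery stay exact.
#' @param bond_length_nm P-to-N distance (nm).
#' @param chain_bond_length_nm distance between successive chain beads (nm).
#' @param charges named numeric: partial charge (e) per role `P`, `N`, `C`,
#'   `W`. Default is the zwitterionic headgroup stand-in `P = -1`, `N = +1`,
#'   neutral chains and waters.
#' @param n_gap_waters waters placed uniformly in the inter-membrane gap
#'   (double systems only).
#' @param seed integer seed.
#' @return A `bilayer_frame_spec` list.
#' @export
bilayer_frame_spec <- function(n_lipids_per_leaflet = 100L,
                               n_membranes = 1L,
                               intermembrane_distance_nm = 2.0,
                               thickness_nm = 4.0,
                               mean_tilt_cos = c(outer = 0.3, inner = 0.3),
                               chain_beads_per_lipid = 8L,
                               chain_bond_cos = 1,
                               box_xy_nm = 8.1,
                               box_z_nm = NULL,
                               positional_noise_nm = 0.05,
                               bond_length_nm = 0.45,
                               chain_bond_length_nm = 0.2,
                               charges = c(P = -1, N = 1, C = 0, W = 0),
                               n_gap_waters = 0L,
                               seed = NULL) {
  n_membranes <- as.integer(n_membranes)
  if (!n_membranes %in% c(1L, 2L)) stop("n_membranes must be 1 or 2", call. = FALSE)
  stopifnot_scalar(thickness_nm, "thickness_nm", positive = TRUE)
  stopifnot_scalar(intermembrane_distance_nm, "intermembrane_distance_nm",
                   positive = TRUE)
  stopifnot_scalar(box_xy_nm, "box_xy_nm", positive = TRUE)
  stopifnot_scalar(positional_noise_nm, "positional_noise_nm", nonneg = TRUE)
  stopifnot_scalar(bond_length_nm, "bond_length_nm", positive = TRUE)
  if (length(mean_tilt_cos) == 1L)
    mean_tilt_cos <- c(outer = unname(mean_tilt_cos), inner = unname(mean_tilt_cos))
  if (any(mean_tilt_cos < 0) || any(mean_tilt_cos > 1))
    stop("mean_tilt_cos must lie in [0, 1]", call. = FALSE)
  if (abs(chain_bond_cos) > 1) stop("chain_bond_cos must lie in [-1, 1]", call. = FALSE)
  if (!all(c("P", "N", "C", "W") %in% names(charges)))
    stop("charges must name roles P, N, C, W", call. = FALSE)
  margin <- 2.5
  if (is.null(box_z_nm))
    box_z_nm <- if (n_membranes == 1L) thickness_nm + 2 * margin
                else 2 * thickness_nm + intermembrane_distance_nm + 2 * margin
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 n_membranes = n_membranes,
                 intermembrane_distance_nm = intermembrane_distance_nm,
                 thickness_nm = thickness_nm,
                 mean_tilt_cos = mean_tilt_cos,
                 chain_beads_per_lipid = as.integer(chain_beads_per_lipid),
                 chain_bond_cos = chain_bond_cos,
                 box_xy_nm = box_xy_nm, box_z_nm = box_z_nm,
                 positional_noise_nm = positional_noise_nm,
                 bond_length_nm = bond_length_nm,
                 chain_bond_length_nm = chain_bond_length_nm,
                 charges = charges, n_gap_waters = as.integer(n_gap_waters),
                 seed = seed),
            class = "bilayer_frame_spec")
}

#' Generate a synthetic bilayer frame
#'
#' @param spec a [bilayer_frame_spec()].
#' @param time_ns time stamp for the frame.
#' @return A [bilayer_frame()] carrying ground-truth `membrane` and
#'   `leaflet` columns (leaflets numbered bottom-up in z) and a `truth`
#'   attribute with the spec values every trajectory metric should recover.
#' @export
generate_bilayer_frame <- function(spec, time_ns = 0) {
  if (!inherits(spec, "bilayer_frame_spec"))
    stop("'spec' must be a bilayer_frame_spec", call. = FALSE)
  n <- spec$n_lipids_per_leaflet
  t <- spec$thickness_nm; d <- spec$intermembrane_distance_nm
  zc <- spec$box_z_nm / 2
  if (spec$n_membranes == 1L) {
    layer_z <- c(zc - t / 2, zc + t / 2)
    membrane_of <- c(1L, 1L)
  } else {
    layer_z <- c(zc - d / 2 - t, zc - d / 2, zc + d / 2, zc + d / 2 + t)
    membrane_of <- c(1L, 1L, 2L, 2L)
    if (layer_z[1] < 0 || layer_z[4] > spec$box_z_nm)
      stop("box_z_nm too small for the membrane stack", call. = FALSE)
  }
  n_leaf <- length(layer_z)
  # normal: +z for the upper leaflet of each membrane, -z for the lower
  normal_of <- rep(c(-1, 1), times = spec$n_membranes)
  # leaflet class: inner = gap-facing (double systems), else outer
  class_of <- if (spec$n_membranes == 1L) c("outer", "outer")
              else c("outer", "inner", "inner", "outer")

  nxl <- ceiling(sqrt(n))
  a <- spec$box_xy_nm / nxl
  k <- seq_len(n) - 1L
  lat_x <- (k %% nxl + 0.5) * a
  lat_y <- (k %/% nxl + 0.5) * a

  with_seed(spec$seed, {
    parts <- vector("list", n_leaf + 1L)
    for (lf in seq_len(n_leaf)) {
      ns <- normal_of[lf]
      jit <- if (spec$positional_noise_nm > 0)
        matrix(rnorm(3 * n, 0, spec$positional_noise_nm), n, 3) else matrix(0, n, 3)
      px <- lat_x + jit[, 1]; py <- lat_y + jit[, 2]; pz <- layer_z[lf] + jit[, 3]
      ct <- spec$mean_tilt_cos[[class_of[lf]]]
      st <- sqrt(1 - ct^2)
      az <- runif(n, 0, 2 * pi)
      b <- spec$bond_length_nm
      nx <- px + b * st * cos(az); ny <- py + b * st * sin(az)
      nz <- pz + b * ct * ns
      lip0 <- (lf - 1L) * n
      lip <- lip0 + seq_len(n)
      rows <- list(data.frame(x = px, y = py, z = pz, role = "P", lipid = lip),
                   data.frame(x = nx, y = ny, z = nz, role = "N", lipid = lip))
      if (spec$chain_beads_per_lipid > 0L) {
        cb <- spec$chain_bond_cos; sb <- sqrt(1 - cb^2)
        s <- spec$chain_bond_length_nm
        cx <- px; cy <- py; cz <- pz
        for (j in seq_len(spec$chain_beads_per_lipid)) {
          azc <- runif(n, 0, 2 * pi)
          cx <- cx + s * sb * cos(azc); cy <- cy + s * sb * sin(azc)
          cz <- cz - s * cb * ns       # chains descend toward the midplane
          rows[[2L + j]] <- data.frame(x = cx, y = cy, z = cz, role = "C", lipid = lip)
        }
      }
      leafp <- do.call(rbind, rows)
      leafp$membrane <- membrane_of[lf]
      leafp$leaflet <- lf
      parts[[lf]] <- leafp
    }
    if (spec$n_membranes == 2L && spec$n_gap_waters > 0L) {
      nw <- spec$n_gap_waters
      parts[[n_leaf + 1L]] <- data.frame(
        x = runif(nw, 0, spec$box_xy_nm), y = runif(nw, 0, spec$box_xy_nm),
        z = runif(nw, layer_z[2] + 1e-6, layer_z[3] - 1e-6),
        role = "W", lipid = NA_integer_, membrane = NA_integer_,
        leaflet = NA_integer_)
    }
    particles <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    fr <- bilayer_frame(particles,
                        box_nm = c(spec$box_xy_nm, spec$box_xy_nm, spec$box_z_nm),
                        time_ns = time_ns)
    attr(fr, "spec") <- spec
    attr(fr, "truth") <- list(
      thickness_nm = t,
      intermembrane_distance_nm = if (spec$n_membranes == 2L) d else NA_real_,
      mean_tilt_cos = spec$mean_tilt_cos,
      chain_order_S = (3 * spec$chain_bond_cos^2 - 1) / 2,
      lateral_area_nm2 = spec$box_xy_nm^2,
      area_per_lipid_nm2 = spec$box_xy_nm^2 / n,
      gap_waters_per_nm2 = if (spec$n_membranes == 2L)
        spec$n_gap_waters / spec$box_xy_nm^2 else NA_real_)
    fr
  })
}
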