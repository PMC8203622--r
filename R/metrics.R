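#' Membrane thickness from P-atom layers
#'
#' Thickness of one membrane: absolute difference between the mean z of the
#' P particles of its upper and lower leaflets.
#'
#' @param frame a [bilayer_frame()].
#' @param assignment a [assign_leaflets()] result.
#' @param membrane_id which membrane (1-based, bottom-up).
#' @return thickness in nm.
#' @export
membrane_thickness <- function(frame, assignment, membrane_id = 1L) {
  zs <- leaflet_p_means(frame, assignment)
  lf <- assignment[assignment$membrane == membrane_id, ]
  if (!nrow(lf)) stop("no lipids in membrane ", membrane_id, call. = FALSE)
  ids <- sort(unique(lf$leaflet))
  if (length(ids) != 2L) stop("membrane ", membrane_id, " lacks two leaflets", call. = FALSE)
  abs(zs[ids[2]] - zs[ids[1]])
}

#' Inter-membrane distance
#'
#' Distance between the mean P-layer heights of the two gap-facing (inner)
#' leaflets of a double-membrane system.
#'
#' @inheritParams membrane_thickness
#' @return distance in nm.
#' @export
intermembrane_distance <- function(frame, assignment) {
  if (attr(assignment, "n_membranes") != 2L)
    stop("inter-membrane distance requires a double-membrane system", call. = FALSE)
  zs <- leaflet_p_means(frame, assignment)
  abs(zs[3] - zs[2])
}

leaflet_p_means <- function(frame, assignment) {
  p <- frame[frame$role == "P", ]
  lf <- assignment$leaflet[match(p$lipid, assignment$lipid)]
  if (anyNA(lf)) stop("assignment does not cover all lipids", call. = FALSE)
  if (any(table(lf) == 0)) stop("empty leaflet", call. = FALSE)
  as.numeric(tapply(p$z, lf, mean))
}

#' Lateral membrane area and area per lipid
#'
#' The lateral area is the x-y box cross-section; area per lipid divides it
#' by the number of lipids per leaflet.
#'
#' @inheritParams membrane_thickness
#' @return area in nm^2.
#' @export
lateral_area <- function(frame) {
  b <- box_nm(frame)
  b[1] * b[2]
}

#' @rdname lateral_area
#' @export
area_per_lipid <- function(frame, assignment) {
  n_leaf <- 2L * attr(assignment, "n_membranes")
  lateral_area(frame) / (nrow(assignment) / n_leaf)
}

#' Membrane volume
#'
#' Volume of one membrane, defined as lateral area times P-layer thickness.
#'
#' @inheritParams membrane_thickness
#' @return volume in nm^3.
#' @export
membrane_volume <- function(frame, assignment, membrane_id = 1L) {
  lateral_area(frame) * membrane_thickness(frame, assignment, membrane_id)
}

#' Headgroup tilt cosine
#'
#' Per lipid, the P-to-N vector is compared with the leaflet outward normal
#' (the z-axis, signed): `cos(phi) = (v . n) / |v|`. The vector is
#' minimum-imaged in x and y (headgroups are assumed not to wrap in z).
#'
#' @inheritParams membrane_thickness
#' @param leaflet leaflet selector: a global leaflet index (bottom-up), or
#'   `"inner"`/`"outer"` to pool the matching leaflets.
#' @return list with `mean_cos` and per-lipid `cos_phi` (named by lipid).
#' @export
headgroup_tilt <- function(frame, assignment, leaflet) {
  if (is.character(leaflet)) {
    rows <- assignment[assignment$class == leaflet, ]
    if (!nrow(rows)) stop("no leaflet of class '", leaflet, "'", call. = FALSE)
  } else {
    rows <- assignment[assignment$leaflet == leaflet, ]
    if (!nrow(rows)) stop("no leaflet ", leaflet, call. = FALSE)
  }
  v <- headgroup_vectors(frame, rows$lipid)
  vn <- v$vz * rows$normal[match(v$lipid, rows$lipid)]
  len <- sqrt(v$vx^2 + v$vy^2 + v$vz^2)
  if (any(len == 0)) stop("coincident P and N particles", call. = FALSE)
  cosphi <- vn / len
  names(cosphi) <- v$lipid
  list(mean_cos = mean(cosphi), cos_phi = cosphi)
}

# P->N vectors for the given lipids, minimum-imaged in x,y.
headgroup_vectors <- function(frame, lipids) {
  b <- box_nm(frame)
  p <- frame[frame$role == "P" & frame$lipid %in% lipids, ]
  nn <- frame[frame$role == "N" & frame$lipid %in% lipids, ]
  nn <- nn[match(p$lipid, nn$lipid), ]
  dx <- min_image(nn$x - p$x, b[1])
  dy <- min_image(nn$y - p$y, b[2])
  list(lipid = p$lipid, vx = dx, vy = dy, vz = nn$z - p$z)
}

min_image <- function(d, L) d - L * round(d / L)

#' Chain order parameter per bond
#'
#' The standard second-Legendre order parameter
#' `S = (3 <cos^2 theta> - 1) / 2` of each successive chain bond (P to first
#' bead, then bead to bead) relative to the membrane normal (z-axis),
#' averaged over all lipids.
#'
#' @inheritParams membrane_thickness
#' @return numeric vector, one `S` per bond index.
#' @export
chain_order <- function(frame, assignment) {
  b <- box_nm(frame)
  ch <- frame[frame$role %in% c("P", "C"), ]
  ch <- ch[!is.na(ch$lipid), ]
  ch <- ch[order(ch$lipid, match(ch$role, c("P", "C")),
                 seq_len(nrow(ch))), ]     # P first, then beads in file order
  sp <- split(seq_len(nrow(ch)), ch$lipid)
  nb <- vapply(sp, length, integer(1)) - 1L
  if (all(nb <= 0)) stop("no chain beads in frame", call. = FALSE)
  maxb <- max(nb)
  s_sum <- numeric(maxb); s_n <- integer(maxb)
  for (idx in sp) {
    if (length(idx) < 2L) next
    dx <- min_image(diff(ch$x[idx]), b[1])
    dy <- min_image(diff(ch$y[idx]), b[2])
    dz <- diff(ch$z[idx])
    c2 <- dz^2 / (dx^2 + dy^2 + dz^2)
    j <- seq_along(c2)
    s_sum[j] <- s_sum[j] + (3 * c2 - 1) / 2
    s_n[j] <- s_n[j] + 1L
  }
  s_sum / s_n
}

#' Water density in the inter-membrane gap
#'
#' Number of water-oxygen particles whose z lies strictly between the mean
#' P layers of the two gap-facing leaflets, per nm^2 of lateral area.
#'
#' @inheritParams membrane_thickness
#' @return waters per nm^2.
#' @export
waters_in_gap <- function(frame, assignment) {
  if (attr(assignment, "n_membranes") != 2L)
    stop("gap hydration requires a double-membrane system", call. = FALSE)
  zs <- leaflet_p_means(frame, assignment)
  w <- frame[frame$role == "W", ]
  lo <- min(zs[2], zs[3]); hi <- max(zs[2], zs[3])
  sum(w$z > lo & w$z < hi) / lateral_area(frame)
}

#' Leaflet-internal electrostatic energy
#'
#' Sum of Coulomb pair energies between all charged lipid particles within
#' each leaflet, with a real-space cutoff and minimum-image convention in x
#' and y: `E = sum_(i<j, r_ij <= cutoff) f q_i q_j / r_ij` with
#' `f = 138.935` kJ mol^-1 nm e^-2. All intra-leaflet pairs are included
#' (no bonded exclusions). In double systems the two gap-facing and the two
#' solvent-facing leaflet energies are additionally averaged.
#'
#' @inheritParams membrane_thickness
#' @param charges named numeric vector of partial charges (e) per role
#'   (`P`, `N`, `C`, `W`). Defaults to the charges stored in the frame's
#'   generator spec, if present.
#' @param cutoff_nm real-space cutoff (nm), default 1.2.
#' @return list: `per_leaflet` (kJ/mol, named by leaflet index),
#'   `inner_mean`, `outer_mean` (the latter two `NA` for single membranes
#'   except `outer_mean`, the mean over both leaflets).
#' @export
leaflet_electrostatic_energy <- function(frame, assignment, charges = NULL,
                                         cutoff_nm = 1.2) {
  stopifnot_scalar(cutoff_nm, "cutoff_nm", positive = TRUE)
  if (is.null(charges)) {
    sp <- attr(frame, "spec")
    if (!is.null(sp)) charges <- sp$charges
  }
  if (is.null(charges)) stop("'charges' must be supplied", call. = FALSE)
  b <- box_nm(frame)
  lp <- frame[frame$role != "W", ]
  miss <- setdiff(unique(lp$role), names(charges))
  if (length(miss))
    stop("missing charge for role(s): ", paste(miss, collapse = ", "), call. = FALSE)
  lf_of <- assignment$leaflet[match(lp$lipid, assignment$lipid)]
  k <- 2L * attr(assignment, "n_membranes")
  e <- vapply(seq_len(k), function(lf) {
    sub <- lp[lf_of == lf, ]
    q <- unname(charges[sub$role])
    keep <- q != 0
    coulomb_sum(sub$x[keep], sub$y[keep], sub$z[keep], q[keep], b, cutoff_nm)
  }, numeric(1))
  names(e) <- seq_len(k)
  if (k == 4L) {
    list(per_leaflet = e, inner_mean = mean(e[2:3]), outer_mean = mean(e[c(1, 4)]))
  } else {
    list(per_leaflet = e, inner_mean = NA_real_, outer_mean = mean(e))
  }
}

# Direct cutoff Coulomb sum over all i<j pairs, minimum image in x,y.
coulomb_sum <- function(x, y, z, q, box, cutoff) {
  n <- length(x)
  if (n < 2L) return(0)
  f <- 138.935                      # kJ mol^-1 nm e^-2
  dx <- min_image(outer(x, x, `-`), box[1])
  dy <- min_image(outer(y, y, `-`), box[2])
  dz <- outer(z, z, `-`)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  qq <- outer(q, q)
  m <- upper.tri(r) & r <= cutoff
  f * sum(qq[m] / r[m])
}

#' Per-frame membrane metrics table
#'
#' Computes the full per-frame observable set: one row per membrane with
#' thickness, lateral area, area per lipid, volume, mean headgroup tilt
#' cosine per leaflet side, mean chain order, and (double systems)
#' inter-membrane distance and gap hydration.
#'
#' @inheritParams membrane_thickness
#' @param n_membranes used when `assignment` is `NULL`.
#' @param assignment optional precomputed [assign_leaflets()] result.
#' @return data.frame, one row per membrane.
#' @export
membrane_metrics <- function(frame, n_membranes = 1L, assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_leaflets(frame, n_membranes)
  nm <- attr(assignment, "n_membranes")
  dist <- if (nm == 2L) intermembrane_distance(frame, assignment) else NA_real_
  gapw <- if (nm == 2L) waters_in_gap(frame, assignment) else NA_real_
  s_mean <- mean(chain_order(frame, assignment))
  rows <- lapply(seq_len(nm), function(m) {
    lfs <- sort(unique(assignment$leaflet[assignment$membrane == m]))
    th <- membrane_thickness(frame, assignment, m)
    data.frame(time_ns = attr(frame, "time_ns"), membrane = m,
               thickness_nm = th,
               lateral_area_nm2 = lateral_area(frame),
               area_per_lipid_nm2 = area_per_lipid(frame, assignment),
               volume_nm3 = lateral_area(frame) * th,
               cos_phi_lower = headgroup_tilt(frame, assignment, lfs[1])$mean_cos,
               cos_phi_upper = headgroup_tilt(frame, assignment, lfs[2])$mean_cos,
               chain_order_S = s_mean,
               intermembrane_distance_nm = dist,
               gap_waters_per_nm2 = gapw)
  })
  do.call(rbind, rows)
}
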