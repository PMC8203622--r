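#' Headgroup angle restraint
#'
#' The bias potential `E(phi) = k * (1 - cos(phi - phi0))` on the angle
#' `phi` between the P-to-N headgroup vector and the membrane normal
#' (+z axis). The energy is non-negative, 2*pi-periodic, zero at
#' `phi = phi0` and maximal (`2k`) at `phi = phi0 + pi`. Placing `phi0` at
#' 90 degrees biases headgroups towards the membrane plane; `phi0 = 0`
#' biases them along the normal.
#'
#' @param k force constant (kJ/mol, >= 0); useful biasing strengths span
#'   roughly 0.5-30 kJ/mol.
#' @param phi0 location of the potential minimum (radians, in `[0, pi]`).
#' @return An `angle_restraint` list.
#' @export
angle_restraint <- function(k, phi0) {
  stopifnot_scalar(k, "k", nonneg = TRUE)
  stopifnot_scalar(phi0, "phi0")
  if (phi0 < 0 || phi0 > pi) stop("phi0 must lie in [0, pi]", call. = FALSE)
  structure(list(k = k, phi0 = phi0), class = "angle_restraint")
}

#' @rdname angle_restraint
#' @param phi angle(s) in radians.
#' @param restraint an [angle_restraint()].
#' @return `restraint_energy`: energy in kJ/mol (vectorised over `phi`).
#' @export
restraint_energy <- function(phi, restraint) {
  restraint$k * (1 - cos(phi - restraint$phi0))
}

#' Analytic restraint forces on the P and N particles
#'
#' Negative gradient of [restraint_energy()] with respect to both particle
#' positions, where `phi` is the angle of the P-to-N vector to +z. The
#' angle depends only on the relative vector, so the forces on P and N are
#' equal and opposite (zero net force).
#'
#' @param p_pos,n_pos length-3 positions (nm) of the P and N particles.
#' @param restraint an [angle_restraint()].
#' @return list: `force_p`, `force_n` (kJ/mol/nm), `phi` (radians),
#'   `energy` (kJ/mol).
#' @export
restraint_forces <- function(p_pos, n_pos, restraint) {
  v <- as.numeric(n_pos) - as.numeric(p_pos)
  r <- sqrt(sum(v^2))
  if (r < .Machine$double.eps) stop("coincident P and N particles", call. = FALSE)
  cphi <- v[3] / r
  cphi <- max(-1, min(1, cphi))
  phi <- acos(cphi)
  sphi <- sqrt(max(0, 1 - cphi^2))
  dEdphi <- restraint$k * sin(phi - restraint$phi0)
  if (sphi < 1e-10) {
    if (abs(dEdphi) < 1e-10) {
      fn <- c(0, 0, 0)                  # flat at the pole (phi0 at 0 or pi)
    } else {
      stop("gradient undefined at the pole (phi = 0 or pi) for this phi0",
           call. = FALSE)
    }
  } else {
    # dphi/dv = -(e_z - cos(phi) v / r) / (r sin(phi))
    dphidv <- -(c(0, 0, 1) - cphi * v / r) / (r * sphi)
    fn <- -dEdphi * dphidv              # force on N = -dE/dn
  }
  list(force_p = -fn, force_n = fn, phi = phi,
       energy = restraint_energy(phi, restraint))
}

#' Toy overdamped relaxation of headgroup orientations under a restraint
#'
#' A deliberately simple demonstration dynamics (not molecular dynamics):
#' each lipid's headgroup direction is a unit vector confined to the
#' outward hemisphere, evolving by overdamped gradient descent on the
#' restraint energy plus tangential thermal noise, with the P-N bond length
#' fixed (orientation-only update). It produces bias-driven tilt time
#' series suitable as input to the relaxation-kinetics stage. With `k = 0`
#' the stationary distribution is uniform on the hemisphere
#' (mean cos phi = 1/2); with a strong restraint at `phi0 = 0` the mean cos
#' approaches 1.
#'
#' @param n_lipids number of independent orientations.
#' @param restraint an [angle_restraint()].
#' @param friction friction coefficient `gamma` (kJ mol^-1 ns nm^-2 scale;
#'   sets the time unit together with `dt_ns`).
#' @param kT_kJ_mol thermal energy (default 2.494, i.e. 300 K).
#' @param dt_ns time step (ns).
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param init_cos initial tilt cosine for all lipids (default: uniform on
#'   the hemisphere).
#' @return data.frame with `time_ns` and `mean_cos_phi`; the per-lipid
#'   cosine trajectory is in `attr(, "cos_phi")` (time x lipid).
#' @export
demo_tilt_relaxation <- function(n_lipids, restraint, friction = 1,
                                 kT_kJ_mol = 2.494, dt_ns = 1e-4,
                                 n_steps = 1000L, seed = NULL,
                                 init_cos = NULL) {
  stopifnot_scalar(friction, "friction", positive = TRUE)
  stopifnot_scalar(dt_ns, "dt_ns", positive = TRUE)
  with_seed(seed, {
    if (is.null(init_cos)) {
      cz <- runif(n_lipids)               # uniform on the hemisphere
    } else {
      cz <- rep(init_cos, length.out = n_lipids)
    }
    az <- runif(n_lipids, 0, 2 * pi)
    sz <- sqrt(1 - cz^2)
    u <- cbind(sz * cos(az), sz * sin(az), cz)
    amp <- sqrt(2 * kT_kJ_mol * dt_ns / friction)
    cosmat <- matrix(NA_real_, n_steps + 1L, n_lipids)
    cosmat[1L, ] <- u[, 3]
    for (s in seq_len(n_steps)) {
      cphi <- pmin(1, pmax(-1, u[, 3]))
      sphi <- sqrt(pmax(1e-12, 1 - cphi^2))
      phi <- acos(cphi)
      # gradient of E wrt u (depends on u_z only), then project tangentially
      gz <- restraint$k * sin(phi - restraint$phi0) * (-1 / sphi)
      g <- cbind(0, 0, gz)
      gdotu <- gz * u[, 3]
      gt <- g - gdotu * u
      eta <- matrix(rnorm(3 * n_lipids), n_lipids, 3)
      eta <- eta - rowSums(eta * u) * u   # tangential noise
      u <- u - gt * (dt_ns / friction) + amp * eta
      u <- u / sqrt(rowSums(u^2))
      u[, 3] <- abs(u[, 3])               # reflect at the membrane plane
      cosmat[s + 1L, ] <- u[, 3]
    }
    out <- data.frame(time_ns = (0:n_steps) * dt_ns,
                      mean_cos_phi = rowMeans(cosmat))
    attr(out, "cos_phi") <- cosmat
    out
  })
}
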