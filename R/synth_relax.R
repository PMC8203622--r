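#' Specification for a synthetic relaxation ensemble
#'
#' Replica sets of observable time series following the single-exponential
#' relaxation `f(t) = x_inf + (x0 - x_inf) * exp(-t / tau)` plus iid
#' additive Gaussian noise. The default observables and time constants
#' emulate the equilibration of two apposed single bilayers into a
#' double-membrane stack: headgroup tilt relaxes first, then area, then
#' thickness. Default sampling is 1 ns at 1 ps intervals over 500 replicas.
#'
#' @param observables named list; each element a list/vector with `x0`,
#'   `x_inf`, `tau_ns` for one observable.
#' @param dt_ns sampling interval (ns).
#' @param duration_ns series duration (ns); should span several tau.
#' @param noise_sigma additive Gaussian noise SD (observable units).
#' @param n_replicas number of independent replicas.
#' @param seed integer master seed; each replica draws from an independent
#'   sub-stream so subsets are reproducible.
#' @return A `relaxation_ensemble_spec` list.
#' @export
relaxation_ensemble_spec <- function(observables = list(
                                       tilt = c(x0 = 0, x_inf = 1, tau_ns = 0.05),
                                       area = c(x0 = 0, x_inf = 1, tau_ns = 0.15),
                                       thickness = c(x0 = 0, x_inf = 1, tau_ns = 0.40)),
                                     dt_ns = 0.001,
                                     duration_ns = 1,
                                     noise_sigma = 0.05,
                                     n_replicas = 500L,
                                     seed = NULL) {
  stopifnot_scalar(dt_ns, "dt_ns", positive = TRUE)
  stopifnot_scalar(duration_ns, "duration_ns", positive = TRUE)
  stopifnot_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 1L) stop("n_replicas must be >= 1", call. = FALSE)
  if (!length(names(observables)) || anyNA(names(observables)))
    stop("observables must be named", call. = FALSE)
  for (nm in names(observables)) {
    ob <- as.list(observables[[nm]])
    if (!all(c("x0", "x_inf", "tau_ns") %in% names(ob)))
      stop("observable '", nm, "' needs x0, x_inf, tau_ns", call. = FALSE)
    if (ob$tau_ns <= 0) stop("tau must be > 0 for '", nm, "'", call. = FALSE)
    observables[[nm]] <- ob
  }
  structure(list(observables = observables, dt_ns = dt_ns,
                 duration_ns = duration_ns, noise_sigma = noise_sigma,
                 n_replicas = n_replicas, seed = seed),
            class = "relaxation_ensemble_spec")
}

#' Generate a synthetic relaxation ensemble
#'
#' @param spec a [relaxation_ensemble_spec()].
#' @return A `relaxation_ensemble` list: `time_ns` (shared grid) and
#'   `observables`, a named list of `n_time x n_replicas` matrices. The
#'   spec travels along as attribute `spec`.
#' @export
generate_relaxation_ensemble <- function(spec) {
  if (!inherits(spec, "relaxation_ensemble_spec"))
    stop("'spec' must be a relaxation_ensemble_spec", call. = FALSE)
  times <- seq(0, spec$duration_ns, by = spec$dt_ns)
  nt <- length(times)
  seeds <- substream_seeds(spec$seed, spec$n_replicas)
  obs <- lapply(spec$observables, function(ob) {
    clean <- relaxation_curve(times, ob$x0, ob$x_inf, ob$tau_ns)
    m <- matrix(clean, nt, spec$n_replicas)
    m
  })
  if (spec$noise_sigma > 0) {
    for (r in seq_len(spec$n_replicas)) {
      noise <- with_seed(seeds[r],
        matrix(rnorm(nt * length(obs), 0, spec$noise_sigma), nt, length(obs)))
      for (k in seq_along(obs)) obs[[k]][, r] <- obs[[k]][, r] + noise[, k]
    }
  }
  structure(list(time_ns = times, observables = obs),
            spec = spec, class = "relaxation_ensemble")
}

#' The exponential relaxation curve
#'
#' `f(t) = x_inf + (x0 - x_inf) * exp(-t / tau)`: value `x0` at `t = 0`
#' relaxing to `x_inf` with time constant `tau`.
#'
#' @param t_ns times (ns).
#' @param x0 initial value.
#' @param x_inf equilibrium value.
#' @param tau_ns relaxation time constant (ns, > 0).
#' @return numeric vector of curve values.
#' @export
relaxation_curve <- function(t_ns, x0, x_inf, tau_ns) {
  stopifnot_scalar(tau_ns, "tau_ns", positive = TRUE)
  x_inf + (x0 - x_inf) * exp(-t_ns / tau_ns)
}
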