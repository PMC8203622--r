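#' Fit an exponential relaxation to one time series
#'
#' Nonlinear least squares of `f(t) = x_inf + (x0 - x_inf) * exp(-t / tau)`
#' over `(x0, x_inf, tau)` with `tau` bounded positive
#' (Levenberg-Marquardt). Initial values are derivative-free: `x0` from the
#' first sample, `x_inf` from the mean of the last 10% of samples, `tau`
#' from the time at which the series first traverses 63% of the gap between
#' them. Fits that fail to converge (or that are unidentifiable, e.g. a
#' constant series) return `converged = FALSE` rather than throwing.
#'
#' @param times_ns strictly increasing sample times (ns), length >= 5.
#' @param values observable values.
#' @return A `relaxation_fit` list: `x0`, `x_inf`, `tau_ns`, `rms`
#'   (residual RMS), `converged`.
#' @export
fit_relaxation <- function(times_ns, values) {
  if (length(times_ns) < 5L) stop("need at least 5 samples", call. = FALSE)
  if (length(times_ns) != length(values)) stop("length mismatch", call. = FALSE)
  if (any(diff(times_ns) <= 0)) stop("times must be strictly increasing", call. = FALSE)

  fail <- structure(list(x0 = NA_real_, x_inf = NA_real_, tau_ns = NA_real_,
                         rms = NA_real_, converged = FALSE),
                    class = "relaxation_fit")
  if (sd(values) == 0) return(fail)       # tau unidentifiable

  x0_i <- values[1]
  n <- length(values)
  x_inf_i <- mean(values[max(1L, ceiling(0.9 * n)):n])
  gap <- x_inf_i - x0_i
  if (abs(gap) < .Machine$double.eps) {
    tau_i <- diff(range(times_ns)) / 3
  } else {
    crossed <- which(abs(values - x0_i) >= 0.63 * abs(gap))
    tau_i <- if (length(crossed)) max(times_ns[crossed[1]] - times_ns[1],
                                      diff(times_ns)[1])
             else diff(range(times_ns)) / 3
  }

  dat <- data.frame(t = times_ns - times_ns[1], y = values)
  fit <- try(minpack.lm::nlsLM(
    y ~ x_inf + (x0 - x_inf) * exp(-t / tau), data = dat,
    start = list(x0 = x0_i, x_inf = x_inf_i, tau = tau_i),
    lower = c(-Inf, -Inf, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(fail)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["tau"]] <= 0) return(fail)
  structure(list(x0 = unname(cf[["x0"]]), x_inf = unname(cf[["x_inf"]]),
                 tau_ns = unname(cf[["tau"]]),
                 rms = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<relaxation_fit> x0 %.4g -> x_inf %.4g, tau %.4g ns (rms %.3g)\n",
                x$x0, x$x_inf, x$tau_ns, x$rms))
  else cat("<relaxation_fit> not converged\n")
  invisible(x)
}

#' Normalise a series between single- and double-bilayer endpoints
#'
#' Affine map sending the equilibrated single-bilayer value to 0 and the
#' equilibrated double-bilayer value to 1:
#' `y = (x - x_single) / (x_double - x_single)`.
#'
#' @param x numeric series.
#' @param x_single equilibrated single-bilayer value (maps to 0).
#' @param x_double equilibrated double-bilayer value (maps to 1).
#' @return normalised series.
#' @export
normalize_endpoints <- function(x, x_single, x_double) {
  if (x_single == x_double)
    stop("endpoints are equal; normalisation undefined", call. = FALSE)
  (x - x_single) / (x_double - x_single)
}

#' Pointwise ensemble mean and SD
#'
#' @param replicas matrix (time x replica) or list of equal-length numeric
#'   vectors sharing one time grid.
#' @return list with `mean` and `sd` vectors (sample SD; `NA` for a single
#'   replica).
#' @export
ensemble_average <- function(replicas) {
  if (is.list(replicas) && !is.matrix(replicas))
    replicas <- do.call(cbind, replicas)
  if (!is.matrix(replicas)) replicas <- matrix(replicas, ncol = 1)
  list(mean = rowMeans(replicas),
       sd = apply(replicas, 1, sd))
}

#' Fit every replica of an ensemble
#'
#' @param ensemble a [generate_relaxation_ensemble()] result, or a list with
#'   `time_ns` and `observables` (matrices time x replica).
#' @return data.frame with one row per (observable, replica): `observable`,
#'   `replica`, `x0`, `x_inf`, `tau_ns`, `rms`, `converged`.
#' @export
fit_ensemble <- function(ensemble) {
  rows <- lapply(names(ensemble$observables), function(nm) {
    m <- ensemble$observables[[nm]]
    do.call(rbind, lapply(seq_len(ncol(m)), function(r) {
      f <- fit_relaxation(ensemble$time_ns, m[, r])
      data.frame(observable = nm, replica = r, x0 = f$x0, x_inf = f$x_inf,
                 tau_ns = f$tau_ns, rms = f$rms, converged = f$converged)
    }))
  })
  do.call(rbind, rows)
}

#' Order relaxation time constants across observables
#'
#' Takes per-replica fitted time constants for each observable, reports the
#' median tau (diverged fits excluded but counted), and assesses each
#' pairwise order `tau_a < tau_b` by bootstrap over replicas: the support
#' for a pair is the fraction of resamples in which the median tau of `a`
#' is smaller than that of `b`. A full ordering is declared only when every
#' pairwise support along it reaches `support_threshold`. The bootstrap is
#' this package's uncertainty layer over the plain median comparison.
#'
#' @param fits a [fit_ensemble()] data.frame, or a named list of numeric
#'   tau vectors per observable.
#' @param n_bootstrap bootstrap resamples (0 with single replicas:
#'   supports undefined).
#' @param seed RNG seed for resampling.
#' @param support_threshold minimum pairwise support to declare an order.
#' @return An `ordering_result` list: `median_tau_ns`, `n_converged`,
#'   `n_diverged`, `support` (named `a<b` fractions, `NA` if undefined),
#'   `ordering` (character vector of observable names, fastest first, or
#'   `NULL` when not declared), `declared`.
#' @export
tau_ordering <- function(fits, n_bootstrap = 1000L, seed = NULL,
                         support_threshold = 0.95) {
  if (is.data.frame(fits)) {
    taus <- split(fits$tau_ns[fits$converged], fits$observable[fits$converged])
    n_div <- tapply(!fits$converged, fits$observable, sum)
    # preserve first-appearance order of observables
    ord_names <- unique(fits$observable)
    taus <- taus[ord_names]
    n_div <- n_div[ord_names]
  } else {
    taus <- lapply(fits, function(x) x[is.finite(x)])
    n_div <- vapply(fits, function(x) sum(!is.finite(x)), numeric(1))
  }
  if (length(taus) < 2L) stop("need at least two observables", call. = FALSE)
  empty <- vapply(taus, length, integer(1)) == 0L
  if (any(empty))
    stop("all fits diverged for: ", paste(names(taus)[empty], collapse = ", "),
         call. = FALSE)

  med <- vapply(taus, median, numeric(1))
  nms <- names(taus)[order(med)]

  pairs <- utils::combn(names(taus), 2, simplify = FALSE)
  can_boot <- all(vapply(taus, length, integer(1)) >= 2L) && n_bootstrap > 0L
  if (can_boot) {
    boot_med <- with_seed(seed, {
      vapply(taus, function(tv) {
        n <- length(tv)
        idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), n)
        apply(matrix(tv[idx], n), 2, median)
      }, numeric(n_bootstrap))
    })
    support <- vapply(pairs, function(pr) {
      a <- pr[1]; b <- pr[2]
      if (med[a] > med[b]) { a <- pr[2]; b <- pr[1] }
      mean(boot_med[, a] < boot_med[, b])
    }, numeric(1))
    names(support) <- vapply(pairs, function(pr) {
      if (med[pr[1]] <= med[pr[2]]) paste(pr[1], pr[2], sep = " < ")
      else paste(pr[2], pr[1], sep = " < ")
    }, character(1))
    declared <- all(support >= support_threshold)
  } else {
    support <- stats::setNames(rep(NA_real_, length(pairs)),
                               vapply(pairs, paste, character(1), collapse = " ? "))
    declared <- FALSE
  }

  structure(list(median_tau_ns = med,
                 n_converged = vapply(taus, length, integer(1)),
                 n_diverged = as.integer(n_div),
                 support = support,
                 ordering = if (declared) nms else NULL,
                 declared = declared,
                 support_threshold = support_threshold),
            class = "ordering_result")
}

#' @export
print.ordering_result <- function(x, ...) {
  cat("<ordering_result> median tau (ns):",
      paste(sprintf("%s=%.4g", names(x$median_tau_ns), x$median_tau_ns),
            collapse = ", "), "\n")
  if (x$declared)
    cat("declared ordering:", paste(x$ordering, collapse = " < "),
        sprintf("(all pairwise supports >= %.2f)\n", x$support_threshold))
  else cat("no ordering declared at support threshold",
           x$support_threshold, "\n")
  invisible(x)
}
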