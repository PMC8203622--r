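test_that("noise-free ensembles equal the closed form everywhere", {
  sp <- relaxation_ensemble_spec(noise_sigma = 0, n_replicas = 3L,
                                 dt_ns = 0.01, duration_ns = 0.5, seed = 1)
  ens <- generate_relaxation_ensemble(sp)
  for (nm in names(ens$observables)) {
    ob <- sp$observables[[nm]]
    clean <- relaxation_curve(ens$time_ns, ob$x0, ob$x_inf, ob$tau_ns)
    for (r in 1:3)
      expect_equal(ens$observables[[nm]][, r], clean, tolerance = 1e-15)
  }
})

test_that("the ensemble mean tracks the closed form within sampling error", {
  sp <- relaxation_ensemble_spec(noise_sigma = 0.05, n_replicas = 500L,
                                 dt_ns = 0.02, duration_ns = 1, seed = 2)
  ens <- generate_relaxation_ensemble(sp)
  avg <- ensemble_average(ens$observables$tilt)
  clean <- relaxation_curve(ens$time_ns, 0, 1, 0.05)
  expect_true(all(abs(avg$mean - clean) <= 3 * 0.05 / sqrt(500)))
})

test_that("single-replica ensembles and invalid taus behave as contracted", {
  ens <- generate_relaxation_ensemble(relaxation_ensemble_spec(
    n_replicas = 1L, dt_ns = 0.01, duration_ns = 0.2, seed = 3))
  expect_equal(ncol(ens$observables$tilt), 1L)
  expect_error(relaxation_ensemble_spec(observables = list(
    tilt = c(x0 = 0, x_inf = 1, tau_ns = -1))), "tau")
})

test_that("exact series are recovered to 1e-6 relative", {
  t <- seq(0, 1, by = 0.01)
  y <- relaxation_curve(t, 1, 0, 0.2)
  f <- fit_relaxation(t, y)
  expect_true(f$converged)
  expect_equal(f$x0, 1, tolerance = 1e-6)
  expect_equal(f$x_inf, 0, tolerance = 1e-6)
  expect_equal(f$tau_ns, 0.2, tolerance = 1e-6)
  expect_lt(f$rms, 1e-8)
})

test_that("unidentifiable or malformed series are handled", {
  expect_false(fit_relaxation(seq(0, 1, 0.1), rep(2, 11))$converged)
  expect_error(fit_relaxation(1:4, 1:4), "5 samples")
  expect_error(fit_relaxation(c(0, 1, 1, 2, 3), rnorm(5)), "increasing")
})

test_that("tau is recovered within 10% in at least 95% of noisy repeats", {
  t <- seq(0, 1, by = 0.0001)               # 0.1 ps sampling over 1 ns
  clean <- relaxation_curve(t, 0, 1, 0.15)
  ok <- vapply(1:100, function(i) {
    set.seed(6000 + i)
    f <- fit_relaxation(t, clean + rnorm(length(t), 0, 0.05))
    f$converged && abs(f$tau_ns - 0.15) / 0.15 <= 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("endpoint normalisation maps the endpoints to 0 and 1", {
  expect_equal(normalize_endpoints(3.9, x_single = 3.9, x_double = 4.4), 0)
  expect_equal(normalize_endpoints(4.4, x_single = 3.9, x_double = 4.4), 1)
  expect_error(normalize_endpoints(1, 2, 2), "equal")
})

test_that("normalisation is affine-invariant and exactly invertible", {
  x <- c(3.9, 4.0, 4.15, 4.35, 4.4)
  a <- 2.7; b <- -1.3
  y1 <- normalize_endpoints(x, 3.9, 4.4)
  y2 <- normalize_endpoints(a * x + b, a * 3.9 + b, a * 4.4 + b)
  expect_equal(y1, y2, tolerance = 1e-12)
  back <- y1 * (4.4 - 3.9) + 3.9
  expect_identical(back, x)
})

test_that("ensemble averaging follows its definition", {
  m <- cbind(rep(0.3, 5), rep(0.3, 5))
  expect_equal(ensemble_average(m)$sd, rep(0, 5))
  two <- ensemble_average(cbind(0, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5))
  m2 <- matrix(rnorm(20), 4, 5)
  expect_equal(ensemble_average(m2), ensemble_average(m2[, 5:1]))
})

test_that("well-separated taus yield a declared ordering with high support", {
  ens <- generate_relaxation_ensemble(relaxation_ensemble_spec(
    n_replicas = 200L, seed = 7))
  fits <- fit_ensemble(ens)
  expect_true(all(fits$converged))
  ord <- tau_ordering(fits, n_bootstrap = 500L, seed = 8)
  expect_true(ord$declared)
  expect_equal(ord$ordering, c("tilt", "area", "thickness"))
  expect_true(all(ord$support >= 0.95))
})

test_that("equal taus do not earn a declared ordering", {
  ens <- generate_relaxation_ensemble(relaxation_ensemble_spec(
    observables = list(tilt = c(x0 = 0, x_inf = 1, tau_ns = 0.15),
                       area = c(x0 = 0, x_inf = 1, tau_ns = 0.15),
                       thickness = c(x0 = 0, x_inf = 1, tau_ns = 0.15)),
    n_replicas = 60L, dt_ns = 0.01, noise_sigma = 0.05, seed = 9))
  ord <- tau_ordering(fit_ensemble(ens), n_bootstrap = 500L, seed = 10)
  expect_false(ord$declared)
})

test_that("single replicas give point medians without supports", {
  ord <- tau_ordering(list(tilt = 0.05, area = 0.15, thickness = 0.4),
                      n_bootstrap = 500L, seed = 1)
  expect_equal(unname(ord$median_tau_ns), c(0.05, 0.15, 0.4))
  expect_true(all(is.na(ord$support)))
  expect_false(ord$declared)
})

test_that("fully diverged observables are an error", {
  expect_error(tau_ordering(list(tilt = c(0.1, 0.2), area = c(NA_real_, NA_real_))),
               "diverged")
})
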