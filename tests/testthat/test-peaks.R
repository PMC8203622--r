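test_that("two-Gaussian peaks are refined to sub-sample precision", {
  prof <- gaussian_profile(c(10, 14), sigma = 1, spacing = 1, n = 40)
  oracle <- dense_maxima(function(x)
    exp(-(x - 10)^2 / 2) + exp(-(x - 14)^2 / 2), 5, 19)
  expect_length(oracle, 2L)
  pk <- detect_headgroup_peaks(prof, smoothing_sigma_px = 0)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$position_nm, oracle, tolerance = 0.1)
})

test_that("single Gaussian gives one peak, flat profile none", {
  one <- gaussian_profile(12, sigma = 1.5, n = 30)
  expect_equal(nrow(detect_headgroup_peaks(one)), 1L)
  flat <- intensity_profile(0:19, rep(2, 20))
  expect_equal(nrow(detect_headgroup_peaks(flat)), 0L)
})

test_that("minimum separation keeps only the more prominent peak", {
  prof <- gaussian_profile(c(10, 10.6), sigma = 0.4, n = 30,
                           amplitudes = c(1, 0.8))
  pk <- detect_headgroup_peaks(prof, smoothing_sigma_px = 0,
                               min_separation_nm = 1)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position_nm - 10), 0.2)
})

test_that("low-prominence ripples are rejected", {
  pos <- 0:63
  y <- exp(-(pos - 30)^2 / 8) + 0.01 * sin(pos)
  pk <- detect_headgroup_peaks(intensity_profile(pos, y),
                               smoothing_sigma_px = 0,
                               min_prominence_frac = 0.1)
  expect_equal(nrow(pk), 1L)
})

test_that("thickness from two peaks is their separation", {
  # peaks at sample 10 and 14 on a 0.5 nm grid -> 2.0 nm apart
  prof <- gaussian_profile(c(5, 7), sigma = 0.5, spacing = 0.5, n = 40)
  tm <- measure_thickness(prof, "free", smoothing_sigma_px = 0)
  expect_true(tm$resolved)
  expect_equal(tm$thickness_nm, 2.0, tolerance = 5e-3)  # ridge-overlap pull
})

test_that("tight interface with 4.5 nm membranes measures 4.5 per membrane", {
  b <- generate_vesicle_pair_image(vesicle_image_spec(
    docking_type = "tight", membrane_thickness_nm = 3.9,
    interface_thickening_nm = 0.6, seed = 5))
  tm <- measure_synthetic_image(b, pipeline_config())
  expect_equal(nrow(tm), 2L)
  expect_true(all(tm$resolved))
  expect_equal(tm$thickness_nm, c(4.5, 4.5), tolerance = 0.25 / 4.5)
})

test_that("sub-resolution proximal ridges merge and are flagged unresolved", {
  sg <- 0.6
  gap <- 1.0                              # below the 2*sigma merging limit
  # dense analytic oracle: the two proximal ridges form a single maximum
  f <- function(x) exp(-(x - gap / 2)^2 / (2 * sg^2)) +
                   exp(-(x + gap / 2)^2 / (2 * sg^2))
  expect_length(dense_maxima(f, -3, 3), 1L)

  b <- generate_vesicle_pair_image(vesicle_image_spec(
    docking_type = "tight", interface_gap_nm = gap,
    headgroup_ridge_sigma_nm = sg, noise_sigma = 0))
  tm <- measure_synthetic_image(b, pipeline_config())
  expect_false(any(tm$resolved))
  expect_true(all(is.na(tm$thickness_nm)))
  expect_lt(tm$n_peaks[1], 4L)
})

test_that("free context with fewer than two peaks is unresolved", {
  one <- gaussian_profile(12, sigma = 1.5, n = 30)
  tm <- measure_thickness(one, "free")
  expect_false(tm$resolved)
  expect_true(is.na(tm$thickness_nm))
})

test_that("thickness estimator bias shrinks with pixel size", {
  bias_at <- function(px) {
    b <- generate_vesicle_pair_image(vesicle_image_spec(
      image_size_px = as.integer(128 / px), pixel_size_nm = px,
      docking_type = "free", noise_sigma = 0))
    tm <- measure_synthetic_image(b, pipeline_config())
    abs(tm$thickness_nm - 4.0)
  }
  expect_lt(bias_at(0.25), bias_at(0.5) + 1e-9)
  expect_lt(bias_at(0.25), 0.25 / 2)
})
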