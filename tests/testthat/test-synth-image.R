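test_that("same spec and seed render bit-identical images", {
  sp <- vesicle_image_spec(docking_type = "tight", seed = 42)
  b1 <- generate_vesicle_pair_image(sp)
  b2 <- generate_vesicle_pair_image(sp)
  expect_identical(unclass(b1$density), unclass(b2$density))
  expect_identical(unclass(b1$protein), unclass(b2$protein))
  b3 <- generate_vesicle_pair_image(vesicle_image_spec(docking_type = "tight",
                                                       seed = 43))
  expect_false(identical(unclass(b1$density), unclass(b3$density)))
})

test_that("noise-free free vesicle yields two radial maxima 4 nm apart", {
  sp <- vesicle_image_spec(docking_type = "free", noise_sigma = 0,
                           membrane_thickness_nm = 4.0)
  b <- generate_vesicle_pair_image(sp)
  tr <- b$truth
  # analytic ridge-sum oracle along the radius
  sg <- sp$headgroup_ridge_sigma_nm
  f <- function(r) exp(-(r - tr$ridge_radii_nm[1])^2 / (2 * sg^2)) +
                   exp(-(r - tr$ridge_radii_nm[2])^2 / (2 * sg^2))
  oracle <- dense_maxima(f, 30, 60)
  expect_length(oracle, 2L)
  expect_equal(diff(oracle), 4.0, tolerance = 1e-3)  # dense-grid resolution

  prof <- radial_profile(b$density, tr$centers_nm[1, ],
                         r_max_nm = tr$radii_nm + 16, bin_width_px = 1)
  pk <- detect_headgroup_peaks(prof, smoothing_sigma_px = 0)
  big <- pk[order(pk$prominence, decreasing = TRUE)[1:2], ]
  expect_equal(sort(big$position_nm), oracle, tolerance = 0.5)  # within a bin
  expect_equal(diff(sort(big$position_nm)), 4.0, tolerance = 0.25)
})

test_that("zero protein_interface_ratio empties the contact zone", {
  sp <- vesicle_image_spec(docking_type = "tight", protein_interface_ratio = 0,
                           noise_sigma = 0)
  b <- generate_vesicle_pair_image(sp)
  tr <- b$truth
  px <- 0.5
  xi <- round(tr$interface_x_nm / px) + 1
  yi <- round(tr$interface_y_nm / px) + 1
  zone <- b$protein[(yi - 10):(yi + 10), (xi - 2):(xi + 2)]
  bg <- median(b$protein[1:5, ])
  expect_lt(mean(zone) - bg, 1e-6)
})

test_that("ground truth encodes the interface thickening contract", {
  bt <- generate_vesicle_pair_image(vesicle_image_spec(
    docking_type = "tight", membrane_thickness_nm = 4,
    interface_thickening_nm = 0.6, seed = 1))
  expect_equal(bt$truth$thickness_interface_nm, 4.6)
  expect_equal(bt$truth$thickness_free_nm, 4.0)
  bl <- generate_vesicle_pair_image(vesicle_image_spec(
    docking_type = "loose", membrane_thickness_nm = 4, seed = 1))
  expect_equal(bl$truth$thickness_interface_nm, 4.0)
  # the four interface ridges are ordered and straddle the gap
  rx <- bt$truth$interface_ridge_x_nm
  expect_equal(rx[2] - rx[1], 4.6)
  expect_equal(rx[4] - rx[3], 4.6)
  expect_equal(rx[3] - rx[2], bt$truth$gap_nm)
})

test_that("invalid image specs are rejected", {
  expect_error(vesicle_image_spec(pixel_size_nm = 0), "pixel_size_nm")
  expect_error(vesicle_image_spec(pixel_size_nm = -1), "pixel_size_nm")
  expect_error(vesicle_image_spec(docking_type = "free",
                                  radii_nm = 3, membrane_thickness_nm = 4),
               "radii")
  expect_error(vesicle_image_spec(docking_type = "tight", radii_nm = c(20, 20),
                                  contact_halfwidth_nm = 19),
               "overlap")
  expect_error(vesicle_image_spec(docking_type = "tight",
                                  protein_interface_ratio = -0.2),
               "protein_interface_ratio")
})

test_that("interface thickening series is recovered monotonically", {
  cfg <- pipeline_config()
  mean_meas <- vapply(c(0, 0.3, 0.6, 0.9), function(th) {
    vals <- vapply(1:8, function(i) {
      b <- generate_vesicle_pair_image(vesicle_image_spec(
        docking_type = "tight", interface_thickening_nm = th,
        seed = 1000 + round(1000 * th) + i))
      tm <- measure_synthetic_image(b, cfg)
      mean(tm$thickness_nm[tm$resolved])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_meas) > 0))
})
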