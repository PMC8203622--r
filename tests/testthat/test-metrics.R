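test_that("leaflet assignment recovers generator truth", {
  fr1 <- generate_bilayer_frame(bilayer_frame_spec(seed = 7))
  a1 <- assign_leaflets(fr1, 1L)
  truth1 <- fr1[fr1$role == "P", c("lipid", "leaflet")]
  expect_equal(a1$leaflet[match(truth1$lipid, a1$lipid)], truth1$leaflet)

  fr2 <- generate_bilayer_frame(bilayer_frame_spec(
    n_membranes = 2L, intermembrane_distance_nm = 0.4, seed = 8))
  a2 <- assign_leaflets(fr2, 2L)
  truth2 <- fr2[fr2$role == "P", c("lipid", "leaflet")]
  expect_equal(a2$leaflet[match(truth2$lipid, a2$lipid)], truth2$leaflet)
  expect_equal(length(unique(a2$leaflet)), 4L)
})

test_that("degenerate P layers are an error", {
  n <- 10
  parts <- rbind(
    data.frame(x = runif(n), y = runif(n), z = 3, role = "P", lipid = 1:n),
    data.frame(x = runif(n), y = runif(n), z = 3.45, role = "N", lipid = 1:n))
  fr <- manual_frame(parts)
  expect_error(assign_leaflets(fr, 1L), "degenerate|overlap")
})

test_that("thickness and distance are simple P-layer arithmetic", {
  n <- 8
  mk_layer <- function(z, lip0)
    rbind(data.frame(x = seq_len(n), y = 1, z = z, role = "P",
                     lipid = lip0 + seq_len(n)),
          data.frame(x = seq_len(n), y = 1, z = z + 0.4, role = "N",
                     lipid = lip0 + seq_len(n)))
  fr <- manual_frame(rbind(mk_layer(2.0, 0), mk_layer(6.0, n)),
                     box = c(10, 10, 12))
  asg <- assign_leaflets(fr, 1L)
  expect_equal(membrane_thickness(fr, asg, 1), 4.0)

  fr2 <- manual_frame(rbind(mk_layer(2.0, 0), mk_layer(6.0, n),
                            mk_layer(8.0, 2 * n), mk_layer(8.5, 3 * n)),
                      box = c(10, 10, 12))
  asg2 <- assign_leaflets(fr2, 2L)
  expect_equal(intermembrane_distance(fr2, asg2), abs(8.0 - 6.0))
  expect_error(intermembrane_distance(fr, asg), "double")
})

test_that("thickness is unbiased under zero-mean positional noise", {
  th <- vapply(1:200, function(i) {
    fr <- generate_bilayer_frame(bilayer_frame_spec(
      thickness_nm = 4.2, positional_noise_nm = 0.1, seed = 9000 + i))
    membrane_thickness(fr, assign_leaflets(fr, 1L), 1)
  }, numeric(1))
  se <- 0.1 * sqrt(2 / 100) / sqrt(200)
  expect_lt(abs(mean(th) - 4.2), 3 * se)
})

test_that("geometric metrics are translation- and relabeling-invariant", {
  fr <- generate_bilayer_frame(bilayer_frame_spec(
    n_membranes = 2L, n_lipids_per_leaflet = 25L, seed = 10))
  asg <- assign_leaflets(fr, 2L)
  base <- c(membrane_thickness(fr, asg, 1), intermembrane_distance(fr, asg))

  shifted <- fr
  shifted$z <- shifted$z + 1.3
  attr(shifted, "box_nm") <- attr(fr, "box_nm") + c(0, 0, 2)
  asg_s <- assign_leaflets(shifted, 2L)
  expect_equal(c(membrane_thickness(shifted, asg_s, 1),
                 intermembrane_distance(shifted, asg_s)), base)

  perm <- fr[sample(nrow(fr)), ]
  asg_p <- assign_leaflets(perm, 2L)
  expect_equal(c(membrane_thickness(perm, asg_p, 1),
                 intermembrane_distance(perm, asg_p)), base)
})

test_that("area, per-lipid area and volume follow the box arithmetic", {
  fr <- generate_bilayer_frame(bilayer_frame_spec(box_xy_nm = 8.1,
                                                  thickness_nm = 4.0,
                                                  positional_noise_nm = 0,
                                                  seed = 1))
  asg <- assign_leaflets(fr, 1L)
  expect_equal(lateral_area(fr), 65.61)
  expect_equal(area_per_lipid(fr, asg), 0.6561)
  expect_equal(membrane_volume(fr, asg, 1), 65.61 * 4.0)
})

test_that("fixed-volume area shrinkage raises thickness by the inverse factor", {
  shrink <- 0.95
  f1 <- generate_bilayer_frame(bilayer_frame_spec(positional_noise_nm = 0,
                                                  seed = 1))
  f2 <- generate_bilayer_frame(bilayer_frame_spec(
    box_xy_nm = 8.1 * sqrt(shrink), thickness_nm = 4.0 / shrink,
    positional_noise_nm = 0, seed = 1))
  a1 <- assign_leaflets(f1, 1L); a2 <- assign_leaflets(f2, 1L)
  expect_equal(membrane_volume(f2, a2, 1), membrane_volume(f1, a1, 1),
               tolerance = 1e-12)
  expect_equal(membrane_thickness(f2, a2, 1) / membrane_thickness(f1, a1, 1),
               1 / shrink, tolerance = 1e-12)
})

test_that("tilt means match their constructions", {
  # in-plane headgroups
  n <- 12
  parts <- rbind(
    data.frame(x = seq_len(n), y = 1, z = 2, role = "P", lipid = 1:n),
    data.frame(x = seq_len(n) + 0.45, y = 1, z = 2, role = "N", lipid = 1:n),
    data.frame(x = seq_len(n), y = 3, z = 6, role = "P", lipid = n + 1:n),
    data.frame(x = seq_len(n) + 0.45, y = 3, z = 6, role = "N", lipid = n + 1:n))
  fr <- manual_frame(parts, box = c(20, 20, 10))
  asg <- assign_leaflets(fr, 1L)
  expect_equal(headgroup_tilt(fr, asg, 1)$mean_cos, 0)
  expect_equal(headgroup_tilt(fr, asg, 2)$mean_cos, 0)

  # uniform over the outward hemisphere: mean cos = 1/2 (Monte-Carlo bound)
  set.seed(42)
  m <- 600
  cz <- runif(m); az <- runif(m, 0, 2 * pi); sz <- sqrt(1 - cz^2)
  hemi <- rbind(
    data.frame(x = runif(m, 0, 20), y = runif(m, 0, 20), z = 6, role = "P",
               lipid = 1:m),
    data.frame(x = 0, y = 0, z = 0, role = "N", lipid = 1:m))
  hemi$x[hemi$role == "N"] <- hemi$x[hemi$role == "P"] + 0.45 * sz * cos(az)
  hemi$y[hemi$role == "N"] <- hemi$y[hemi$role == "P"] + 0.45 * sz * sin(az)
  hemi$z[hemi$role == "N"] <- 6 + 0.45 * cz
  low <- data.frame(x = rep(1, 4), y = 1:4, z = 2, role = rep(c("P", "N"), 2),
                    lipid = rep(m + 1:2, each = 2))
  low$z[low$role == "N"] <- 1.55
  fr2 <- manual_frame(rbind(hemi, low), box = c(20, 20, 10))
  asg2 <- assign_leaflets(fr2, 1L)
  expect_equal(headgroup_tilt(fr2, asg2, 2)$mean_cos, 0.5,
               tolerance = 3 / sqrt(12 * m) / 0.5)
})

test_that("flipping the outward normal flips the tilt sign", {
  fr <- generate_bilayer_frame(bilayer_frame_spec(n_lipids_per_leaflet = 25L,
                                                  seed = 12))
  asg <- assign_leaflets(fr, 1L)
  t1 <- headgroup_tilt(fr, asg, 1)$mean_cos
  flipped <- asg
  flipped$normal <- -flipped$normal
  expect_equal(headgroup_tilt(fr, flipped, 1)$mean_cos, -t1)
})

test_that("chain order hits its closed-form limits", {
  frp <- generate_bilayer_frame(bilayer_frame_spec(
    n_lipids_per_leaflet = 16L, chain_bond_cos = 1, positional_noise_nm = 0,
    seed = 1))
  asgp <- assign_leaflets(frp, 1L)
  expect_equal(unique(round(chain_order(frp, asgp), 12)), 1)

  fr0 <- generate_bilayer_frame(bilayer_frame_spec(
    n_lipids_per_leaflet = 16L, chain_bond_cos = 0, positional_noise_nm = 0,
    seed = 1))
  asg0 <- assign_leaflets(fr0, 1L)
  expect_equal(unique(round(chain_order(fr0, asg0), 12)), -0.5)

  # isotropic bond directions -> S near 0
  set.seed(11)
  n <- 400
  cz <- runif(n, -1, 1); az <- runif(n, 0, 2 * pi); sz <- sqrt(1 - cz^2)
  parts <- rbind(
    data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30), z = 6, role = "P",
               lipid = 1:n),
    data.frame(x = 0, y = 0, z = 6.45, role = "N", lipid = 1:n),
    data.frame(x = 0, y = 0, z = 0, role = "C", lipid = 1:n),
    data.frame(x = runif(2, 0, 30), y = runif(2, 0, 30), z = 2,
               role = rep("P", 2), lipid = n + 1:2),
    data.frame(x = 1:2, y = 1, z = 1.55, role = rep("N", 2), lipid = n + 1:2))
  pidx <- which(parts$role == "P" & parts$lipid <= n)
  nidx <- which(parts$role == "N" & parts$lipid <= n)
  cidx <- which(parts$role == "C")
  parts$x[nidx] <- parts$x[pidx]; parts$y[nidx] <- parts$y[pidx]
  parts$x[cidx] <- parts$x[pidx] + 0.3 * sz * cos(az)
  parts$y[cidx] <- parts$y[pidx] + 0.3 * sz * sin(az)
  parts$z[cidx] <- 6 + 0.3 * cz
  fr <- manual_frame(parts, box = c(30, 30, 10))
  asg <- assign_leaflets(fr, 1L)
  s <- chain_order(fr, asg)
  expect_lt(abs(s[1]), 3 * sqrt(0.2) / sqrt(n))   # var of P2(cos) is 1/5
})

test_that("gap hydration counts waters between the facing P layers", {
  fr0 <- generate_bilayer_frame(bilayer_frame_spec(n_membranes = 2L,
                                                   n_gap_waters = 0L,
                                                   seed = 14))
  asg0 <- assign_leaflets(fr0, 2L)
  expect_equal(waters_in_gap(fr0, asg0), 0)

  fr <- generate_bilayer_frame(bilayer_frame_spec(
    n_membranes = 2L, n_gap_waters = 50L, box_xy_nm = 8.1,
    positional_noise_nm = 0, seed = 15))
  asg <- assign_leaflets(fr, 2L)
  expect_equal(waters_in_gap(fr, asg), 50 / 65.61)

  dens <- vapply(c(120L, 60L, 20L), function(nw) {
    f <- generate_bilayer_frame(bilayer_frame_spec(
      n_membranes = 2L, n_gap_waters = nw, seed = 16))
    waters_in_gap(f, assign_leaflets(f, 2L))
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})
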