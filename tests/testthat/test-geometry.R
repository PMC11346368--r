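test_that("centerline resampling is arclength-uniform with endpoints kept", {
  cl <- resample_centerline(data.frame(x = 0, y = 0, z = c(0, 10)), 0.5)
  expect_equal(nrow(cl), 21)
  expect_equal(cl$s_mm, seq(0, 10, 0.5))
  # non-multiple length keeps the distal endpoint
  cl2 <- resample_centerline(data.frame(x = 0, y = 0, z = c(0, 10.3)), 0.5)
  expect_equal(max(cl2$s_mm), 10.3)
  expect_error(resample_centerline(data.frame(x = 0, y = 0, z = 0)),
               "at least 2")
  expect_error(
    resample_centerline(data.frame(x = c(0, 0, 1), y = 0, z = c(0, 0, 1))),
    "duplicate")
})

test_that("resampled polyline preserves total arclength", {
  set.seed(31)
  for (i in 1:5) {
    pts <- data.frame(x = cumsum(runif(8)), y = cumsum(runif(8)),
                      z = cumsum(runif(8)))
    L <- sum(sqrt(rowSums(diff(as.matrix(pts))^2)))
    cl <- resample_centerline(pts, 0.5)
    L2 <- sum(sqrt(rowSums(diff(as.matrix(cl[, 1:3]))^2)))
    expect_lt(abs(L - L2), 0.5)
  }
})

test_that("Simpson volume is exact for constants and quadratics", {
  expect_equal(simpson_volume(rep(10, 41), 0.5), 200)
  s <- seq(0, 2, length.out = 5)
  expect_equal(simpson_volume(s^2, 0.5), 8 / 3, tolerance = 1e-14)
  # odd interval counts use the 3/8 tail and stay exact for cubics
  s6 <- seq(0, 2.5, by = 0.5)
  expect_equal(simpson_volume(s6^3, 0.5), 2.5^4 / 4, tolerance = 1e-12)
  s4 <- seq(0, 1.5, by = 0.5)
  expect_equal(simpson_volume(s4^2, 0.5), 1.5^3 / 3, tolerance = 1e-12)
})

test_that("Simpson volume validates input", {
  expect_error(simpson_volume(c(1, 2), 0.5), "at least 3")
  expect_error(simpson_volume(c(1, -1, 2), 0.5), "non-negative")
  expect_error(simpson_volume(rep(1, 5), 0), "spacing")
})

test_that("Simpson matches a refined trapezoid oracle on random profiles", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    L <- runif(1, 10, 40)
    s <- seq(0, L, length.out = n)
    a <- 6 + 2 * sin(2 * pi * s / L + runif(1, 0, 6)) +
      runif(1, 0.5, 1.5) * cos(4 * pi * s / L + runif(1, 0, 6))
    h <- s[2] - s[1]
    v <- simpson_volume(a, h)
    expect_lt(abs(v - trapezoid_oracle(a, h)) / v, 0.005)
  }
})

test_that("volume integration is additive over abutting intervals", {
  # composite Simpson is additive when the split lands on a station with an
  # even interval count on each side
  set.seed(12)
  a <- abs(rnorm(41)) + 0.5
  s <- seq(0, 20, by = 0.5)
  whole <- profile_volume(s, a, 0, 20, 0.5)
  parts <- profile_volume(s, a, 0, 10, 0.5) +
    profile_volume(s, a, 10, 20, 0.5)
  expect_lt(abs(whole - parts) / whole, 1e-9)
  expect_error(profile_volume(s, a, 5, 5), "non-positive")
  expect_error(profile_volume(s, a, -1, 5), "beyond")
})

test_that("tube cross-sections recover analytic areas", {
  spec <- tube_spec(voxel = 0.2)
  ph <- make_phantom(spec)
  cs <- extract_cross_sections(ph$image, ph$labels, ph$centerline)
  interior <- cs[cs$s_mm > 2 & cs$s_mm < 18, ]
  expect_true(all(abs(interior$lumen_area_mm2 / (pi * 1.5^2) - 1) < 0.03))
  expect_true(all(cs$vessel_area_mm2 >= cs$lumen_area_mm2))
  expect_equal(cs$plaque_area_mm2,
               cs$vessel_area_mm2 - cs$lumen_area_mm2)
  # lumen + plaque volume = vessel volume (identity is per-station exact)
  h <- attr(cs, "step_mm")
  expect_equal(simpson_volume(cs$lumen_area_mm2, h) +
                 simpson_volume(cs$plaque_area_mm2, h),
               simpson_volume(cs$vessel_area_mm2, h), tolerance = 1e-12)
})

test_that("stations outside the vessel see zero areas", {
  spec <- tube_spec(voxel = 0.4)
  ph <- make_phantom(spec)
  # a centerline displaced far to the side stays inside the volume but
  # samples only background labels near the lateral edge
  far <- data.frame(x = min(ph$centerline$x) - 3.6, y = 0, z = c(5, 8))
  cs <- extract_cross_sections(ph$image, ph$labels, far, step_mm = 1,
                               half_width_mm = 0.4)
  expect_true(all(cs$lumen_area_mm2 == 0))
  expect_true(all(cs$vessel_area_mm2 == 0))
})

test_that("planes leaving the volume are flagged and excluded", {
  spec <- tube_spec(voxel = 0.4)
  ph <- make_phantom(spec)
  long <- data.frame(x = 0, y = 0, z = c(0, 40))  # runs past the volume
  expect_warning(
    cs <- extract_cross_sections(ph$image, ph$labels, long, step_mm = 1),
    "excluded")
  expect_gt(attr(cs, "n_excluded"), 0)
  expect_true(all(cs$s_mm <= 23))
})

test_that("in-plane grid refinement changes areas by less than 1%", {
  spec <- tube_spec(voxel = 0.2)
  ph <- make_phantom(spec)
  c1 <- extract_cross_sections(ph$image, ph$labels, ph$centerline,
                               step_mm = 2, inplane_res_mm = 0.1)
  c2 <- extract_cross_sections(ph$image, ph$labels, ph$centerline,
                               step_mm = 2, inplane_res_mm = 0.05)
  mid <- c1$s_mm > 2 & c1$s_mm < 18
  expect_true(all(abs(c2$lumen_area_mm2[mid] / c1$lumen_area_mm2[mid] - 1)
                  < 0.01))
})

test_that("helical phantoms quantify like straight ones", {
  spec <- phantom_spec(length_mm = 15, centerline_kind = "helical",
                       helix_radius_mm = 10, helix_pitch_mm = 150,
                       lumen_radius_mm = 1.5, outer_radius_mm = 2.2,
                       voxel_mm = 0.25, psf_sigma_mm = 0, noise_sd_hu = 0,
                       seed = 5)
  ph <- make_phantom(spec)
  cs <- extract_cross_sections(ph$image, ph$labels, ph$centerline,
                               step_mm = 0.5)
  interior <- cs[cs$s_mm > 2 & cs$s_mm < 13, ]
  expect_true(all(abs(interior$lumen_area_mm2 / (pi * 1.5^2) - 1) < 0.05))
  expect_true(all(abs(interior$vessel_area_mm2 / (pi * 2.2^2) - 1) < 0.05))
})
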