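test_that("analytic ground truth matches closed-form annular volumes", {
  spec <- tube_spec()
  gt <- ground_truth(spec)
  expect_equal(gt$volumes$plaque_mm3, pi * (2.5^2 - 1.5^2) * 20,
               tolerance = 1e-6)
  expect_equal(gt$volumes$lumen_mm3, pi * 1.5^2 * 20, tolerance = 1e-6)
  # per-station partition: components sum to vessel - lumen
  st <- gt$stations
  expect_equal(st$cp_area_mm2 + st$ncp_area_mm2 + st$lap_area_mm2,
               st$vessel_area_mm2 - st$lumen_area_mm2)
})

test_that("zero-plaque phantom has zero plaque volume everywhere", {
  spec <- tube_spec(lumen = 1.5, outer = 1.5)
  gt <- ground_truth(spec)
  expect_equal(gt$volumes$plaque_mm3, 0, tolerance = 1e-9)
  expect_true(all(abs(gt$stations$plaque_area_mm2) < 1e-9))
})

test_that("non-physical wall geometry is rejected, naming the station", {
  expect_error(
    phantom_spec(length_mm = 20, lumen_radius_mm = 2, outer_radius_mm = 2,
                 stenoses = NULL,
                 bulges = tibble::tibble(center_mm = 10, width_mm = 5,
                                         height_mm = -0.5)),
    "outer radius < lumen radius at arclength")
  expect_error(phantom_spec(stenoses = tibble::tibble(
    center_mm = 10, width_mm = 5, severity = 1.2)), "severity")
})

test_that("overlapping deposits are rejected; disjoint ones accepted", {
  dep2 <- tibble::tibble(start_mm = c(2, 5), end_mm = c(10, 8),
                         start_deg = c(0, 50), width_deg = c(90, 90),
                         component = c("CP", "LAP"))
  expect_error(tube_spec(deposits = dep2), "overlap")
  dep_ok <- dep2
  dep_ok$start_deg <- c(0, 120)
  expect_s3_class(tube_spec(deposits = dep_ok), "phantom_spec")
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- tube_spec(voxel = 0.5, psf = 0.3, noise = 10, seed = 11)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$labels$label, p2$labels$label)
})

test_that("ground truth is independent of the voxel grid", {
  s1 <- tube_spec(voxel = 0.4,
                  stenoses = tibble::tibble(center_mm = 10, width_mm = 4,
                                            severity = 0.4))
  s2 <- s1
  s2$voxel_mm <- 0.2
  expect_identical(ground_truth(s1)$stations, ground_truth(s2)$stations)
  expect_identical(ground_truth(s1)$volumes, ground_truth(s2)$volumes)
})

test_that("voxelized lumen volume converges to the analytic value", {
  spec <- tube_spec(voxel = 0.2)
  ph <- make_phantom(spec)
  vox_lumen <- sum(ph$labels$label == 1L) * spec$voxel_mm^3
  expect_lt(abs(vox_lumen / (pi * 1.5^2 * 20) - 1), 0.02)
})

test_that("component HU histograms match the specified distributions", {
  spec <- phantom_spec(
    length_mm = 30, lumen_radius_mm = 1.5, outer_radius_mm = 2.6,
    deposits = tibble::tibble(start_mm = c(2, 22), end_mm = c(20, 28),
                              start_deg = c(0, 240), width_deg = 100,
                              component = c("NCP", "LAP")),
    voxel_mm = 0.2, psf_sigma_mm = 0, noise_sd_hu = 0, seed = 3)
  ph <- make_phantom(spec)
  pure <- function(code) {
    m <- plaquekit:::erode6(ph$labels$component == code)
    ph$image$data[m]
  }
  hp <- spec$hu_params
  lum <- pure(1L)
  expect_gt(length(lum), 1e4)
  expect_gt(ks.test(lum, "pnorm", hp$lumen[1], hp$lumen[2])$p.value, 0.01)
  ncp <- pure(3L)
  expect_gt(length(ncp), 1e4)
  expect_gt(ks.test(ncp, "pnorm", hp$ncp[1], hp$ncp[2])$p.value, 0.01)
  lap <- pure(4L)
  expect_gt(ks.test(lap, "pnorm", hp$lap[1], hp$lap[2])$p.value, 0.01)
})

test_that("noise-free identity pullback reproduces truth areas at 1 mm", {
  spec <- tube_spec(stenoses = tibble::tibble(center_mm = 10, width_mm = 5,
                                              severity = 0.4))
  gt <- ground_truth(spec)
  pb <- emulate_ivus_pullback(gt, area_noise_cv = 0, warp = identity,
                              seed = 1)
  s <- pb$station_mm
  expect_equal(pb$lumen_area_mm2, pi * lumen_radius(spec, s)^2,
               tolerance = 1e-6)
  expect_equal(pb$vessel_area_mm2, pi * outer_radius(spec, s)^2,
               tolerance = 1e-6)
})

test_that("a linear pullback warp scales length and anchor positions", {
  spec <- tube_spec(bifurcations_mm = c(5, 12))
  gt <- ground_truth(spec)
  pb <- emulate_ivus_pullback(gt, area_noise_cv = 0,
                              warp = function(s) 1.1 * s, seed = 1)
  a <- pullback_anchors(pb)
  expect_equal(a$position_mm[a$kind == "end"], 1.1 * 20, tolerance = 1e-6)
  expect_equal(a$position_mm[a$kind == "bifurcation"], 1.1 * c(5, 12),
               tolerance = 1e-6)
})

test_that("pullback area noise has the requested coefficient of variation", {
  spec <- tube_spec(length_mm = 210)
  gt <- ground_truth(spec)
  pb <- emulate_ivus_pullback(gt, area_noise_cv = 0.05, warp = identity,
                              seed = 42)
  ratio <- pb$lumen_area_mm2 / (pi * 1.5^2)
  expect_gt(nrow(pb), 200)
  cv <- sd(ratio) / mean(ratio)
  expect_gt(cv, 0.03)
  expect_lt(cv, 0.07)
})

test_that("pullback emulation validates its inputs", {
  gt <- ground_truth(tube_spec())
  expect_error(emulate_ivus_pullback(gt, area_noise_cv = -0.1), "area_noise_cv")
  expect_error(emulate_ivus_pullback(gt, warp = function(s) -s),
               "increasing")
  expect_error(emulate_ivus_pullback(gt, warp = function(s) sin(s)),
               "increasing")
})

test_that("cohorts are reproducible and span component mixes", {
  c1 <- sample_cohort(50, seed = 9)
  c2 <- sample_cohort(50, seed = 9)
  expect_identical(c1[[7]]$spec, c2[[7]]$spec)
  expect_identical(c1[[7]]$pullback, c2[[7]]$pullback)
  lap_frac <- mean(purrr::map_dbl(c1, ~ .x$truth$volumes$lap_mm3) > 0)
  expect_gte(lap_frac, 0.35)
  expect_lte(lap_frac, 0.65)
  cp_present <- purrr::map_dbl(c1, ~ .x$truth$volumes$cp_mm3) > 0
  expect_true(any(cp_present) && any(!cp_present))
  one <- sample_cohort(1, seed = 2)
  expect_length(one, 1)
  # paired sides agree on the vessel: truth underlies both
  expect_identical(one[[1]]$truth$spec, one[[1]]$spec)
})
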