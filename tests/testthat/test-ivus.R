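make_profile <- function(vessel, lumen, calc = 0, atten = 0) {
  pullback_profile(tibble::tibble(
    station_mm = seq_along(vessel) - 1,
    lumen_area_mm2 = lumen, vessel_area_mm2 = vessel,
    calc_arc_deg = calc, atten_arc_deg = atten))
}

test_that("plaque burden is (vessel - lumen)/vessel in percent", {
  p <- make_profile(rep(20, 5), rep(10, 5))
  expect_equal(plaque_burden_profile(p)$burden_pct, rep(50, 5))
  p2 <- make_profile(rep(8, 4), rep(8, 4))
  expect_equal(plaque_burden_profile(p2)$burden_pct, rep(0, 4))
  p3 <- make_profile(c(10, 0, 10), c(5, 0, 5))
  expect_true(is.na(plaque_burden_profile(p3)$burden_pct[2]))
  # constructed profiles enforce vessel >= lumen, so feed a raw tibble
  p4 <- tibble::tibble(station_mm = 0:1, lumen_area_mm2 = c(5, 11),
                       vessel_area_mm2 = c(10, 10))
  expect_error(plaque_burden_profile(p4), "station")
})

test_that("the worked burden profile yields one 2 mm lesion", {
  les <- detect_lesions(c(30, 45, 46, 47, 30))
  expect_equal(nrow(les), 1)
  expect_equal(les$length_mm, 2)
  expect_equal(les$start_idx, 2)
  expect_equal(les$end_idx, 4)
  expect_equal(les$max_burden_pct, 47)
})

test_that("degenerate burden profiles detect as expected", {
  expect_equal(nrow(detect_lesions(rep(30, 20))), 0)
  les <- detect_lesions(rep(55, 10))
  expect_equal(nrow(les), 1)
  expect_equal(les$length_mm, 9)
  # two qualifying stations span only 1 mm: not a lesion
  expect_equal(nrow(detect_lesions(c(10, 50, 50, 10))), 0)
})

test_that("lesion detection agrees with exhaustive window search", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    burden <- runif(n, 20, 70)
    if (runif(1) < 0.3) burden[sample(n, 2)] <- NA
    got <- detect_lesions(burden)
    want <- brute_force_lesions(burden)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$start_idx, unname(want[, "start"]))
      expect_equal(got$end_idx, unname(want[, "end"]))
    }
  }
})

test_that("lesions are invariant to sub-threshold padding at the ends", {
  burden <- c(30, 45, 50, 60, 48, 20, 55, 60, 58, 10)
  a <- detect_lesions(burden)
  b <- detect_lesions(c(10, 20, burden, 5))
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$start_idx - a$start_idx, rep(2L, nrow(a)))
  expect_equal(a$length_mm, b$length_mm)
})

test_that("full-thickness component areas follow the angular fraction", {
  p <- make_profile(rep(12, 3), rep(4, 3), atten = 90)
  q <- qualitative_component_areas(p)
  expect_equal(q$atten_area_mm2, rep(2, 3))
  p0 <- make_profile(rep(12, 3), rep(4, 3))
  expect_equal(qualitative_component_areas(p0)$calc_area_mm2, rep(0, 3))
  pf <- make_profile(rep(12, 3), rep(4, 3), calc = 360)
  qf <- qualitative_component_areas(pf)
  expect_equal(qf$calc_area_mm2, qf$plaque_area_mm2)
  pb <- make_profile(rep(12, 3), rep(4, 3), calc = 200, atten = 200)
  expect_error(qualitative_component_areas(pb), "360")
})

test_that("component areas never exceed plaque area", {
  set.seed(4)
  for (i in 1:20) {
    n <- 15
    lum <- runif(n, 2, 8)
    ves <- lum + runif(n, 0, 10)
    p <- make_profile(ves, lum, calc = runif(n, 0, 180),
                      atten = runif(n, 0, 180))
    q <- qualitative_component_areas(p)
    expect_true(all(q$calc_area_mm2 <= q$plaque_area_mm2 + 1e-12))
    expect_true(all(q$atten_area_mm2 <= q$plaque_area_mm2 + 1e-12))
  }
})

test_that("lesion volumes integrate the restricted profiles", {
  p <- make_profile(rep(12, 21), rep(4, 21))
  les <- tibble::tibble(lesion = 1, start_mm = 5, end_mm = 15)
  v <- ivus_lesion_volumes(p, les)
  expect_equal(v$tpv_mm3, 80, tolerance = 1e-9)
  expect_equal(v$lumen_mm3, 40, tolerance = 1e-9)
  expect_error(
    ivus_lesion_volumes(p, tibble::tibble(lesion = 1, start_mm = 5,
                                          end_mm = 5)),
    "non-positive")
  expect_error(
    ivus_lesion_volumes(p, tibble::tibble(lesion = 1, start_mm = 15,
                                          end_mm = 25)),
    "outside")
})

test_that("noise-free identity emulation round-trips lesion volumes", {
  spec <- tube_spec(
    length_mm = 40, lumen = 1.6, outer = 1.85, voxel = 0.4,
    stenoses = tibble::tibble(center_mm = 20, width_mm = 10,
                              severity = 0.45),
    bulges = tibble::tibble(center_mm = 20, width_mm = 10, height_mm = 1))
  gt <- ground_truth(spec)
  pb <- emulate_ivus_pullback(gt, area_noise_cv = 0, warp = identity,
                              seed = 1)
  les <- detect_lesions(plaque_burden_profile(pb))
  expect_equal(nrow(les), 1)
  v <- ivus_lesion_volumes(pb, les)
  tv <- truth_volumes(spec, les$start_mm, les$end_mm)
  expect_lt(abs(v$tpv_mm3 / tv$plaque_mm3 - 1), 0.01)
  expect_lt(abs(v$lumen_mm3 / tv$lumen_mm3 - 1), 0.01)
})

test_that("pullback profiles validate structure and anchors", {
  expect_error(make_profile(c(10, 10), c(5, -1)), "vessel >= lumen >= 0")
  st <- tibble::tibble(station_mm = 0:3, lumen_area_mm2 = 5,
                       vessel_area_mm2 = 10)
  expect_error(
    pullback_profile(st, anchors = tibble::tibble(
      position_mm = c(0, 3), kind = c("start", "start"))),
    "exactly one")
  expect_error(
    pullback_profile(st, anchors = tibble::tibble(
      position_mm = c(0, 3.5, 3), kind = c("start", "bifurcation", "end"))),
    "strictly between")
})
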