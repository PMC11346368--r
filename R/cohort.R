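#' Cohort sampling distribution
#'
#' Parameter ranges for randomized phantom cases.  Each case is one vessel
#' carrying one focal lesion: a concentric raised-cosine stenosis plus
#' outward wall bulge, with optional calcified and low-attenuation deposits
#' (disjoint angular sectors) inside the lesion, two bifurcation landmarks,
#' and a random monotone pullback warp.  Component mixes therefore span
#' zero-CP, zero-LAP and mixed lesions.
#'
#' Lesion-size ranges are calibrated so the cohort's per-lesion total
#' plaque volumes show the dispersion typical of clinical IVUS lesion
#' cohorts (median near 155 mm^3 with quartiles around 79 and 255 mm^3,
#' mean lesion length in the low tens of mm with a wide spread): vessel
#' caliber and lesion extent vary widely, and the power-law draws of
#' lesion width and bulge height skew the cohort toward smaller lesions
#' with a long large-lesion tail.
#'
#' @param length_mm vessel length (mm).
#' @param lumen_radius_mm range of baseline lumen radius (mm), uniform.
#' @param media_mm baseline wall thickness outside lesions (mm).
#' @param lesion_width_mm range of the raised-cosine half-width w (the
#'   lesion spans about 2w mm); drawn as `min + (max-min) u^1.6`.
#' @param severity range of fractional lumen narrowing, uniform.
#' @param bulge_mm range of outward wall bulge height (mm); drawn as
#'   `min + (max-min) u^1.3`.
#' @param cp_prob,lap_prob probability a lesion carries a CP / LAP deposit.
#' @param cp_width_deg,lap_width_deg angular sector ranges (degrees).
#' @param cp_length_mm,lap_length_mm axial extent ranges (mm).
#' @param bif1_frac,bif2_frac bifurcation positions as fractions of length.
#' @param voxel_mm,psf_sigma_mm,noise_sd_hu imaging parameters.
#' @param area_noise_cv IVUS area noise coefficient of variation.
#' @param warp_knots interior knots of the random pullback warp.
#' @param warp_slope_range pullback-speed slope bounds.
#' @return list of class `cohort_distribution`.
#' @export
cohort_distribution <- function(length_mm = 60,
                                lumen_radius_mm = c(1.2, 1.9),
                                media_mm = 0.22,
                                lesion_width_mm = c(3, 25),
                                severity = c(0.1, 0.6),
                                bulge_mm = c(0.2, 1.2),
                                cp_prob = 0.6,
                                lap_prob = 0.5,
                                cp_width_deg = c(40, 110),
                                lap_width_deg = c(20, 60),
                                cp_length_mm = c(4, 12),
                                lap_length_mm = c(3, 8),
                                bif1_frac = c(0.08, 0.2),
                                bif2_frac = c(0.6, 0.85),
                                voxel_mm = 0.4,
                                psf_sigma_mm = 0.3,
                                noise_sd_hu = 15,
                                area_noise_cv = 0.05,
                                warp_knots = 3,
                                warp_slope_range = c(0.8, 1.25)) {
  structure(as.list(environment()), class = "cohort_distribution")
}

runif1 <- function(rng) runif(1, rng[1], rng[2])

# Draw one phantom case description under the distribution.
draw_case_spec <- function(dist, case_seed) {
  with_rng(case_seed, {
    L <- dist$length_mm
    rl <- runif1(dist$lumen_radius_mm)
    w <- dist$lesion_width_mm[1] +
      diff(dist$lesion_width_mm) * runif(1)^1.6
    center <- runif(1, w + 2, L - w - 2)
    sev <- runif1(dist$severity)
    bulge <- dist$bulge_mm[1] + diff(dist$bulge_mm) * runif(1)^1.3
    deposits <- list()
    cp_start_deg <- NA
    cp_width <- 0
    if (runif(1) < dist$cp_prob) {
      cp_width <- runif1(dist$cp_width_deg)
      cp_start_deg <- runif(1, 0, 360)
      len <- min(runif1(dist$cp_length_mm), 1.4 * w)
      c0 <- center + runif(1, -0.4, 0.4) * w
      deposits$cp <- tibble(
        start_mm = max(0, c0 - len / 2), end_mm = min(L, c0 + len / 2),
        start_deg = cp_start_deg, width_deg = cp_width, component = "CP")
    }
    if (runif(1) < dist$lap_prob) {
      lw <- runif1(dist$lap_width_deg)
      if (is.na(cp_start_deg)) {
        ls <- runif(1, 0, 360)
      } else {
        # place the LAP sector in the free arc left by the CP sector
        free <- 360 - cp_width - lw - 10
        ls <- (cp_start_deg + cp_width + 5 + runif(1, 0, max(free, 0))) %% 360
      }
      len <- min(runif1(dist$lap_length_mm), 1.4 * w)
      c0 <- center + runif(1, -0.4, 0.4) * w
      deposits$lap <- tibble(
        start_mm = max(0, c0 - len / 2), end_mm = min(L, c0 + len / 2),
        start_deg = ls, width_deg = lw, component = "LAP")
    }
    bifs <- c(runif1(dist$bif1_frac), runif1(dist$bif2_frac)) * L
    phantom_spec(
      length_mm = L,
      lumen_radius_mm = rl,
      outer_radius_mm = rl + dist$media_mm,
      stenoses = tibble(center_mm = center, width_mm = w, severity = sev),
      bulges = tibble(center_mm = center, width_mm = w, height_mm = bulge),
      deposits = bind_rows(deposits),
      bifurcations_mm = bifs,
      voxel_mm = dist$voxel_mm,
      psf_sigma_mm = dist$psf_sigma_mm,
      noise_sd_hu = dist$noise_sd_hu,
      seed = with_rng(case_seed + 1L, sample.int(.Machine$integer.max, 1)))
  })
}

#' Sample a cohort of paired phantom / pullback cases
#'
#' Draws `n_lesions` reproducible cases: each holds the phantom
#' specification (rendered on demand with [make_phantom()]), its analytic
#' ground truth, the generating pullback warp and the emulated IVUS
#' pullback.  Identical `n_lesions` + `seed` + distribution reproduce the
#' cohort exactly.
#'
#' @param n_lesions number of cases (>= 1).
#' @param dist a [cohort_distribution()].
#' @param seed integer seed.
#' @return list of class `phantom_cohort`; each case is a list with `id`,
#'   `spec`, `truth`, `warp` and `pullback`.
#' @export
sample_cohort <- function(n_lesions, dist = cohort_distribution(),
                          seed = 1L) {
  if (!is.numeric(n_lesions) || n_lesions < 1) abort("n_lesions must be >= 1")
  seeds <- derive_seeds(seed, 3L * n_lesions)
  cases <- purrr::map(seq_len(n_lesions), function(i) {
    spec <- draw_case_spec(dist, seeds[3 * i - 2])
    truth <- ground_truth(spec)
    warp <- random_pullback_warp(spec$length_mm, n_knots = dist$warp_knots,
                                 slope_range = dist$warp_slope_range,
                                 seed = seeds[3 * i - 1])
    pullback <- emulate_ivus_pullback(truth,
                                      area_noise_cv = dist$area_noise_cv,
                                      warp = warp, seed = seeds[3 * i])
    list(id = i, spec = spec, truth = truth, warp = warp,
         pullback = pullback)
  })
  structure(cases, class = "phantom_cohort", seed = seed, dist = dist)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases (seed %d)\n", length(x),
              attr(x, "seed")))
  invisible(x)
}
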