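#' Define a digital coronary vessel phantom
#'
#' A phantom is an analytically defined vessel: a centerline (straight or
#' helical), a lumen radius profile (baseline radius with smooth stenoses),
#' an outer-wall radius profile (baseline radius with smooth plaque bulges),
#' and a set of plaque deposits, each occupying an axial interval and an
#' angular sector of the wall at full wall thickness.  Components are
#' calcified (CP), non-calcified (NCP) and low-attenuation (LAP) plaque;
#' wall tissue outside every deposit is NCP, so the components partition the
#' wall exactly.  Hounsfield-unit (HU) distributions per region, a Gaussian
#' point-spread sigma, additive noise, voxel spacing and a seed complete the
#' imaging model.
#'
#' Radius profiles use raised-cosine perturbations: a stenosis with
#' `center_mm`, `width_mm` and fractional `severity` multiplies the baseline
#' lumen radius by `1 - severity * bump((s - center)/width)` where
#' `bump(u) = (1 + cos(pi u))/2` on `|u| <= 1`; a bulge adds
#' `height_mm * bump(...)` to the outer radius.
#'
#' @param length_mm vessel length along the centerline (mm).
#' @param centerline_kind `"straight"` or `"helical"`.
#' @param helix_radius_mm,helix_pitch_mm helix geometry (helical only);
#'   pitch is the axial rise per turn.
#' @param lumen_radius_mm baseline lumen radius (mm).
#' @param outer_radius_mm baseline outer-wall radius (mm); must exceed the
#'   lumen radius everywhere once stenoses/bulges apply.
#' @param stenoses tibble with columns `center_mm`, `width_mm`, `severity`
#'   (fractional narrowing in `[0, 1)`).
#' @param bulges tibble with columns `center_mm`, `width_mm`, `height_mm`.
#' @param deposits tibble with columns `start_mm`, `end_mm`, `start_deg`,
#'   `width_deg`, `component` (one of `"CP"`, `"NCP"`, `"LAP"`).  Deposits
#'   must be pairwise disjoint in axial-by-angular extent.
#' @param bifurcations_mm arclengths of bifurcation landmarks, used as
#'   co-registration anchors.
#' @param hu_params named list of `c(mean, sd)` HU pairs for `lumen`, `cp`,
#'   `ncp`, `lap`, `background`.
#' @param psf_sigma_mm Gaussian point-spread sigma (mm, >= 0).
#' @param noise_sd_hu additive image noise SD (HU, >= 0).
#' @param voxel_mm isotropic voxel spacing (mm, > 0).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(length_mm = 20, lumen_radius_mm = 1.5,
#'                      outer_radius_mm = 2.5, seed = 1)
#' gt <- ground_truth(spec)
#' gt$volumes
phantom_spec <- function(length_mm = 40,
                         centerline_kind = c("straight", "helical"),
                         helix_radius_mm = 8,
                         helix_pitch_mm = 120,
                         lumen_radius_mm = 1.8,
                         outer_radius_mm = lumen_radius_mm + 0.25,
                         stenoses = NULL,
                         bulges = NULL,
                         deposits = NULL,
                         bifurcations_mm = numeric(),
                         hu_params = default_hu_params(),
                         psf_sigma_mm = 0.3,
                         noise_sd_hu = 15,
                         voxel_mm = 0.4,
                         seed = 1L) {
  centerline_kind <- match.arg(centerline_kind)
  stop_if_not_number(length_mm, "length_mm", 0, strict = TRUE)
  stop_if_not_number(lumen_radius_mm, "lumen_radius_mm", 0, strict = TRUE)
  stop_if_not_number(outer_radius_mm, "outer_radius_mm", 0, strict = TRUE)
  stop_if_not_number(psf_sigma_mm, "psf_sigma_mm", 0)
  stop_if_not_number(noise_sd_hu, "noise_sd_hu", 0)
  stop_if_not_number(voxel_mm, "voxel_mm", 0, strict = TRUE)
  empty_stenoses <- tibble(center_mm = double(), width_mm = double(),
                           severity = double())
  empty_bulges <- tibble(center_mm = double(), width_mm = double(),
                         height_mm = double())
  empty_deposits <- tibble(start_mm = double(), end_mm = double(),
                           start_deg = double(), width_deg = double(),
                           component = character())
  stenoses <- if (is.null(stenoses)) empty_stenoses else as_tibble(stenoses)
  bulges <- if (is.null(bulges)) empty_bulges else as_tibble(bulges)
  deposits <- if (is.null(deposits)) empty_deposits else as_tibble(deposits)
  if (nrow(stenoses) && any(stenoses$severity < 0 | stenoses$severity >= 1)) {
    abort("stenosis `severity` must lie in [0, 1)")
  }
  if (nrow(deposits)) {
    if (!all(deposits$component %in% c("CP", "NCP", "LAP"))) {
      abort("deposit `component` must be CP, NCP or LAP")
    }
    if (any(deposits$width_deg <= 0 | deposits$width_deg > 360)) {
      abort("deposit `width_deg` must lie in (0, 360]")
    }
    if (any(deposits$start_mm < 0 | deposits$end_mm > length_mm |
            deposits$end_mm <= deposits$start_mm)) {
      abort("deposit axial intervals must satisfy 0 <= start < end <= length")
    }
    check_deposit_overlap(deposits)
  }
  needed <- c("lumen", "cp", "ncp", "lap", "background")
  if (!all(needed %in% names(hu_params))) {
    abort(paste("hu_params must name:", paste(needed, collapse = ", ")))
  }
  spec <- structure(
    list(length_mm = length_mm, centerline_kind = centerline_kind,
         helix_radius_mm = helix_radius_mm, helix_pitch_mm = helix_pitch_mm,
         lumen_radius_mm = lumen_radius_mm, outer_radius_mm = outer_radius_mm,
         stenoses = stenoses, bulges = bulges, deposits = deposits,
         bifurcations_mm = sort(bifurcations_mm), hu_params = hu_params,
         psf_sigma_mm = psf_sigma_mm, noise_sd_hu = noise_sd_hu,
         voxel_mm = voxel_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_wall_order(spec)
  spec
}

#' Default per-region Hounsfield-unit distributions
#'
#' Means/SDs chosen so that default phantoms exercise all three HU
#' characterization windows and both sides of the adaptive calcium-threshold
#' branch `max(350, lumen mean + SD)`: contrast-enhanced lumen N(450, 60)
#' puts the adaptive branch (510 HU) above the 350 HU floor, CP N(700, 100)
#' truncated below at that nominal threshold, NCP N(80, 30), LAP N(0, 15),
#' background N(-50, 20).
#'
#' @return named list of `c(mean, sd)` pairs.
#' @export
default_hu_params <- function() {
  list(lumen = c(450, 60), cp = c(700, 100), ncp = c(80, 30),
       lap = c(0, 15), background = c(-50, 20))
}

# Deposits must tile, not stack: reject axial-and-angular overlap so the
# analytic ground truth needs no precedence rule.
check_deposit_overlap <- function(deposits) {
  n <- nrow(deposits)
  if (n < 2) return(invisible(TRUE))
  arcs <- purrr::map(seq_len(n), function(i) {
    a0 <- deposits$start_deg[i] %% 360
    a1 <- a0 + deposits$width_deg[i]
    if (a1 <= 360) matrix(c(a0, a1), 1) else
      rbind(c(a0, 360), c(0, a1 - 360))
  })
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ax <- min(deposits$end_mm[i], deposits$end_mm[j]) -
      max(deposits$start_mm[i], deposits$start_mm[j])
    if (ax <= 0) next
    for (u in seq_len(nrow(arcs[[i]]))) for (v in seq_len(nrow(arcs[[j]]))) {
      ov <- min(arcs[[i]][u, 2], arcs[[j]][v, 2]) -
        max(arcs[[i]][u, 1], arcs[[j]][v, 1])
      if (ov > 1e-9) {
        abort(sprintf("deposits %d and %d overlap (axially and angularly)", i, j))
      }
    }
  }
  invisible(TRUE)
}

raised_cosine <- function(u) ifelse(abs(u) <= 1, (1 + cos(pi * u)) / 2, 0)

#' Analytic radius profiles of a phantom
#'
#' @param spec a [phantom_spec()].
#' @param s arclength positions (mm).
#' @return `lumen_radius()` and `outer_radius()` return radii in mm.
#' @export
lumen_radius <- function(spec, s) {
  r <- rep(spec$lumen_radius_mm, length(s))
  if (nrow(spec$stenoses)) {
    for (i in seq_len(nrow(spec$stenoses))) {
      st <- spec$stenoses[i, ]
      r <- r - spec$lumen_radius_mm * st$severity *
        raised_cosine((s - st$center_mm) / st$width_mm)
    }
  }
  pmax(r, 0)
}

#' @rdname lumen_radius
#' @export
outer_radius <- function(spec, s) {
  r <- rep(spec$outer_radius_mm, length(s))
  if (nrow(spec$bulges)) {
    for (i in seq_len(nrow(spec$bulges))) {
      b <- spec$bulges[i, ]
      r <- r + b$height_mm * raised_cosine((s - b$center_mm) / b$width_mm)
    }
  }
  r
}

validate_wall_order <- function(spec, ds = 0.05) {
  s <- seq(0, spec$length_mm, by = ds)
  bad <- which(outer_radius(spec, s) < lumen_radius(spec, s))
  if (length(bad)) {
    abort(sprintf(
      "outer radius < lumen radius at arclength %.2f mm (non-physical wall)",
      s[bad[1]]))
  }
  invisible(TRUE)
}

# Per-station analytic areas (mm^2).  Component areas are angular fractions
# of the wall annulus; wall outside any deposit counts as NCP.
truth_areas <- function(spec, s) {
  rl <- lumen_radius(spec, s)
  ro <- outer_radius(spec, s)
  lumen <- pi * rl^2
  vessel <- pi * ro^2
  plaque <- vessel - lumen
  cp <- ncp_dep <- lap <- rep(0, length(s))
  if (nrow(spec$deposits)) {
    for (i in seq_len(nrow(spec$deposits))) {
      d <- spec$deposits[i, ]
      inax <- s >= d$start_mm & s < d$end_mm
      frac <- d$width_deg / 360
      add <- ifelse(inax, frac * plaque, 0)
      switch(d$component,
             CP = cp <- cp + add,
             LAP = lap <- lap + add,
             NCP = ncp_dep <- ncp_dep + add)
    }
  }
  tibble(s_mm = s, lumen_area_mm2 = lumen, vessel_area_mm2 = vessel,
         plaque_area_mm2 = plaque, cp_area_mm2 = cp, lap_area_mm2 = lap,
         ncp_area_mm2 = plaque - cp - lap)
}

#' Analytic ground truth for a phantom
#'
#' Per-station areas and component volumes are derived from the closed-form
#' radius profiles, never from the voxel grid: refining `voxel_mm` changes
#' the ground truth by exactly zero.  Volumes use dense fixed-step Simpson
#' quadrature (0.01 mm) of the analytic area profiles.
#'
#' @param spec a [phantom_spec()].
#' @param station_mm station spacing of the reported area table (mm).
#' @return object of class `ground_truth`: list with `stations` (tibble),
#'   `volumes` (tibble of component volumes over the full vessel),
#'   `bifurcations_mm`, `length_mm` and the originating `spec`.
#' @export
ground_truth <- function(spec, station_mm = 0.5) {
  stations <- truth_areas(spec, seq(0, spec$length_mm, by = station_mm))
  vols <- truth_volumes(spec, 0, spec$length_mm)
  structure(list(stations = stations, volumes = vols,
                 bifurcations_mm = spec$bifurcations_mm,
                 length_mm = spec$length_mm, spec = spec),
            class = "ground_truth")
}

#' True component volumes over an axial interval
#'
#' @param spec a [phantom_spec()].
#' @param start_mm,end_mm interval `[start, end)` in arclength mm.
#' @param quad_step_mm quadrature step (mm).
#' @return one-row tibble of lumen/vessel/plaque/CP/NCP/LAP volumes (mm^3).
#' @export
truth_volumes <- function(spec, start_mm = 0, end_mm = spec$length_mm,
                          quad_step_mm = 0.01) {
  if (end_mm <= start_mm) abort("end_mm must exceed start_mm")
  n <- max(5L, 2L * ceiling((end_mm - start_mm) / quad_step_mm / 2) + 1L)
  s <- seq(start_mm, end_mm, length.out = n)
  a <- truth_areas(spec, s)
  h <- s[2] - s[1]
  integ <- function(y) simpson_volume(y, h)
  tibble(lumen_mm3 = integ(a$lumen_area_mm2),
         vessel_mm3 = integ(a$vessel_area_mm2),
         plaque_mm3 = integ(a$plaque_area_mm2),
         cp_mm3 = integ(a$cp_area_mm2),
         ncp_mm3 = integ(a$ncp_area_mm2),
         lap_mm3 = integ(a$lap_area_mm2))
}

#' Cross-section series taken directly from analytic truth
#'
#' A noise-free, discretization-free stand-in for image-based extraction;
#' used for co-registration experiments where only the 1D lumen profile
#' matters.
#'
#' @inheritParams ground_truth
#' @param step_mm station spacing (mm).
#' @return a cross-section tibble with the same columns as
#'   [extract_cross_sections()] area output.
#' @export
truth_cross_sections <- function(spec, step_mm = 0.5) {
  if (inherits(spec, "ground_truth")) spec <- spec$spec
  truth_areas(spec, seq(0, spec$length_mm, by = step_mm))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s vessel, %.1f mm, lumen %.2f mm / outer %.2f mm\n",
              x$centerline_kind, x$length_mm, x$lumen_radius_mm,
              x$outer_radius_mm))
  cat(sprintf("  %d stenosis(es), %d bulge(s), %d deposit(s), %d bifurcation(s)\n",
              nrow(x$stenoses), nrow(x$bulges), nrow(x$deposits),
              length(x$bifurcations_mm)))
  cat(sprintf("  voxel %.2f mm, PSF %.2f mm, noise %.1f HU, seed %d\n",
              x$voxel_mm, x$psf_sigma_mm, x$noise_sd_hu, x$seed))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %.1f mm vessel, %d stations\n", x$length_mm,
              nrow(x$stations)))
  print(x$volumes)
  invisible(x)
}
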