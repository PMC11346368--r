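#' Random monotone pullback warp
#'
#' Emulates pullback-speed variation as a monotone map from vessel
#' arclength (mm) to recorded pullback distance (mm): a monotone
#' piecewise-cubic (Hyman-filtered) spline through `n_knots` interior knots,
#' with per-segment slopes drawn uniformly from `slope_range` (default
#' `[0.8, 1.25]`), anchored at `warp(0) = 0`.  Invertible by construction.
#'
#' @param length_mm vessel arclength range of the warp domain (mm).
#' @param n_knots number of interior knots.
#' @param slope_range slope bounds per knot segment.
#' @param seed integer seed.
#' @return function mapping arclength mm to pullback mm, with a `knots`
#'   attribute; class `pullback_warp`.
#' @export
random_pullback_warp <- function(length_mm, n_knots = 3,
                                 slope_range = c(0.8, 1.25), seed = 1L) {
  with_rng(seed, {
    sk <- sort(c(0, runif(n_knots, 0.1, 0.9) * length_mm, length_mm))
    slopes <- runif(length(sk) - 1, slope_range[1], slope_range[2])
    pk <- c(0, cumsum(slopes * diff(sk)))
    f <- splinefun(sk, pk, method = "hyman")
    structure(f, knots = tibble(s_mm = sk, pullback_mm = pk),
              class = c("pullback_warp", "function"))
  })
}

# Numeric inverse of a strictly increasing warp on [0, length_mm]
# (dense-grid monotone interpolation; adequate well below station spacing).
warp_inverse_fun <- function(warp, length_mm, grid_mm = 0.005) {
  s <- seq(0, length_mm, by = grid_mm)
  p <- warp(s)
  if (any(diff(p) <= 0)) abort("warp must be strictly increasing")
  approxfun(p, s, rule = 2)
}

#' Emulate an IVUS pullback from phantom ground truth
#'
#' Produces the per-millimetre pullback record an IVUS core laboratory
#' would: stations at 1 mm increments of pullback distance, lumen and
#' vessel (external elastic membrane) cross-sectional areas equal to the
#' analytic truth at the warp-inverse arclength, degraded by multiplicative
#' lognormal noise with the given coefficient of variation (unit mean, so
#' areas stay positive and unbiased).  Vessel area is floored at lumen area
#' after noise.  Calcified and attenuated angular arcs are copied from the
#' CP and LAP deposit sectors at each station.  Anchor landmarks are emitted
#' for the pullback start, end and every bifurcation, at warped positions.
#'
#' @param truth a [ground_truth()] (or a phantom).
#' @param area_noise_cv coefficient of variation of the area noise (>= 0).
#' @param warp strictly increasing function arclength mm -> pullback mm
#'   (default identity).
#' @param seed integer seed for the noise stream.
#' @return tibble of class `pullback_profile` with columns `station_mm`,
#'   `lumen_area_mm2`, `vessel_area_mm2`, `calc_arc_deg`, `atten_arc_deg`;
#'   anchors in the `anchors` attribute (tibble `position_mm`, `kind`).
#' @export
emulate_ivus_pullback <- function(truth, area_noise_cv = 0.05,
                                  warp = identity, seed = 1L) {
  if (inherits(truth, "phantom")) truth <- truth$truth
  stopifnot(inherits(truth, "ground_truth"))
  stop_if_not_number(area_noise_cv, "area_noise_cv", 0)
  spec <- truth$spec
  L <- truth$length_mm
  p0 <- warp(0)
  pL <- warp(L)
  if (pL <= p0) abort("warp must be strictly increasing")
  inv <- warp_inverse_fun(warp, L)
  stations <- seq(p0, pL, by = 1)
  s_true <- inv(stations)
  a <- truth_areas(spec, s_true)
  n <- length(stations)
  fac <- function() {
    if (area_noise_cv == 0) return(rep(1, n))
    s2 <- log(1 + area_noise_cv^2)
    exp(rnorm(n, -s2 / 2, sqrt(s2)))
  }
  prof <- with_rng(seed, {
    lum <- a$lumen_area_mm2 * fac()
    ves <- a$vessel_area_mm2 * fac()
    tibble(station_mm = stations, lumen_area_mm2 = lum,
           vessel_area_mm2 = pmax(ves, lum))
  })
  arcs <- deposit_arcs(spec, s_true)
  prof$calc_arc_deg <- arcs$calc
  prof$atten_arc_deg <- arcs$atten
  anchors <- tibble(
    position_mm = c(p0, warp(spec$bifurcations_mm), pL),
    kind = c("start", rep("bifurcation", length(spec$bifurcations_mm)),
             "end"))
  new_pullback_profile(prof, anchors)
}

deposit_arcs <- function(spec, s) {
  calc <- atten <- rep(0, length(s))
  if (nrow(spec$deposits)) {
    for (i in seq_len(nrow(spec$deposits))) {
      d <- spec$deposits[i, ]
      inax <- s >= d$start_mm & s < d$end_mm
      if (d$component == "CP") calc <- calc + inax * d$width_deg
      if (d$component == "LAP") atten <- atten + inax * d$width_deg
    }
  }
  list(calc = pmin(calc, 360), atten = pmin(atten, 360))
}

new_pullback_profile <- function(prof, anchors) {
  validate_pullback(prof, anchors)
  structure(prof, anchors = anchors,
            class = c("pullback_profile", class(tibble())))
}

#' Assemble a pullback profile from per-station tables
#'
#' @param stations tibble with `station_mm` (uniform 1 mm spacing),
#'   `lumen_area_mm2`, `vessel_area_mm2` and optionally `calc_arc_deg`,
#'   `atten_arc_deg`.
#' @param anchors tibble with `position_mm` and `kind` (`"start"`,
#'   `"bifurcation"` or `"end"`); exactly one start and one end, start
#'   before all bifurcations before end.
#' @return a `pullback_profile` tibble.
#' @export
pullback_profile <- function(stations, anchors = NULL) {
  stations <- as_tibble(stations)
  if (!"calc_arc_deg" %in% names(stations)) stations$calc_arc_deg <- 0
  if (!"atten_arc_deg" %in% names(stations)) stations$atten_arc_deg <- 0
  if (is.null(anchors)) {
    anchors <- tibble(position_mm = range(stations$station_mm),
                      kind = c("start", "end"))
  }
  new_pullback_profile(stations, anchors)
}

validate_pullback <- function(prof, anchors) {
  ds <- diff(prof$station_mm)
  if (length(ds) && (max(ds) - min(ds) > 1e-6)) {
    abort("pullback stations must be uniformly spaced")
  }
  if (any(prof$lumen_area_mm2 < 0) ||
      any(prof$vessel_area_mm2 < prof$lumen_area_mm2 - 1e-9)) {
    abort("pullback areas must satisfy vessel >= lumen >= 0")
  }
  arcs <- c(prof$calc_arc_deg, prof$atten_arc_deg)
  if (any(arcs < 0 | arcs > 360)) abort("arcs must lie in [0, 360] degrees")
  if (sum(anchors$kind == "start") != 1 || sum(anchors$kind == "end") != 1) {
    abort("anchors must include exactly one start and one end")
  }
  st <- anchors$position_mm[anchors$kind == "start"]
  en <- anchors$position_mm[anchors$kind == "end"]
  bif <- anchors$position_mm[anchors$kind == "bifurcation"]
  if (length(bif) && (any(bif <= st) || any(bif >= en))) {
    abort("bifurcation anchors must lie strictly between start and end")
  }
  invisible(TRUE)
}

#' Anchor landmarks of a pullback profile
#' @param profile a `pullback_profile`.
#' @return tibble with `position_mm`, `kind`.
#' @export
pullback_anchors <- function(profile) attr(profile, "anchors")
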