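#' Render a phantom specification into voxel data
#'
#' Voxelizes the analytic vessel geometry by supersampled sampling (3 per
#' axis by default, i.e. 27 sub-samples per voxel, averaged to fractional
#' occupancy -> partial volume), draws per-voxel HU values from the
#' per-region distributions, convolves with the Gaussian point-spread
#' function and adds voxel noise.  Label volumes (lumen/wall and per-component)
#' are taken from the analytic geometry at voxel centers and are noise-free.
#' Ground truth is computed analytically from the spec and never touches the
#' grid.
#'
#' @param spec a [phantom_spec()].
#' @param supersample sub-samples per axis for partial-volume occupancy.
#' @param margin_mm padding around the vessel bounding box (mm).
#' @return object of class `phantom`: list with `image` (an
#'   [image_volume()] of HU), `labels` (label volume, codes 0 background /
#'   1 lumen / 2 wall, plus a `component` array with codes 0 background /
#'   1 lumen / 2 CP / 3 NCP / 4 LAP), `centerline` (tibble) and `truth`
#'   (a [ground_truth()]).
#' @export
#' @examples
#' spec <- phantom_spec(length_mm = 10, voxel_mm = 0.5, seed = 7)
#' ph <- make_phantom(spec)
#' dim(ph$image$data)
make_phantom <- function(spec, supersample = 3L, margin_mm = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_wall_order(spec)
  cl <- phantom_centerline(spec, step_mm = 0.5)
  lut_s <- seq(0, spec$length_mm, by = 0.05)
  lut_rl <- lumen_radius(spec, lut_s)
  lut_ro <- outer_radius(spec, lut_s)
  rmax <- max(lut_ro)
  lo <- c(min(cl$x) - rmax - margin_mm, min(cl$y) - rmax - margin_mm,
          min(cl$z) - margin_mm)
  hi <- c(max(cl$x) + rmax + margin_mm, max(cl$y) + rmax + margin_mm,
          max(cl$z) + margin_mm)
  vox <- spec$voxel_mm
  # snap the grid to integer voxel multiples so the vessel axis passes
  # through voxel centers; avoids a half-voxel quantization bias in areas
  origin <- vox * floor(lo / vox)
  dims <- as.integer(ceiling((hi - origin) / vox)) + 1L
  dep <- deposit_matrix(spec)
  rend <- render_phantom_cpp(dims, rep(vox, 3), origin,
                             as.matrix(cl[, c("x", "y", "z")]), cl$s_mm,
                             spec$centerline_kind == "straight",
                             lut_s, lut_rl, lut_ro, dep,
                             as.integer(supersample))
  nvox <- prod(dims)
  occ <- matrix(rend$occupancy, nrow = nvox, ncol = 5)
  hp <- spec$hu_params
  cp_floor <- max(350, hp$lumen[1] + hp$lumen[2])
  hu <- with_rng(spec$seed, {
    draws <- cbind(
      rnorm(nvox, hp$background[1], hp$background[2]),
      rnorm(nvox, hp$lumen[1], hp$lumen[2]),
      rtruncnorm_lower(nvox, hp$cp[1], hp$cp[2], cp_floor),
      rnorm(nvox, hp$ncp[1], hp$ncp[2]),
      rnorm(nvox, hp$lap[1], hp$lap[2]))
    h <- rowSums(occ * draws)
    if (spec$psf_sigma_mm > 0) {
      h <- gauss_blur3d_cpp(h, dims, rep(spec$psf_sigma_mm / vox, 3))
    }
    if (spec$noise_sd_hu > 0) h <- h + rnorm(nvox, 0, spec$noise_sd_hu)
    h
  })
  img <- image_volume(array(as.numeric(hu), dims), spacing = rep(vox, 3),
                      origin = origin)
  region <- array(rend$region, dims)
  lab <- region
  lab[region >= 2L] <- 2L
  labels <- structure(list(label = lab, component = region,
                           spacing = rep(vox, 3), origin = origin),
                      class = "label_volume")
  structure(list(image = img, labels = labels, centerline = cl,
                 truth = ground_truth(spec), spec = spec),
            class = "phantom")
}

# Truncated normal (lower bound) via inverse-CDF; keeps calcium draws at or
# above the nominal adaptive threshold.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(runif(n, p0, 1))
}

deposit_matrix <- function(spec) {
  d <- spec$deposits
  if (!nrow(d)) return(matrix(numeric(), 0, 5))
  code <- c(CP = 2, NCP = 3, LAP = 4)[d$component]
  cbind(d$start_mm, d$end_mm, d$start_deg %% 360,
        d$start_deg %% 360 + d$width_deg, code)
}

#' Analytic centerline of a phantom
#'
#' @param spec a [phantom_spec()].
#' @param step_mm arclength step of the returned polyline (mm).
#' @return tibble with columns `x`, `y`, `z`, `s_mm`, class `centerline`.
#' @export
phantom_centerline <- function(spec, step_mm = 0.5) {
  s <- seq(0, spec$length_mm, by = step_mm)
  if (s[length(s)] < spec$length_mm) s <- c(s, spec$length_mm)
  if (spec$centerline_kind == "straight") {
    pts <- tibble(x = 0, y = 0, z = s, s_mm = s)
  } else {
    R <- spec$helix_radius_mm
    b <- spec$helix_pitch_mm / (2 * pi)
    c0 <- sqrt(R^2 + b^2)
    t <- s / c0
    pts <- tibble(x = R * cos(t) - R, y = R * sin(t), z = b * t, s_mm = s)
  }
  structure(pts, class = c("centerline", class(tibble())))
}

#' Construct an image volume
#'
#' Minimal container for a scalar 3D grid: data array, per-axis voxel
#' spacing (mm) and world origin of voxel (1,1,1) (mm).
#'
#' @param data 3D numeric array.
#' @param spacing length-3 positive voxel spacing (mm).
#' @param origin length-3 world position of the first voxel center (mm).
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive values")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %.3g x %.3g x %.3g mm\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$spec)
  print(x$image)
  invisible(x)
}
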