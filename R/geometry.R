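#' Resample a centerline to uniform arclength spacing
#'
#' Chord-length parameterizes the ordered 3D polyline and linearly
#' interpolates positions at uniform arclength steps, preserving both
#' endpoints (the final station lands exactly on the distal endpoint even
#' when the total length is not a multiple of `step_mm`).  Arclength is
#' measured proximal to distal, zero at the ostial end.
#'
#' @param points a data frame or matrix with columns/cols `x`, `y`, `z` (mm).
#' @param step_mm arclength step (mm, > 0).
#' @return tibble with `x`, `y`, `z`, `s_mm`; class `centerline`.
#' @export
#' @examples
#' cl <- resample_centerline(data.frame(x = 0, y = 0, z = c(0, 10)), 0.5)
#' nrow(cl)  # 21 stations
resample_centerline <- function(points, step_mm = 0.5) {
  stop_if_not_number(step_mm, "step_mm", 0, strict = TRUE)
  p <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  storage.mode(p) <- "double"
  if (nrow(p) < 2) abort("centerline needs at least 2 distinct points")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) {
    abort(sprintf("duplicate consecutive centerline points at index %d",
                  which(seg == 0)[1]))
  }
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  out_s <- seq(0, L, by = step_mm)
  if (out_s[length(out_s)] < L - 1e-9) out_s <- c(out_s, L)
  out_s[length(out_s)] <- L
  structure(
    tibble(x = approx(s, p[, 1], out_s)$y,
           y = approx(s, p[, 2], out_s)$y,
           z = approx(s, p[, 3], out_s)$y,
           s_mm = out_s),
    class = c("centerline", class(tibble())))
}

#' Volume of an area profile by Simpson's rule
#'
#' Composite Simpson integration of a uniformly spaced cross-sectional area
#' profile.  When the number of intervals is odd, the final three intervals
#' are integrated with the Simpson 3/8 rule, so the rule is exact for
#' quadratic (and cubic) profiles regardless of station count.
#'
#' @param areas non-negative per-station areas (mm^2), length >= 3.
#' @param spacing_mm uniform station spacing (mm).
#' @return volume in mm^3.
#' @export
#' @examples
#' simpson_volume(rep(10, 41), 0.5)      # 200 mm^3
#' s <- seq(0, 2, length.out = 5)
#' simpson_volume(s^2, 0.5)              # 8/3, exact
simpson_volume <- function(areas, spacing_mm) {
  stop_if_not_number(spacing_mm, "spacing_mm", 0, strict = TRUE)
  n <- length(areas)
  if (n < 3) abort("Simpson integration needs at least 3 stations")
  if (any(!is.finite(areas))) abort("areas must be finite")
  if (any(areas < 0)) abort("areas must be non-negative")
  w <- simpson_weights(n)
  sum(w * areas) * spacing_mm
}

simpson_weights <- function(n) {
  nseg <- n - 1L
  w <- numeric(n)
  if (nseg %% 2L == 0L) {
    w <- c(1, rep(c(4, 2), length.out = n - 2L), 1) / 3
    w[n] <- 1 / 3
  } else if (nseg == 3L) {
    w <- c(1, 3, 3, 1) * 3 / 8
  } else {
    m <- n - 3L  # stations in the leading even-interval block
    w[1:m] <- c(1, rep(c(4, 2), length.out = m - 2L), 1) / 3
    w[m] <- 1 / 3
    w[m:n] <- w[m:n] + c(1, 3, 3, 1) * 3 / 8
  }
  w
}

#' Integrate an area profile over a sub-interval
#'
#' Restricts a (possibly non-uniform) station profile to `[start_mm,
#' end_mm]`, resamples it to uniform spacing by linear interpolation, and
#' integrates with [simpson_volume()].
#'
#' @param s_mm station positions (mm), strictly increasing.
#' @param areas per-station areas (mm^2).
#' @param start_mm,end_mm integration bounds, within the station range.
#' @param step_mm target resampling step (mm).
#' @return volume in mm^3.
#' @export
profile_volume <- function(s_mm, areas, start_mm = min(s_mm),
                           end_mm = max(s_mm), step_mm = 0.5) {
  if (end_mm <= start_mm) abort("integration interval has non-positive length")
  if (start_mm < min(s_mm) - 1e-9 || end_mm > max(s_mm) + 1e-9) {
    abort("integration interval extends beyond the profile")
  }
  npt <- max(5L, as.integer(ceiling((end_mm - start_mm) / step_mm)) + 1L)
  grid <- seq(start_mm, end_mm, length.out = npt)
  a <- approx(s_mm, areas, grid, rule = 2)$y
  simpson_volume(pmax(a, 0), grid[2] - grid[1])
}

# ---- interpolation on voxel grids ---------------------------------------

# Continuous (0-based) voxel coordinates of world points.
grid_coords <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
}

# Nearest-voxel lookup; NA outside the volume.
sample_nearest <- function(arr, pts, spacing, origin) {
  g <- round(grid_coords(pts, spacing, origin))
  d <- dim(arr)
  ok <- g[, 1] >= 0 & g[, 1] < d[1] & g[, 2] >= 0 & g[, 2] < d[2] &
    g[, 3] >= 0 & g[, 3] < d[3]
  out <- rep(NA_real_, nrow(pts))
  idx <- 1 + g[ok, 1] + d[1] * (g[ok, 2] + d[2] * g[ok, 3])
  out[ok] <- arr[idx]
  out
}

# Trilinear interpolation; NA outside the volume.
sample_trilinear <- function(arr, pts, spacing, origin) {
  g <- grid_coords(pts, spacing, origin)
  d <- dim(arr)
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= d[1] - 2 & i0[, 2] >= 0 &
    i0[, 2] <= d[2] - 2 & i0[, 3] >= 0 & i0[, 3] <= d[3] - 2
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  base <- 1 + i0[, 1] + d[1] * (i0[, 2] + d[2] * i0[, 3])
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base];            v100 <- arr[base + sx]
  v010 <- arr[base + sy];       v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];       v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];  v111 <- arr[base + sx + sy + sz]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
    (c01 * (1 - fy) + c11 * fy) * fz
  out
}

#' Extract per-station cross-sectional areas along a centerline
#'
#' At each arclength station a plane orthogonal to the local centerline
#' tangent is sampled on a square grid of pitch `inplane_res_mm`.  In-plane
#' membership is decided by the label at the sample center (nearest voxel,
#' no anti-aliasing): lumen area counts lumen-labeled samples, vessel area
#' counts lumen-or-wall samples, each times `inplane_res_mm^2`; plaque area
#' is vessel minus lumen by construction.  Wall-sample HU values (trilinear
#' interpolation of the image) are retained per station in a list column for
#' downstream characterization.  Stations whose sampling plane exits the
#' volume are dropped; their count is recorded in the `n_excluded`
#' attribute.
#'
#' @param image an [image_volume()] of HU.
#' @param labels the paired label volume (codes 0/1/2 =
#'   background/lumen/wall).
#' @param centerline data frame with `x`, `y`, `z` (mm).
#' @param step_mm station spacing along the centerline (mm).
#' @param inplane_res_mm in-plane sampling pitch (mm).
#' @param half_width_mm half-extent of the sampling plane (mm).
#' @return tibble of class `cross_sections`: `s_mm`, `lumen_area_mm2`,
#'   `vessel_area_mm2`, `plaque_area_mm2`, `wall_hu` (list of HU vectors);
#'   attributes `step_mm`, `inplane_res_mm`, `n_excluded`.
#' @export
extract_cross_sections <- function(image, labels, centerline, step_mm = 0.5,
                                   inplane_res_mm = 0.1, half_width_mm = 4) {
  stopifnot(inherits(image, "image_volume"))
  cl <- resample_centerline(centerline, step_mm)
  p <- as.matrix(cl[, c("x", "y", "z")])
  n <- nrow(p)
  tg <- rbind(p[2, ] - p[1, ],
              (p[-(1:2), , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / 2,
              p[n, ] - p[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  off <- seq(-half_width_mm, half_width_mm, by = inplane_res_mm)
  uv <- as.matrix(expand.grid(u = off, v = off))
  a_px <- inplane_res_mm^2
  rows <- vector("list", n)
  excluded <- 0L
  for (i in seq_len(n)) {
    t <- tg[i, ]
    ref <- if (abs(t[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
    e1 <- ref - sum(ref * t) * t
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t[2] * e1[3] - t[3] * e1[2],
            t[3] * e1[1] - t[1] * e1[3],
            t[1] * e1[2] - t[2] * e1[1])
    pts <- cbind(p[i, 1] + uv[, 1] * e1[1] + uv[, 2] * e2[1],
                 p[i, 2] + uv[, 1] * e1[2] + uv[, 2] * e2[2],
                 p[i, 3] + uv[, 1] * e1[3] + uv[, 2] * e2[3])
    lab <- sample_nearest(labels$label, pts, labels$spacing, labels$origin)
    if (anyNA(lab)) {
      excluded <- excluded + 1L
      next
    }
    wall <- lab == 2
    hu <- if (any(wall)) {
      sample_trilinear(image$data, pts[wall, , drop = FALSE], image$spacing,
                       image$origin)
    } else numeric()
    rows[[i]] <- tibble(
      s_mm = cl$s_mm[i],
      lumen_area_mm2 = sum(lab == 1) * a_px,
      vessel_area_mm2 = sum(lab >= 1) * a_px,
      wall_hu = list(hu[!is.na(hu)]))
  }
  out <- bind_rows(rows)
  out$plaque_area_mm2 <- out$vessel_area_mm2 - out$lumen_area_mm2
  out <- out[, c("s_mm", "lumen_area_mm2", "vessel_area_mm2",
                 "plaque_area_mm2", "wall_hu")]
  if (excluded > 0) {
    warn(sprintf("%d station(s) excluded: sampling plane exits the volume",
                 excluded))
  }
  structure(out, class = c("cross_sections", class(tibble())),
            step_mm = step_mm, inplane_res_mm = inplane_res_mm,
            n_excluded = excluded)
}
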