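#' Adaptive calcified-plaque threshold from lumen attenuation
#'
#' The calcium threshold adapts to lumen contrast enhancement: it is the
#' maximum of 350 HU and the mean lumen intensity plus one sample standard
#' deviation (n - 1 denominator) of the lumen intensities.
#'
#' @param lumen_hu HU samples from the contrast-enhanced lumen (>= 2 values).
#' @return threshold in HU (never below 350).
#' @export
#' @examples
#' adaptive_cp_threshold(c(380, 400, 420))  # mean + SD > 350
adaptive_cp_threshold <- function(lumen_hu) {
  lumen_hu <- lumen_hu[is.finite(lumen_hu)]
  if (length(lumen_hu) < 2) {
    abort("adaptive threshold needs at least 2 lumen HU samples")
  }
  max(350, mean(lumen_hu) + sd(lumen_hu))
}

#' Plaque-component HU thresholds
#'
#' Fixed low-attenuation window bounds (-30 and 30 HU) plus the per-vessel
#' adaptive calcium threshold.  Intervals are half-open so the component
#' partition is exact: excluded `(-Inf, -30)`, LAP `[-30, 30)`, NCP
#' `[30, cp)`, CP `[cp, Inf)`.
#'
#' @param cp_threshold_hu calcium threshold (HU, >= 350), typically from
#'   [adaptive_cp_threshold()].
#' @return object of class `component_thresholds`.
#' @export
component_thresholds <- function(cp_threshold_hu = 350) {
  stop_if_not_number(cp_threshold_hu, "cp_threshold_hu", 350)
  structure(list(lap_low = -30, lap_high = 30,
                 cp_threshold = cp_threshold_hu),
            class = "component_thresholds")
}

#' @export
print.component_thresholds <- function(x, ...) {
  cat(sprintf(
    "<component_thresholds> LAP [%g, %g) HU, NCP [%g, %g) HU, CP >= %g HU\n",
    x$lap_low, x$lap_high, x$lap_high, x$cp_threshold, x$cp_threshold))
  invisible(x)
}

#' Classify wall HU samples into plaque components
#'
#' @param hu numeric vector of wall-sample HU values.
#' @param thresholds a [component_thresholds()].
#' @return factor with levels `excluded`, `LAP`, `NCP`, `CP`.
#' @export
#' @examples
#' th <- component_thresholds(460)
#' classify_wall_sample(c(-100, 0, 100, 500), th)
classify_wall_sample <- function(hu, thresholds) {
  stopifnot(inherits(thresholds, "component_thresholds"))
  out <- character(length(hu))
  out[hu < thresholds$lap_low] <- "excluded"
  out[hu >= thresholds$lap_low & hu < thresholds$lap_high] <- "LAP"
  out[hu >= thresholds$lap_high & hu < thresholds$cp_threshold] <- "NCP"
  out[hu >= thresholds$cp_threshold] <- "CP"
  factor(out, levels = c("excluded", "LAP", "NCP", "CP"))
}

#' Add per-station component areas to a cross-section series
#'
#' Classifies each station's retained wall HU samples with
#' [classify_wall_sample()] and converts counts to areas.  The four
#' component areas (CP, NCP-window, LAP, excluded) sum exactly to the plaque
#' area at every station.
#'
#' @param series a `cross_sections` tibble from [extract_cross_sections()].
#' @param thresholds a [component_thresholds()].
#' @return the series with `cp_area_mm2`, `ncp_area_mm2`, `lap_area_mm2`,
#'   `excluded_area_mm2` columns; thresholds stored in the
#'   `component_thresholds` attribute.
#' @export
classify_sections <- function(series, thresholds) {
  if (!"wall_hu" %in% names(series)) {
    abort("series has no `wall_hu` samples; run extract_cross_sections() first")
  }
  a_px <- attr(series, "inplane_res_mm")^2
  counts <- purrr::map(series$wall_hu, function(hu) {
    table(classify_wall_sample(hu, thresholds))
  })
  series$cp_area_mm2 <- purrr::map_dbl(counts, ~ .x[["CP"]]) * a_px
  series$ncp_area_mm2 <- purrr::map_dbl(counts, ~ .x[["NCP"]]) * a_px
  series$lap_area_mm2 <- purrr::map_dbl(counts, ~ .x[["LAP"]]) * a_px
  series$excluded_area_mm2 <- purrr::map_dbl(counts, ~ .x[["excluded"]]) * a_px
  attr(series, "component_thresholds") <- thresholds
  series
}

#' Aggregate component areas into plaque volumes
#'
#' Integrates each component area profile with [simpson_volume()].  Total
#' plaque volume (TPV) is the sum of the classified component volumes
#' (CP + NCP-window + LAP); reported NCP is TPV minus CP, so LAP is a
#' sub-component of NCP and the CP / NCP percentages of TPV sum to 100.
#' Wall volume below the LAP window (-30 HU) is excluded from TPV and
#' reported separately.
#'
#' @param series a classified `cross_sections` tibble
#'   (see [classify_sections()]).
#' @param spacing_mm station spacing; defaults to the series' own step.
#' @return one-row tibble of class `plaque_volumes`: `tpv_mm3`, `cp_mm3`,
#'   `ncp_mm3`, `lap_mm3`, `pct_cp`, `pct_ncp`, `pct_lap`,
#'   `excluded_below_lap_mm3`, `lumen_mm3`, `vessel_mm3`.  Percentages are
#'   `NA` when TPV is zero.
#' @export
component_volumes <- function(series, spacing_mm = attr(series, "step_mm")) {
  needed <- c("cp_area_mm2", "ncp_area_mm2", "lap_area_mm2",
              "excluded_area_mm2")
  if (!all(needed %in% names(series))) {
    abort("series lacks component areas; run classify_sections() first")
  }
  lens <- lengths(series[c("s_mm", needed)])
  if (length(unique(lens)) != 1) abort("inconsistent series column lengths")
  if (is.null(spacing_mm)) {
    spacing_mm <- diff(series$s_mm[1:2])
  }
  ds <- diff(series$s_mm)
  if (max(ds) - min(ds) > 1e-6) {
    abort("series stations are not uniformly spaced; resample first")
  }
  integ <- function(col) simpson_volume(series[[col]], spacing_mm)
  cp <- integ("cp_area_mm2")
  ncp_win <- integ("ncp_area_mm2")
  lap <- integ("lap_area_mm2")
  tpv <- cp + ncp_win + lap
  ncp <- tpv - cp
  pct <- function(v) if (tpv > 0) 100 * v / tpv else NA_real_
  structure(
    tibble(tpv_mm3 = tpv, cp_mm3 = cp, ncp_mm3 = ncp, lap_mm3 = lap,
           pct_cp = pct(cp), pct_ncp = pct(ncp), pct_lap = pct(lap),
           excluded_below_lap_mm3 = integ("excluded_area_mm2"),
           lumen_mm3 = integ("lumen_area_mm2"),
           vessel_mm3 = integ("vessel_area_mm2")),
    class = c("plaque_volumes", class(tibble())))
}

#' Lumen HU samples for the adaptive threshold
#'
#' Collects image HU at lumen-labeled voxels after one-voxel (6-neighbor)
#' morphological erosion of the lumen mask, suppressing partial-volume
#' contamination at the lumen boundary.
#'
#' @param image an [image_volume()].
#' @param labels the paired label volume.
#' @return numeric vector of HU samples (falls back to the uneroded lumen
#'   when erosion empties the mask).
#' @export
lumen_hu_samples <- function(image, labels) {
  m <- labels$label == 1L
  er <- erode6(m)
  if (!any(er)) er <- m
  as.numeric(image$data[er])
}

erode6 <- function(m) {
  d <- dim(m)
  out <- m
  pad <- function(arr, axis, dir) {
    idx <- lapply(d, seq_len)
    src <- idx
    if (dir > 0) {
      idx[[axis]] <- seq_len(d[axis] - 1)
      src[[axis]] <- 2:d[axis]
    } else {
      idx[[axis]] <- 2:d[axis]
      src[[axis]] <- seq_len(d[axis] - 1)
    }
    res <- array(FALSE, d)
    res[idx[[1]], idx[[2]], idx[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (axis in 1:3) for (dir in c(-1, 1)) out <- out & pad(m, axis, dir)
  out
}

#' Quantify and characterize plaque from a CT volume
#'
#' End-to-end CT-side quantification: computes the per-vessel adaptive
#' calcium threshold from eroded lumen voxels, extracts per-station
#' cross-sectional areas along the centerline, and classifies wall samples
#' into components.
#'
#' @inheritParams extract_cross_sections
#' @return a classified `cross_sections` tibble (see [classify_sections()]).
#' @export
ccta_quantify <- function(image, labels, centerline, step_mm = 0.5,
                          inplane_res_mm = 0.1, half_width_mm = 4) {
  thr <- component_thresholds(
    adaptive_cp_threshold(lumen_hu_samples(image, labels)))
  series <- extract_cross_sections(image, labels, centerline,
                                   step_mm = step_mm,
                                   inplane_res_mm = inplane_res_mm,
                                   half_width_mm = half_width_mm)
  classify_sections(series, thr)
}
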