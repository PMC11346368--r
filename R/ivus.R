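#' Per-station plaque burden of a pullback
#'
#' Plaque-plus-media area is vessel (EEM) minus lumen area; plaque burden
#' is that as a percentage of vessel area.  Stations with zero vessel area
#' get `NA` burden.
#'
#' @param profile a `pullback_profile` tibble.
#' @return the profile with a `burden_pct` column.
#' @export
#' @examples
#' p <- pullback_profile(tibble::tibble(
#'   station_mm = 0:4, lumen_area_mm2 = 10, vessel_area_mm2 = 20))
#' plaque_burden_profile(p)$burden_pct  # all 50
plaque_burden_profile <- function(profile) {
  bad <- which(profile$lumen_area_mm2 > profile$vessel_area_mm2 + 1e-9)
  if (length(bad)) {
    abort(sprintf("lumen exceeds vessel area at station %d (%.1f mm)",
                  bad[1], profile$station_mm[bad[1]]))
  }
  profile$burden_pct <- ifelse(
    profile$vessel_area_mm2 > 0,
    100 * (profile$vessel_area_mm2 - profile$lumen_area_mm2) /
      profile$vessel_area_mm2,
    NA_real_)
  profile
}

#' Detect lesions from a plaque-burden profile
#'
#' A lesion is a maximal run of consecutive stations with plaque burden at
#' or above `burden_threshold` whose length is at least `min_length_mm`.
#' Stations are point measurements, so a run of k stations at spacing h
#' spans (k - 1) * h mm: at 1 mm spacing the 2 mm minimum requires 3
#' consecutive qualifying stations.  Runs are strictly contiguous (no gap
#' bridging) and returned proximal to distal.
#'
#' @param burden per-station burden (percent), or a profile tibble with a
#'   `burden_pct` column (computed on the fly from areas if absent).
#' @param spacing_mm station spacing (mm).
#' @param burden_threshold qualifying burden (percent).
#' @param min_length_mm minimum lesion length (mm).
#' @param positions_mm optional station positions; defaults to the profile's
#'   stations or `0, spacing, ...`.
#' @return tibble of class `lesion_table`: `lesion`, `start_mm`, `end_mm`,
#'   `length_mm`, `max_burden_pct`, `start_idx`, `end_idx`.
#' @export
#' @examples
#' detect_lesions(c(30, 45, 46, 47, 30))  # one lesion, 2 mm
detect_lesions <- function(burden, spacing_mm = 1, burden_threshold = 40,
                           min_length_mm = 2, positions_mm = NULL) {
  if (is.data.frame(burden)) {
    prof <- burden
    if (!"burden_pct" %in% names(prof)) prof <- plaque_burden_profile(prof)
    positions_mm <- prof$station_mm
    spacing_mm <- if (nrow(prof) > 1) diff(prof$station_mm[1:2]) else spacing_mm
    burden <- prof$burden_pct
  }
  if (is.null(positions_mm)) {
    positions_mm <- (seq_along(burden) - 1) * spacing_mm
  }
  qual <- !is.na(burden) & burden >= burden_threshold
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths - 1L) * spacing_mm >= min_length_mm - 1e-9
  out <- tibble(
    start_idx = starts[keep], end_idx = ends[keep]) |>
    mutate(start_mm = positions_mm[.data$start_idx],
           end_mm = positions_mm[.data$end_idx],
           length_mm = .data$end_mm - .data$start_mm,
           max_burden_pct = purrr::map2_dbl(
             .data$start_idx, .data$end_idx,
             ~ max(burden[.x:.y])),
           lesion = row_number()) |>
    select("lesion", "start_mm", "end_mm", "length_mm", "max_burden_pct",
           "start_idx", "end_idx")
  structure(out, class = c("lesion_table", class(tibble())))
}

#' Qualitative component areas under the full-thickness assumption
#'
#' Ultrasound cannot see behind calcium or attenuated plaque, so the entire
#' wall thickness under a calcified or attenuated surface arc is assumed to
#' be that component: component area = (arc / 360) x (vessel - lumen).
#' Remaining plaque area is unclassified non-calcified plaque.
#'
#' @param profile a `pullback_profile` with `calc_arc_deg` and
#'   `atten_arc_deg` columns.
#' @return the profile with `plaque_area_mm2`, `calc_area_mm2`,
#'   `atten_area_mm2` columns.
#' @export
qualitative_component_areas <- function(profile) {
  over <- which(profile$calc_arc_deg + profile$atten_arc_deg > 360 + 1e-9)
  if (length(over)) {
    abort(sprintf(
      "calcified + attenuated arcs exceed 360 degrees at station %d", over[1]))
  }
  profile$plaque_area_mm2 <- profile$vessel_area_mm2 - profile$lumen_area_mm2
  profile$calc_area_mm2 <- profile$calc_arc_deg / 360 * profile$plaque_area_mm2
  profile$atten_area_mm2 <-
    profile$atten_arc_deg / 360 * profile$plaque_area_mm2
  profile
}

#' Per-lesion IVUS volumes by Simpson's rule
#'
#' Integrates lumen, vessel, plaque and qualitative component area profiles
#' over each lesion interval with [simpson_volume()] (after restriction and
#' uniform resampling via [profile_volume()]).  Reported non-calcified
#' plaque is plaque minus calcified.
#'
#' @param profile a `pullback_profile`.
#' @param lesions a `lesion_table` from [detect_lesions()] (or any tibble
#'   with `start_mm` / `end_mm` within the pullback range).
#' @param step_mm resampling step for the restricted integrals (mm).
#' @return tibble, one row per lesion: `lesion`, `start_mm`, `end_mm`,
#'   `lumen_mm3`, `vessel_mm3`, `tpv_mm3`, `cp_mm3`, `ncp_mm3`,
#'   `atten_mm3`.
#' @export
ivus_lesion_volumes <- function(profile, lesions, step_mm = 1) {
  profile <- qualitative_component_areas(profile)
  rng <- range(profile$station_mm)
  purrr::pmap(list(lesions[["lesion"]] %||% seq_len(nrow(lesions)),
                   lesions$start_mm, lesions$end_mm),
              function(id, a, b) {
    if (b <= a) abort(sprintf("lesion %s has non-positive length", id))
    if (a < rng[1] - 1e-9 || b > rng[2] + 1e-9) {
      abort(sprintf("lesion %s extends outside the pullback range", id))
    }
    vol <- function(col) {
      profile_volume(profile$station_mm, profile[[col]], a, b,
                     step_mm = step_mm)
    }
    tpv <- vol("plaque_area_mm2")
    cp <- vol("calc_area_mm2")
    tibble(lesion = id, start_mm = a, end_mm = b,
           lumen_mm3 = vol("lumen_area_mm2"),
           vessel_mm3 = vol("vessel_area_mm2"),
           tpv_mm3 = tpv, cp_mm3 = cp, ncp_mm3 = tpv - cp,
           atten_mm3 = vol("atten_area_mm2"))
  }) |> bind_rows()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
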