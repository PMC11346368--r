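#' Build a monotone warp from IVUS pullback positions to CCTA arclength
#'
#' The base map is piecewise-linear through the matched anchor pairs
#' (pullback start, bifurcations in order, pullback end on the IVUS side;
#' the corresponding arclengths on the CCTA side).  With `refine = TRUE`,
#' each inter-anchor segment is subdivided by inserting knots chosen by a
#' monotone dynamic program that matches 5 mm windows of the two (linearly
#' resampled, globally z-scored) lumen-area profiles, with candidate shifts
#' bounded to +/-20% of the segment length and a monotonicity constraint.
#' Windows are scored by negative mean squared difference of the z-scored
#' profiles, which localizes alignment even on monotone ramps where a
#' per-window-normalized correlation is shift-insensitive; a small quadratic
#' shift penalty keeps featureless stretches on the anchored linear map.
#' The refined map still passes exactly through every anchor.
#'
#' @param ivus a `pullback_profile` (anchors attached).
#' @param ccta a cross-section series (needs `s_mm` and `lumen_area_mm2`).
#' @param ccta_anchors tibble with `position_mm` and `kind`, matching the
#'   IVUS anchors one-to-one in order (start, bifurcations, end).
#' @param refine refine between anchors by profile correlation?
#' @param window_mm correlation window length (mm).
#' @param pitch_mm resampling pitch for refinement (mm).
#' @param max_shift_frac shift bound as a fraction of segment length.
#' @param knot_spacing_mm approximate spacing of inserted knots (mm).
#' @return object of class `warp_map`.
#' @export
build_warp <- function(ivus, ccta, ccta_anchors, refine = FALSE,
                       window_mm = 5, pitch_mm = 0.25, max_shift_frac = 0.2,
                       knot_spacing_mm = 2.5) {
  ia <- pullback_anchors(ivus)
  ca <- as_tibble(ccta_anchors)
  if (is.null(ia)) abort("IVUS profile carries no anchors")
  ia <- arrange(ia, .data$position_mm)
  ca <- arrange(ca, .data$position_mm)
  if (nrow(ia) != nrow(ca)) {
    abort(sprintf("anchor counts differ: %d (IVUS) vs %d (CCTA)",
                  nrow(ia), nrow(ca)))
  }
  if (!identical(ia$kind, ca$kind)) {
    abort("anchor kinds do not match one-to-one in order")
  }
  if (any(diff(ia$position_mm) <= 0) || any(diff(ca$position_mm) <= 0)) {
    abort("degenerate (zero-length) anchor segment")
  }
  knots <- tibble(ivus_mm = ia$position_mm, ccta_mm = ca$position_mm,
                  anchor = TRUE)
  if (refine) {
    knots <- refine_warp_knots(knots, ivus, ccta, window_mm, pitch_mm,
                               max_shift_frac, knot_spacing_mm)
  }
  new_warp_map(knots)
}

new_warp_map <- function(knots) {
  knots <- arrange(knots, .data$ivus_mm)
  if (any(diff(knots$ivus_mm) <= 0) || any(diff(knots$ccta_mm) <= 0)) {
    abort("warp knots must be strictly increasing on both sides")
  }
  structure(list(knots = knots), class = "warp_map")
}

#' @export
print.warp_map <- function(x, ...) {
  cat(sprintf("<warp_map> %d knots (%d anchors), domain [%.1f, %.1f] mm\n",
              nrow(x$knots), sum(x$knots$anchor),
              min(x$knots$ivus_mm), max(x$knots$ivus_mm)))
  invisible(x)
}

#' Apply or invert a warp map
#'
#' @param warp a `warp_map`.
#' @param x positions (mm).
#' @return mapped positions (mm).
#' @export
warp_apply <- function(warp, x) {
  k <- warp$knots
  rng <- range(k$ivus_mm)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9)) {
    abort("position outside the warp domain")
  }
  approx(k$ivus_mm, k$ccta_mm, pmin(pmax(x, rng[1]), rng[2]))$y
}

#' @rdname warp_apply
#' @export
warp_invert <- function(warp, x) {
  k <- warp$knots
  rng <- range(k$ccta_mm)
  if (any(x < rng[1] - 1e-9 | x > rng[2] + 1e-9)) {
    abort("position outside the warp range")
  }
  approx(k$ccta_mm, k$ivus_mm, pmin(pmax(x, rng[1]), rng[2]))$y
}

#' Map a pullback interval to CCTA arclength
#'
#' @param warp a `warp_map`.
#' @param start_mm,end_mm interval endpoints on the IVUS side (mm).
#' @return named numeric `c(start_mm, end_mm)` on the CCTA side.
#' @export
map_interval <- function(warp, start_mm, end_mm) {
  if (end_mm <= start_mm) abort("interval must have positive length")
  out <- warp_apply(warp, c(start_mm, end_mm))
  c(start_mm = out[1], end_mm = out[2])
}

# z-scored linear resampling of a profile onto a uniform grid; NA outside.
zscore_resampled <- function(pos, val, pitch) {
  grid <- seq(min(pos), max(pos), by = pitch)
  v <- approx(pos, val, grid)$y
  list(grid = grid, z = (v - mean(v)) / max(sd(v), 1e-12))
}

# Subdivide each inter-anchor segment with knots chosen by a monotone
# dynamic program: candidate shifts (bounded to +/- max_shift_frac of the
# segment length) are scored by windowed matching of the globally z-scored
# lumen profiles (negative mean squared difference; amplitude-sensitive, so
# it localizes on ramps), with a quadratic penalty that pulls featureless
# stretches back to the linear (anchored) map.  The DP enforces strict
# monotonicity with a minimum slope margin, so knots can never cross each
# other or an anchor.
refine_warp_knots <- function(knots, ivus, ccta, window_mm, pitch_mm,
                              max_shift_frac, knot_spacing_mm,
                              lambda = 0.01, min_slope = 0.2) {
  iv <- zscore_resampled(ivus$station_mm, ivus$lumen_area_mm2, pitch_mm)
  cc <- zscore_resampled(ccta$s_mm, ccta$lumen_area_mm2, pitch_mm)
  wgrid <- seq(-window_mm / 2, window_mm / 2, by = pitch_mm)
  out <- knots[1, ]
  for (seg in seq_len(nrow(knots) - 1)) {
    a <- knots$ivus_mm[seg]; b <- knots$ivus_mm[seg + 1]
    sa <- knots$ccta_mm[seg]; sb <- knots$ccta_mm[seg + 1]
    nk <- max(0L, as.integer(round((b - a) / knot_spacing_mm)) - 1L)
    slope <- (sb - sa) / (b - a)
    win_iv <- function(center) approx(iv$grid, iv$z, center + wgrid)$y
    # CCTA window scaled by the anchored segment slope so both windows
    # cover corresponding anatomy even when pullback speed deviates from 1
    win_cc <- function(center) approx(cc$grid, cc$z, center + slope * wgrid)$y
    if (nk > 0) {
      ps <- seq(a, b, length.out = nk + 2L)[-c(1, nk + 2L)]
      m <- max_shift_frac * (sb - sa)
      dgrid <- seq(-m, m, by = pitch_mm)
      nd <- length(dgrid)
      # node scores: profile-match score per (knot, shift)
      score <- matrix(-Inf, nk, nd)
      slin <- sa + (ps - a) * (sb - sa) / (b - a)
      for (j in seq_len(nk)) {
        wiv <- win_iv(ps[j])
        lo <- sa + min_slope * (ps[j] - a)
        hi <- sb - min_slope * (b - ps[j])
        for (d in seq_len(nd)) {
          s <- slin[j] + dgrid[d]
          if (s <= lo || s >= hi) next
          wcc <- win_cc(s)
          okm <- is.finite(wiv) & is.finite(wcc)
          sc <- if (sum(okm) >= 7) -mean((wiv[okm] - wcc[okm])^2) else 0
          score[j, d] <- sc - lambda * dgrid[d]^2
        }
      }
      # monotone DP over shifts
      best <- score[1, ]
      back <- matrix(0L, nk, nd)
      if (nk > 1) {
        for (j in 2:nk) {
          newbest <- rep(-Inf, nd)
          gap <- min_slope * (ps[j] - ps[j - 1])
          for (d in seq_len(nd)) {
            if (!is.finite(score[j, d])) next
            s_j <- slin[j] + dgrid[d]
            feas <- which(is.finite(best) &
                            slin[j - 1] + dgrid <= s_j - gap)
            if (!length(feas)) next
            k <- feas[which.max(best[feas])]
            newbest[d] <- best[k] + score[j, d]
            back[j, d] <- k
          }
          best <- newbest
        }
      }
      if (any(is.finite(best))) {
        path <- integer(nk)
        path[nk] <- which.max(best)
        if (nk > 1) for (j in nk:2) path[j - 1] <- back[j, path[j]]
        add <- tibble(ivus_mm = ps, ccta_mm = slin + dgrid[path],
                      anchor = FALSE)
        out <- bind_rows(out, add)
      }
    }
    out <- bind_rows(out, knots[seg + 1, ])
  }
  out
}

#' Per-lesion matched CCTA and IVUS volumes
#'
#' For each IVUS-detected lesion, computes the IVUS volumes over the lesion
#' interval and the CCTA volumes over the warp-mapped arclength interval.
#' Lesions whose mapped interval falls outside the CCTA series coverage are
#' excluded; the exclusions (with reasons) are recorded in the `excluded`
#' attribute.
#'
#' @param ccta a classified cross-section series (see [ccta_quantify()]).
#' @param ivus a `pullback_profile`.
#' @param lesions a `lesion_table` from [detect_lesions()].
#' @param warp a `warp_map` from [build_warp()].
#' @param ccta_step_mm resampling step for CCTA lesion integrals (mm).
#' @return tibble of class `matched_lesions`, one row per analyzed lesion,
#'   with `ivus_*` and `ccta_*` volume columns (mm^3).
#' @export
lesion_matched_volumes <- function(ccta, ivus, lesions, warp,
                                   ccta_step_mm = 0.5) {
  iv <- ivus_lesion_volumes(ivus, lesions)
  srng <- range(ccta$s_mm)
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(iv))) {
    mp <- map_interval(warp, iv$start_mm[i], iv$end_mm[i])
    if (mp[1] < srng[1] - 1e-6 || mp[2] > srng[2] + 1e-6) {
      excl[[length(excl) + 1]] <- tibble(
        lesion = iv$lesion[i],
        reason = sprintf("mapped interval [%.1f, %.1f] outside CCTA coverage",
                         mp[1], mp[2]))
      next
    }
    vol <- function(col) {
      profile_volume(ccta$s_mm, ccta[[col]], mp[1], mp[2],
                     step_mm = ccta_step_mm)
    }
    cp <- vol("cp_area_mm2"); ncpw <- vol("ncp_area_mm2")
    lap <- vol("lap_area_mm2")
    tpv <- cp + ncpw + lap
    rows[[length(rows) + 1]] <- tibble(
      lesion = iv$lesion[i],
      ivus_start_mm = iv$start_mm[i], ivus_end_mm = iv$end_mm[i],
      ccta_start_mm = unname(mp[1]), ccta_end_mm = unname(mp[2]),
      ivus_tpv_mm3 = iv$tpv_mm3[i], ivus_cp_mm3 = iv$cp_mm3[i],
      ivus_ncp_mm3 = iv$ncp_mm3[i], ivus_lap_mm3 = iv$atten_mm3[i],
      ivus_lumen_mm3 = iv$lumen_mm3[i], ivus_vessel_mm3 = iv$vessel_mm3[i],
      ccta_tpv_mm3 = tpv, ccta_cp_mm3 = cp, ccta_ncp_mm3 = tpv - cp,
      ccta_lap_mm3 = lap, ccta_lumen_mm3 = vol("lumen_area_mm2"),
      ccta_vessel_mm3 = vol("vessel_area_mm2"))
  }
  structure(bind_rows(rows),
            excluded = bind_rows(excl),
            class = c("matched_lesions", class(tibble())))
}
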