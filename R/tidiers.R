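#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an agreement report
#'
#' @param x an [agreement_report()].
#' @param type `"measures"` for the per-measure statistics table,
#'   `"lap"` for the LAP-presence ROC table.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.agreement_report <- function(x, type = c("measures", "lap"), ...) {
  type <- match.arg(type)
  if (type == "lap") {
    if (is.null(x$lap)) return(tibble())
    return(as_tibble(x$lap))
  }
  x$measures
}

#' One-row summary of an agreement report
#'
#' @param x an [agreement_report()].
#' @param ... unused.
#' @return one-row tibble keyed on the total-plaque-volume measure.
#' @export
glance.agreement_report <- function(x, ...) {
  m <- x$measures
  tpv <- m[m$measure == "tpv", ]
  one <- function(v) if (length(v)) v[1] else NA_real_
  tibble(n_lesions = x$n_lesions,
         r_tpv = one(tpv$r),
         icc_tpv = one(tpv$icc),
         bias_tpv = one(tpv$mean_diff),
         loa_width_tpv = one(tpv$loa_high - tpv$loa_low),
         auc_lap_8 = if (!is.null(x$lap)) {
           v <- x$lap$auc[x$lap$threshold_mm3 == 8 & x$lap$rule == "youden"]
           if (length(v)) v[1] else NA_real_
         } else NA_real_)
}

#' @export
tidy.plaque_volumes <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @export
tidy.warp_map <- function(x, ...) x$knots

#' @export
glance.study_result <- function(x, ...) {
  bind_cols(tibble(cases = x$manifest$cases),
            glance(x$report))
}

#' @export
tidy.study_result <- function(x, ...) tidy(x$report, ...)
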