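#' Pearson correlation with regression fit
#'
#' Pearson r with a two-sided p-value, plus the ordinary-least-squares
#' regression of the CCTA measurement on the IVUS measurement (IVUS on the
#' abscissa, the convention of scatter displays against the reference
#' standard).
#'
#' @param x reference (IVUS) values.
#' @param y comparison (CCTA) values.
#' @return one-row tibble: `r`, `p`, `slope`, `intercept`, `n`.
#' @export
#' @examples
#' pearson_with_fit(1:10, 2 * (1:10) + 1)  # r = 1, slope 2, intercept 1
pearson_with_fit <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- coef(lm(y ~ x))
  tibble(r = unname(ct$estimate), p = ct$p.value,
         slope = unname(fit[2]), intercept = unname(fit[1]),
         n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as comparison minus reference (`y - x`, i.e.
#' CCTA - IVUS, so underestimation by CCTA gives a negative bias).  Limits
#' of agreement are the mean difference plus/minus 1.96 times the sample
#' standard deviation (n - 1) of the differences.
#'
#' @inheritParams pearson_with_fit
#' @return one-row tibble: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))  # mean 0, SD 1, limits -/+1.96
bland_altman <- function(x, y) {
  ok <- complete.cases(x, y)
  d <- y[ok] - x[ok]
  if (length(d) < 2) abort("need at least 2 paired observations")
  m <- mean(d)
  s <- sd(d)
  tibble(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = length(d))
}

#' Intraclass correlation (two-way, absolute agreement, single measure)
#'
#' ICC(A,1) from the mean-squares decomposition of the n x 2 table of
#' paired measurements: with MSR the between-subject, MSC the
#' between-method and MSE the residual mean square,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2
#' raters.  Absolute agreement penalizes systematic offsets, unlike Pearson
#' correlation.
#'
#' @inheritParams pearson_with_fit
#' @return ICC as a single number.
#' @export
icc_agreement <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Paired t-test on method differences
#'
#' Standard paired t on `d = y - x` with n - 1 degrees of freedom.
#'
#' @inheritParams pearson_with_fit
#' @return one-row tibble: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  ok <- complete.cases(x, y)
  d <- y[ok] - x[ok]
  if (length(d) < 2) abort("need at least 2 paired observations")
  if (sd(d) == 0) abort("zero-variance differences: paired t degenerate")
  tt <- t.test(d)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = mean(d))
}

# ROC by sweeping a cutoff over scores, grouping tied scores into single
# steps.  Positive call: score >= cutoff.  Returns points ordered by FPR.
roc_points <- function(labels, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels); nn <- sum(!labels)
  tp <- vapply(cuts, function(c) sum(scores >= c & labels), 0)
  fp <- vapply(cuts, function(c) sum(scores >= c & !labels), 0)
  tibble(cutoff = c(Inf, cuts), tpr = c(0, tp / np), fpr = c(0, fp / nn))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

confusion_metrics <- function(labels, predicted) {
  tp <- sum(predicted & labels); fp <- sum(predicted & !labels)
  fn <- sum(!predicted & labels); tn <- sum(!predicted & !labels)
  pct <- function(a, b) if (a + b > 0) 100 * a / (a + b) else NA_real_
  tibble(sensitivity = pct(tp, fn), specificity = pct(tn, fp),
         ppv = pct(tp, fp), npv = pct(tn, fn),
         accuracy = 100 * (tp + tn) / length(labels),
         tp = tp, fp = fp, fn = fn, tn = tn)
}

#' LAP-presence ROC analysis against IVUS thresholds
#'
#' For each IVUS low-attenuation-plaque volume threshold, lesions are
#' labeled LAP-present when the IVUS LAP volume meets the threshold, and an
#' ROC curve is built by sweeping a cutoff over the CCTA LAP volumes (tied
#' scores grouped into single steps; AUC by the trapezoid rule, which
#' equals the Mann-Whitney probability with half credit for ties).  Two
#' operating points are reported per threshold: the Youden-optimal CCTA
#' cutoff, and the fixed rule "CCTA LAP > 0".
#'
#' @param ivus_lap per-lesion IVUS LAP (attenuated-plaque) volumes (mm^3).
#' @param ccta_lap per-lesion CCTA LAP volumes (mm^3).
#' @param thresholds IVUS presence thresholds (mm^3).
#' @return tibble of class `lap_roc`: one row per threshold and rule with
#'   `threshold_mm3`, `rule`, `cutoff`, `auc`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percent) and confusion counts.
#' @export
lap_presence_analysis <- function(ivus_lap, ccta_lap,
                                  thresholds = c(2, 4, 8)) {
  ok <- complete.cases(ivus_lap, ccta_lap)
  ivus_lap <- ivus_lap[ok]; ccta_lap <- ccta_lap[ok]
  out <- purrr::map(thresholds, function(th) {
    labels <- ivus_lap >= th
    if (all(labels) || !any(labels)) {
      abort(sprintf(
        "only one class present at IVUS LAP threshold %g mm^3", th))
    }
    roc <- roc_points(labels, ccta_lap)
    auc <- auc_trapezoid(roc)
    youden <- roc$cutoff[which.max(roc$tpr - roc$fpr)]
    bind_rows(
      bind_cols(tibble(threshold_mm3 = th, rule = "youden",
                       cutoff = youden, auc = auc),
                confusion_metrics(labels, ccta_lap >= youden)),
      bind_cols(tibble(threshold_mm3 = th, rule = "positive_volume",
                       cutoff = 0, auc = auc),
                confusion_metrics(labels, ccta_lap > 0)))
  }) |> bind_rows()
  structure(out, class = c("lap_roc", class(tibble())))
}

#' Full per-measure agreement report
#'
#' Runs [pearson_with_fit()], [bland_altman()], [icc_agreement()] and
#' [paired_t()] for each paired volume measure (TPV, CP, NCP, LAP, lumen,
#' vessel) of a matched-lesion table, plus the LAP-presence ROC analysis.
#' Measures whose statistics are undefined on the data at hand (e.g. a
#' degenerate paired t) are reported as `NA`.
#'
#' @param matched a `matched_lesions` tibble from
#'   [lesion_matched_volumes()] (or any tibble with `ivus_<m>_mm3` /
#'   `ccta_<m>_mm3` column pairs).
#' @param measures measure stems to analyze.
#' @param lap_thresholds IVUS LAP presence thresholds (mm^3);
#'   `NULL` skips the ROC analysis.
#' @return object of class `agreement_report`: list with `measures` (per-
#'   measure statistics tibble), `lap` (ROC table or `NULL`) and `n_lesions`.
#' @export
agreement_report <- function(matched,
                             measures = c("tpv", "cp", "ncp", "lap",
                                          "lumen", "vessel"),
                             lap_thresholds = c(2, 4, 8)) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  rows <- purrr::map(measures, function(m) {
    x <- matched[[paste0("ivus_", m, "_mm3")]]
    y <- matched[[paste0("ccta_", m, "_mm3")]]
    if (is.null(x) || is.null(y)) return(NULL)
    pf <- safe(pearson_with_fit(x, y))
    ba <- safe(bland_altman(x, y))
    pt <- safe(paired_t(x, y))
    tibble(measure = m,
           n = sum(complete.cases(x, y)),
           r = pf$r %||% NA_real_, r_p = pf$p %||% NA_real_,
           slope = pf$slope %||% NA_real_,
           intercept = pf$intercept %||% NA_real_,
           icc = safe(icc_agreement(x, y)) %||% NA_real_,
           mean_diff = ba$mean_diff %||% NA_real_,
           sd_diff = ba$sd_diff %||% NA_real_,
           loa_low = ba$loa_low %||% NA_real_,
           loa_high = ba$loa_high %||% NA_real_,
           t = pt$t %||% NA_real_, t_p = pt$p %||% NA_real_)
  }) |> bind_rows()
  lap <- NULL
  if (!is.null(lap_thresholds) &&
      all(c("ivus_lap_mm3", "ccta_lap_mm3") %in% names(matched))) {
    lap <- tryCatch(
      lap_presence_analysis(matched$ivus_lap_mm3, matched$ccta_lap_mm3,
                            lap_thresholds),
      error = function(e) {
        warn(paste("LAP ROC analysis skipped:", conditionMessage(e)))
        NULL
      })
  }
  structure(list(measures = rows, lap = lap, n_lesions = nrow(matched),
                 data = as_tibble(matched)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("<agreement_report> %d lesions\n", x$n_lesions))
  print(x$measures, digits = digits)
  if (!is.null(x$lap)) {
    cat("LAP presence (IVUS thresholds):\n")
    print(x$lap, digits = digits)
  }
  invisible(x)
}
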