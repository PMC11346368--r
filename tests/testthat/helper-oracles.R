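# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Dense trapezoid quadrature of an area profile, refined 10x by linear
# interpolation.
trapezoid_oracle <- function(areas, spacing, refine = 10L) {
  n <- length(areas)
  s <- (seq_len(n) - 1) * spacing
  grid <- seq(0, s[n], length.out = (n - 1) * refine + 1)
  a <- approx(s, areas, grid)$y
  h <- grid[2] - grid[1]
  sum((a[-1] + a[-length(a)]) / 2) * h
}

# Exhaustive lesion search: every maximal contiguous window with all
# stations at/above the burden threshold and span >= min_length.
brute_force_lesions <- function(burden, spacing = 1, thr = 40,
                                min_len = 2) {
  n <- length(burden)
  qual <- !is.na(burden) & burden >= thr
  out <- list()
  i <- 1
  while (i <= n) {
    if (qual[i]) {
      j <- i
      while (j < n && qual[j + 1]) j <- j + 1
      if ((j - i) * spacing >= min_len - 1e-9) {
        out[[length(out) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  do.call(rbind, out)
}

# Mann-Whitney AUC by brute force over all positive/negative pairs, with
# half credit for ties.
mann_whitney_auc <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ICC(A,1) via aov mean squares (independent of the package's closed-form
# row/column decomposition).
icc_aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- anova(lm(value ~ subject + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# A small straight-tube phantom spec used by several tests.
tube_spec <- function(lumen = 1.5, outer = 2.5, length_mm = 20,
                      voxel = 0.4, psf = 0, noise = 0, seed = 1, ...) {
  phantom_spec(length_mm = length_mm, lumen_radius_mm = lumen,
               outer_radius_mm = outer, voxel_mm = voxel,
               psf_sigma_mm = psf, noise_sd_hu = noise, seed = seed, ...)
}
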