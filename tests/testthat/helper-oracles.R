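# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: distances are checked pixel by pixel and
# ANOVA mean squares come from stats::aov.

# exhaustive per-pixel location check (double loop, no vectorised reuse)
oracle_classify <- function(atrophy_mask, fovea_px, geometry,
                            radius_um = 1500) {
  rp <- geometry$height_mm / geometry$n_bscans
  cp <- geometry$width_mm / geometry$n_ascans
  central <- FALSE
  for (r in seq_len(nrow(atrophy_mask))) {
    for (c in seq_len(ncol(atrophy_mask))) {
      if (!atrophy_mask[r, c]) next
      d <- sqrt(((r - 1 - fovea_px[1]) * rp)^2 +
                ((c - 1 - fovea_px[2]) * cp)^2)
      if (d <= radius_um / 1000) central <- TRUE
    }
  }
  list(central_ga = central,
       fovea_involving = isTRUE(atrophy_mask[fovea_px[1] + 1, fovea_px[2] + 1]))
}

# ICC(A,1) via stats::aov mean squares (independent of the package's
# closed-form computation)
oracle_icc <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

small_geometry <- function(nr = 32, nc = 32, w = 6, h = 6) {
  scan_geometry(nr, nc, w, h)
}
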