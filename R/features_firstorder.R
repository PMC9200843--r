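## First-order intensity, discretized-histogram, and intensity-volume
## histogram features. Moment conventions are population (divide by N);
## skewness/kurtosis of a zero-variance region are defined as 0.

pop_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  list(mean = mu, var = m2, skew = skew, kurt = kurt)
}

#' First-order intensity statistics of the segmented region
#'
#' @param image \code{image_volume} (or 3D array).
#' @param mask Binary 3D array aligned to the image.
#' @return Named numeric vector of the 16 intensity features.
#' @export
intensity_features <- function(image, mask) {
  if (!inherits(image, "image_volume")) image <- image_volume(image)
  m <- check_pair(image, mask)
  x <- image$data[m]
  mo <- pop_moments(x)
  q <- unname(stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  cv <- if (abs(mo$mean) > 1e-12) sqrt(mo$var) / abs(mo$mean) else 0
  c(intensity_mean = mo$mean,
    intensity_variance = mo$var,
    intensity_skewness = mo$skew,
    intensity_kurtosis = mo$kurt,
    intensity_median = q[3],
    intensity_min = min(x),
    intensity_max = max(x),
    intensity_range = max(x) - min(x),
    intensity_mad = mean(abs(x - mo$mean)),
    intensity_robust_mad = stats::mad(x),
    intensity_energy = sum(x^2),
    intensity_rms = sqrt(mean(x^2)),
    intensity_iqr = q[4] - q[2],
    intensity_p10 = q[1],
    intensity_p90 = q[5],
    intensity_cov = cv)
}

#' Discretized-histogram statistics
#'
#' Statistics of the gray-level histogram of the quantized region:
#' level moments, Shannon entropy (bits), uniformity (energy), mode and
#' percentile levels.
#'
#' @param quantized A \code{quantized_roi}.
#' @return Named numeric vector of the 15 histogram features.
#' @export
histogram_features <- function(quantized) {
  lev <- quantized$levels[!is.na(quantized$levels)]
  counts <- tabulate(lev, nbins = quantized$n_levels)
  p <- counts / sum(counts)
  nz <- p[p > 0]
  mo <- pop_moments(lev)
  q <- unname(stats::quantile(lev, c(0.1, 0.5, 0.9), type = 1))
  c(hist_mean = mo$mean,
    hist_variance = mo$var,
    hist_skewness = mo$skew,
    hist_kurtosis = mo$kurt,
    hist_entropy = -sum(nz * log2(nz)),
    hist_uniformity = sum(p^2),
    hist_median = q[2],
    hist_mode = which.max(counts),
    hist_p10 = q[1],
    hist_p90 = q[3],
    hist_min_level = min(lev),
    hist_max_level = max(lev),
    hist_range = max(lev) - min(lev),
    hist_max_prob = max(p),
    hist_n_levels = sum(counts > 0))
}

#' Intensity-volume histogram features
#'
#' The IVH relates intensity thresholds to the fraction of the region's
#' volume at or above them. \code{V(f)} is the volume fraction with
#' fractional intensity >= f; \code{I(v)} is the intensity reached by the
#' hottest fraction v of the volume. A constant region has V(f) = 1 for
#' every f.
#'
#' @param image \code{image_volume} (or 3D array).
#' @param mask Binary 3D array aligned to the image.
#' @return Named numeric vector of the 12 IVH features.
#' @export
ivh_features <- function(image, mask) {
  if (!inherits(image, "image_volume")) image <- image_volume(image)
  m <- check_pair(image, mask)
  x <- image$data[m]
  n <- length(x)
  rng <- max(x) - min(x)
  nu <- if (rng > 0) (x - min(x)) / rng else rep(1, n)
  vfrac <- function(f) mean(nu >= f)
  ifrac <- function(v) {
    xs <- sort(x, decreasing = TRUE)
    xs[max(1L, ceiling(v * n))]
  }
  fs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  v <- vapply(fs, vfrac, numeric(1))
  i <- vapply(fs, ifrac, numeric(1))
  out <- c(v, i, v[1] - v[5], i[1] - i[5])
  names(out) <- c("ivh_v10", "ivh_v25", "ivh_v50", "ivh_v75", "ivh_v90",
                  "ivh_i10", "ivh_i25", "ivh_i50", "ivh_i75", "ivh_i90",
                  "ivh_v10_minus_v90", "ivh_i10_minus_i90")
  out
}
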