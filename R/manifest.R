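#' Radiomic feature manifest
#'
#' The fixed, versioned list of the 102 radiomic features the extractor
#' computes, together with the family each belongs to. Eight families are
#' covered: first-order intensity statistics, discretized-histogram
#' statistics, intensity-volume-histogram ("volumetric") features,
#' morphologic (shape) features, gray-level run-length matrix (GLRLM),
#' gray-level size-zone matrix (GLSZM), neighborhood gray-tone difference
#' matrix (NGTDM), and slice-wise rotation-invariant uniform local binary
#' pattern (LBP) histogram bins. Definitions follow the conventions of the
#' Imaging Biomarker Standardisation Initiative where applicable.
#'
#' @return A data.frame with columns \code{name} and \code{family}
#'   (102 rows; families: \code{intensity}, \code{histogram},
#'   \code{volumetric}, \code{morphologic}, \code{GLRLM}, \code{GLSZM},
#'   \code{NGTDM}, \code{LBP}).
#' @export
#' @examples
#' m <- radiomic_manifest()
#' nrow(m)          # 102
#' table(m$family)
radiomic_manifest <- function() {
  intensity <- c(
    "intensity_mean", "intensity_variance", "intensity_skewness",
    "intensity_kurtosis", "intensity_median", "intensity_min",
    "intensity_max", "intensity_range", "intensity_mad",
    "intensity_robust_mad", "intensity_energy", "intensity_rms",
    "intensity_iqr", "intensity_p10", "intensity_p90", "intensity_cov")
  histogram <- c(
    "hist_mean", "hist_variance", "hist_skewness", "hist_kurtosis",
    "hist_entropy", "hist_uniformity", "hist_median", "hist_mode",
    "hist_p10", "hist_p90", "hist_min_level", "hist_max_level",
    "hist_range", "hist_max_prob", "hist_n_levels")
  volumetric <- c(
    "ivh_v10", "ivh_v25", "ivh_v50", "ivh_v75", "ivh_v90",
    "ivh_i10", "ivh_i25", "ivh_i50", "ivh_i75", "ivh_i90",
    "ivh_v10_minus_v90", "ivh_i10_minus_i90")
  morphologic <- c(
    "morph_voxel_count", "morph_volume_cm3", "morph_equiv_diameter_mm",
    "morph_surface_area_mm2", "morph_surface_volume_ratio",
    "morph_sphericity", "morph_compactness1", "morph_compactness2",
    "morph_spherical_disproportion", "morph_max_diameter_mm",
    "morph_elongation", "morph_flatness")
  glrlm <- paste0("glrlm_", c(
    "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
    "gln", "glnn", "rln", "rlnn", "rp", "glv", "rlv", "re"))
  glszm <- paste0("glszm_", c(
    "sae", "lae", "lgze", "hgze", "salge", "sahge", "lalge", "lahge",
    "gln", "glnn", "zsn", "zsnn", "zp", "glv", "zsv", "ze"))
  ngtdm <- paste0("ngtdm_", c(
    "coarseness", "contrast", "busyness", "complexity", "strength"))
  lbp <- paste0("lbp_bin", 0:9)
  data.frame(
    name = c(intensity, histogram, volumetric, morphologic,
             glrlm, glszm, ngtdm, lbp),
    family = rep(c("intensity", "histogram", "volumetric", "morphologic",
                   "GLRLM", "GLSZM", "NGTDM", "LBP"),
                 times = c(length(intensity), length(histogram),
                           length(volumetric), length(morphologic),
                           length(glrlm), length(glszm),
                           length(ngtdm), length(lbp))),
    stringsAsFactors = FALSE)
}

#' Extraction configuration
#'
#' @param n_levels Number of equal-width gray levels used to discretize the
#'   in-mask intensity range before texture-matrix computation. Default 32.
#' @return A list of class \code{extract_config}.
#' @export
extract_config <- function(n_levels = 32L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1L)
    stop("n_levels must be a positive integer")
  structure(list(n_levels = n_levels, manifest = radiomic_manifest()),
            class = "extract_config")
}
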