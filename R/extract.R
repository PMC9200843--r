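#' Extract the full 102-feature radiomic descriptor
#'
#' Runs all eight feature families on a segmented volume and returns the
#' values in manifest order. The input pair is assumed to be already
#' resampled to the cohort target spacing (see
#' \code{\link{compute_min_spacing}} and \code{\link{resample_pair}}).
#'
#' @param image An \code{image_volume}.
#' @param mask Binary 3D array aligned to the image.
#' @param config An \code{\link{extract_config}}.
#' @return Named numeric vector of length 102 with a \code{family}
#'   attribute; all values finite.
#' @export
extract_all <- function(image, mask, config = extract_config()) {
  if (!inherits(image, "image_volume")) image <- image_volume(image)
  m <- check_pair(image, mask)
  q <- quantize_roi(image, m, config$n_levels)
  run <- function(family, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("feature family %s failed: %s", family,
                   conditionMessage(e)), call. = FALSE))
  }
  vals <- c(
    run("intensity",  function() intensity_features(image, m)),
    run("histogram",  function() histogram_features(q)),
    run("volumetric", function() ivh_features(image, m)),
    run("morphologic", function() morphology_features(m, image$spacing)),
    run("GLRLM", function() glrlm_features(q)),
    run("GLSZM", function() glszm_features(q)),
    run("NGTDM", function() ngtdm_features(q)),
    run("LBP",   function() lbp_features(image, m)))
  manifest <- config$manifest
  if (!identical(names(vals), manifest$name))
    vals <- vals[manifest$name]
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("non-finite feature values: ",
         paste(manifest$name[!is.finite(vals)], collapse = ", "))
  attr(vals, "family") <- manifest$family
  vals
}

#' Extract features for a set of image/mask files
#'
#' @param image_paths,mask_paths Equal-length character vectors of NIfTI
#'   paths.
#' @param config An \code{\link{extract_config}}.
#' @param target_spacing Optional length-3 spacing override (mm); by
#'   default the component-wise minimum spacing across the cohort is used.
#' @return data.frame: \code{sample_id} then the 102 feature columns.
#' @export
extract_features <- function(image_paths, mask_paths,
                             config = extract_config(),
                             target_spacing = NULL) {
  stopifnot(length(image_paths) == length(mask_paths),
            length(image_paths) >= 1L)
  pairs <- Map(read_image_mask_pair, image_paths, mask_paths)
  if (is.null(target_spacing))
    target_spacing <- compute_min_spacing(
      lapply(pairs, function(p) p$image$spacing))
  rows <- lapply(pairs, function(p) {
    rs <- resample_pair(p$image, p$mask, target_spacing)
    extract_all(rs$image, rs$mask, config)
  })
  out <- as.data.frame(do.call(rbind, rows))
  ids <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), out,
        row.names = NULL)
}
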