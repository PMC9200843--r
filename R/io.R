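## File formats: NIfTI image/mask pairs, the CSV trio
## (features / clinical / batches), and JSON reports. CSV dialect: UTF-8,
## comma-separated, header row, sample id first column.

#' Read an aligned NIfTI image/mask pair
#'
#' @param image_path,mask_path Paths to NIfTI (.nii/.nii.gz) files.
#' @param tol Spacing agreement tolerance in mm (default 1e-3).
#' @return List: \code{image} (\code{image_volume}) and \code{mask}
#'   (binary array; any label > 0 is foreground).
#' @export
read_image_mask_pair <- function(image_path, mask_path, tol = 1e-3) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (!identical(di, dm))
    stop(sprintf("image grid %s does not match mask grid %s",
                 paste(di, collapse = "x"), paste(dm, collapse = "x")))
  si <- RNifti::pixdim(img)[1:3]
  sm <- RNifti::pixdim(msk)[1:3]
  if (any(abs(si - sm) > tol))
    stop(sprintf("image spacing (%s) and mask spacing (%s) differ beyond %g mm",
                 paste(signif(si, 6), collapse = ", "),
                 paste(signif(sm, 6), collapse = ", "), tol))
  list(image = image_volume(array(as.numeric(img), di), si),
       mask = array(as.numeric(msk) > 0, dm))
}

#' Write an image/mask pair as NIfTI
#'
#' @param image An \code{image_volume}.
#' @param mask Binary 3D array.
#' @param image_path,mask_path Output paths (.nii or .nii.gz).
#' @export
write_image_mask_pair <- function(image, mask, image_path, mask_path) {
  m <- check_pair(image, mask)
  im <- RNifti::asNifti(image$data)
  RNifti::pixdim(im) <- image$spacing
  mk <- RNifti::asNifti(array(as.integer(m), dim(m)))
  RNifti::pixdim(mk) <- image$spacing
  RNifti::writeNifti(im, image_path)
  RNifti::writeNifti(mk, mask_path)
  invisible(c(image_path, mask_path))
}

#' Write a synthetic cohort as the CSV trio
#'
#' Emits \code{features.csv}, \code{clinical.csv} and \code{batches.csv}
#' (the pipeline's input dialect) into \code{dir}. The planted cluster
#' label is written to \code{clinical.csv} as \code{cluster_truth} (it is
#' synthetic ground truth, not an observable).
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(cohort$features)
  utils::write.csv(
    cbind(data.frame(sample_id = ids), as.data.frame(cohort$features)),
    file.path(dir, "features.csv"), row.names = FALSE)
  clin <- cbind(data.frame(sample_id = ids), cohort$clinical,
                cluster_truth = cohort$cluster_truth)
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(
    cbind(data.frame(sample_id = ids), cohort$batches),
    file.path(dir, "batches.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read the cohort CSV trio
#'
#' @param dir Directory containing \code{features.csv},
#'   \code{clinical.csv}, \code{batches.csv}.
#' @return List: \code{features} (matrix), \code{clinical} (data.frame),
#'   \code{batches} (data.frame of factors), \code{sample_id}.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing ", f, " in ", dir)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  feat <- rd("features.csv")
  clin <- rd("clinical.csv")
  bat <- rd("batches.csv")
  ids <- feat$sample_id
  if (!identical(ids, clin$sample_id) || !identical(ids, bat$sample_id))
    stop("sample_id columns disagree across the CSV trio")
  X <- as.matrix(feat[, -1, drop = FALSE])
  rownames(X) <- ids
  bat <- bat[, -1, drop = FALSE]
  bat[] <- lapply(bat, factor)
  list(features = X, clinical = clin[, -1, drop = FALSE], batches = bat,
       sample_id = ids)
}
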