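#' Image volume container
#'
#' Light-weight container for a 3D scalar grid (e.g. CT attenuation in HU)
#' with physical voxel spacing. Voxel centers are at
#' \code{origin + (index - 1) * spacing} on each axis.
#'
#' @param data Numeric 3D array of intensities (finite).
#' @param spacing Numeric length-3 vector of voxel spacing in mm, all > 0.
#' @param origin Numeric length-3 vector, mm. Default c(0, 0, 0).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!all(is.finite(data))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

as_mask <- function(mask) {
  m <- if (inherits(mask, "image_volume")) mask$data else as.array(mask)
  if (length(dim(m)) != 3L) stop("mask must be a 3D array")
  m <- array(as.numeric(m) > 0, dim(m))
  if (!any(m)) stop("mask has no foreground voxel")
  m
}

check_pair <- function(image, mask) {
  m <- as_mask(mask)
  if (!identical(dim(image$data), dim(m)))
    stop(sprintf("image grid (%s) and mask grid (%s) differ",
                 paste(dim(image$data), collapse = "x"),
                 paste(dim(m), collapse = "x")))
  m
}

#' Component-wise minimum voxel spacing across a cohort
#'
#' Scans are resampled to a common grid whose spacing is the minimum of each
#' spacing component over all scans in the cohort, so that no scan is
#' downsampled on any axis.
#'
#' @param spacings A list of length-3 numeric vectors, or a matrix with one
#'   row per scan and 3 columns, in mm.
#' @return Length-3 numeric vector: the component-wise minimum (mm).
#' @export
#' @examples
#' compute_min_spacing(list(c(0.7, 0.7, 1.25), c(0.54, 0.54, 0.8),
#'                          c(0.9, 0.9, 5.0)))
compute_min_spacing <- function(spacings) {
  if (is.list(spacings)) {
    if (length(spacings) == 0L) stop("empty collection of spacings")
    spacings <- do.call(rbind, lapply(spacings, as.numeric))
  }
  spacings <- as.matrix(spacings)
  if (nrow(spacings) == 0L) stop("empty collection of spacings")
  if (ncol(spacings) != 3L) stop("each spacing must have 3 components")
  if (any(!is.finite(spacings)) || any(spacings <= 0))
    stop("all spacing components must be positive and finite")
  apply(spacings, 2L, min)
}

## 1D sample positions for a resampled axis: cover the physical extent of
## the input voxel-center range at the target step.
resample_axis <- function(n_in, sp_in, sp_out) {
  extent <- (n_in - 1L) * sp_in
  n_out <- as.integer(floor(extent / sp_out + 1e-9)) + 1L
  list(n = n_out, pos = seq(0, by = sp_out, length.out = n_out))
}

trilinear_sample <- function(vol, xi, yi, zi) {
  ## xi, yi, zi: fractional voxel indices (1-based) of output sample points
  d <- dim(vol)
  clampf <- function(v, n) pmin(pmax(v, 1), n)
  xi <- clampf(xi, d[1]); yi <- clampf(yi, d[2]); zi <- clampf(zi, d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); x0[d[1] == 1L] <- 1L
  y0 <- pmin(floor(yi), d[2] - 1L); y0[d[2] == 1L] <- 1L
  z0 <- pmin(floor(zi), d[3] - 1L); z0[d[3] == 1L] <- 1L
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  ## expand to full output grid
  X0 <- array(rep(x0, times = ny * nz), c(nx, ny, nz))
  FX <- array(rep(fx, times = ny * nz), c(nx, ny, nz))
  Y0 <- aperm(array(rep(y0, times = nx * nz), c(ny, nx, nz)), c(2, 1, 3))
  FY <- aperm(array(rep(fy, times = nx * nz), c(ny, nx, nz)), c(2, 1, 3))
  Z0 <- array(rep(z0, each = nx * ny), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  x1 <- pmin(X0 + 1L, d[1]); y1 <- pmin(Y0 + 1L, d[2]); z1 <- pmin(Z0 + 1L, d[3])
  idx <- function(i, j, k) vol[cbind(as.vector(i), as.vector(j), as.vector(k))]
  v000 <- idx(X0, Y0, Z0); v100 <- idx(x1, Y0, Z0)
  v010 <- idx(X0, y1, Z0); v110 <- idx(x1, y1, Z0)
  v001 <- idx(X0, Y0, z1); v101 <- idx(x1, Y0, z1)
  v011 <- idx(X0, y1, z1); v111 <- idx(x1, y1, z1)
  fx <- as.vector(FX); fy <- as.vector(FY); fz <- as.vector(FZ)
  out <- (1 - fx) * (1 - fy) * (1 - fz) * v000 + fx * (1 - fy) * (1 - fz) * v100 +
    (1 - fx) * fy * (1 - fz) * v010 + fx * fy * (1 - fz) * v110 +
    (1 - fx) * (1 - fy) * fz * v001 + fx * (1 - fy) * fz * v101 +
    (1 - fx) * fy * fz * v011 + fx * fy * fz * v111
  array(out, c(nx, ny, nz))
}

#' Resample an image/mask pair to a target voxel spacing
#'
#' Anisotropic resampling onto a grid covering the physical extent of the
#' input at the target spacing. Image intensities are interpolated
#' trilinearly; the segmentation mask by nearest neighbor, so the output
#' mask stays binary.
#'
#' @param image An \code{image_volume}.
#' @param mask A binary 3D array (or \code{image_volume}) aligned to
#'   \code{image}.
#' @param target Length-3 numeric target spacing in mm.
#' @return A list with elements \code{image} (resampled
#'   \code{image_volume}) and \code{mask} (binary array).
#' @export
resample_pair <- function(image, mask, target) {
  m <- check_pair(image, mask)
  target <- as.numeric(target)
  if (length(target) != 3L || any(!is.finite(target)) || any(target <= 0))
    stop("target spacing must be three positive values")
  d <- dim(image$data)
  ax <- lapply(1:3, function(a) resample_axis(d[a], image$spacing[a], target[a]))
  n_out <- vapply(ax, `[[`, integer(1), "n")
  if (any(n_out < 2L & d > 1L))
    stop(sprintf("target spacing %s mm too coarse for extent: output grid %s",
                 paste(signif(target, 4), collapse = "x"),
                 paste(n_out, collapse = "x")))
  frac <- lapply(1:3, function(a) ax[[a]]$pos / image$spacing[a] + 1)
  img_out <- trilinear_sample(image$data, frac[[1]], frac[[2]], frac[[3]])
  ## nearest-neighbor indices for the mask
  nn <- lapply(1:3, function(a) pmin(pmax(round(frac[[a]]), 1L), d[a]))
  mask_out <- m[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
  mask_out <- array(mask_out, n_out)
  list(image = image_volume(img_out, target, image$origin),
       mask = mask_out)
}

#' Discretize in-mask intensities to integer gray levels
#'
#' Equal-width bins spanning the in-mask intensity range; the maximum
#' intensity is assigned level \code{n_levels}. A constant region maps to
#' level 1 for any number of levels.
#'
#' @param image An \code{image_volume} (or bare 3D array).
#' @param mask Binary 3D array aligned to the image.
#' @param n_levels Number of gray levels (>= 1).
#' @return A list of class \code{quantized_roi}: \code{levels} (integer 3D
#'   array, NA outside the mask), \code{edges} (bin edges), \code{n_levels},
#'   and \code{spacing}.
#' @export
quantize_roi <- function(image, mask, n_levels = 32L) {
  if (!inherits(image, "image_volume")) image <- image_volume(image)
  m <- check_pair(image, mask)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  vals <- image$data[m]
  lo <- min(vals); hi <- max(vals)
  lev <- array(NA_integer_, dim(m))
  if (hi == lo || n_levels == 1L) {
    lev[m] <- 1L
    edges <- c(lo, hi)
  } else {
    edges <- seq(lo, hi, length.out = n_levels + 1L)
    l <- floor((vals - lo) / (hi - lo) * n_levels) + 1L
    l[l > n_levels] <- n_levels
    lev[m] <- as.integer(l)
  }
  structure(list(levels = lev, edges = edges, n_levels = n_levels,
                 spacing = image$spacing),
            class = "quantized_roi")
}
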