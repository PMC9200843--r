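## Slice-wise rotation-invariant uniform local binary patterns.
## The operator is the classic 2D 3x3 block: the center pixel thresholds
## its 8 neighbors (neighbor >= center -> 1). Codes are mapped to the
## 10-bin riu2 scheme (uniform patterns keep their bit count 0..8, all
## non-uniform patterns share bin 9). Histograms are normalized per axial
## slice and averaged over slices contributing at least one code.

## neighbors in circular order (radius 1)
.lbp_off <- rbind(c(-1, -1), c(0, -1), c(1, -1), c(1, 0),
                  c(1, 1), c(0, 1), c(-1, 1), c(-1, 0))

lbp_code_riu2 <- function(bits) {
  transitions <- sum(bits != bits[c(2:8, 1)])
  if (transitions <= 2) sum(bits) else 9L
}

lbp_slice_hist <- function(img2d, mask2d) {
  d <- dim(img2d)
  if (d[1] < 3L || d[2] < 3L) return(NULL)
  hist <- numeric(10)
  n <- 0L
  for (x in 2:(d[1] - 1L)) for (y in 2:(d[2] - 1L)) {
    if (!mask2d[x, y]) next
    nb <- .lbp_off + rep(c(x, y), each = 8L)
    if (!all(mask2d[nb])) next              # require a fully in-mask 3x3 patch
    bits <- as.integer(img2d[nb] >= img2d[x, y])
    code <- lbp_code_riu2(bits)
    hist[code + 1L] <- hist[code + 1L] + 1
    n <- n + 1L
  }
  if (n == 0L) return(NULL)
  hist / n
}

#' Local binary pattern histogram features
#'
#' Rotation-invariant uniform LBP (8 neighbors, radius 1) computed per
#' axial slice for every in-mask center whose 3x3 patch lies inside the
#' mask; per-slice histograms are normalized and averaged over
#' contributing slices. The 10 histogram bins are the features.
#'
#' @param image \code{image_volume} (or 3D array).
#' @param mask Binary 3D array aligned to the image.
#' @return Named numeric vector \code{lbp_bin0}..\code{lbp_bin9}
#'   (sums to 1).
#' @export
lbp_features <- function(image, mask) {
  if (!inherits(image, "image_volume")) image <- image_volume(image)
  m <- check_pair(image, mask)
  d <- dim(m)
  hists <- list()
  for (z in seq_len(d[3])) {
    h <- lbp_slice_hist(image$data[, , z], m[, , z])
    if (!is.null(h)) hists[[length(hists) + 1L]] <- h
  }
  if (length(hists) == 0L)
    stop("LBP undefined: no axial slice contains a fully in-mask 3x3 patch")
  out <- Reduce(`+`, hists) / length(hists)
  names(out) <- paste0("lbp_bin", 0:9)
  out
}
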