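## Morphologic (shape) features. The surface is triangulated with a
## marching-tetrahedra pass at iso-level 0.5 over a lightly smoothed
## occupancy field (each cube of 8 voxel centers split into 6 tetrahedra
## sharing the main diagonal, vertices linearly interpolated along edges).
## The smoothing anti-aliases the staircase of the binary mask, whose
## faceted iso-surface would overestimate area by ~30% and depress
## sphericity; masks too small to survive smoothing fall back to the
## binary field.

## 8 cube-corner offsets; 6 tetrahedra sharing diagonal corner1-corner7
.mt_corners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                     c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
.mt_tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                  c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))

tri_area <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  w <- c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3], u[1]*v[2] - u[2]*v[1])
  0.5 * sqrt(sum(w^2))
}

## Returns list(area, volume): surface area and the mesh-enclosed volume
## (divergence theorem over outward-oriented triangles). Using the pair
## keeps the isoperimetric ratios (sphericity, compactness) <= 1.
mesh_surface <- function(mask, spacing, iso = 0.5, smooth_sigma = 0.9) {
  m <- mask
  d <- dim(m)
  pm <- array(0, d + 4L)
  pm[3:(d[1]+2), 3:(d[2]+2), 3:(d[3]+2)] <- as.numeric(m)
  field <- smooth_gauss3(pm, smooth_sigma)
  if (max(field) <= iso) field <- pm   # mask too small for anti-aliasing
  pd <- dim(field)
  nc <- pd - 1L
  vals <- vector("list", 8L)
  nin <- array(0L, nc)
  for (c8 in 1:8) {
    o <- .mt_corners[c8, ]
    v <- field[(1:nc[1]) + o[1], (1:nc[2]) + o[2], (1:nc[3]) + o[3],
               drop = FALSE]
    vals[[c8]] <- v
    nin <- nin + (v >= iso)
  }
  mixed <- which(nin > 0L & nin < 8L, arr.ind = TRUE)
  if (nrow(mixed) == 0L) return(list(area = 0, volume = 0))
  area <- 0
  vol6 <- 0   # 6 x signed enclosed volume
  add_tri <- function(p1, p2, p3, ref) {
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2]*v[3] - u[3]*v[2], u[3]*v[1] - u[1]*v[3],
             u[1]*v[2] - u[2]*v[1])
    if (sum(nrm * ((p1 + p2 + p3) / 3 - ref)) < 0) { tmp <- p2; p2 <- p3; p3 <- tmp }
    area <<- area + tri_area(p1, p2, p3)
    vol6 <<- vol6 + sum(p1 * c(p2[2]*p3[3] - p2[3]*p3[2],
                               p2[3]*p3[1] - p2[1]*p3[3],
                               p2[1]*p3[2] - p2[2]*p3[1]))
  }
  for (r in seq_len(nrow(mixed))) {
    cell <- mixed[r, ]
    val8 <- vapply(1:8, function(c8) vals[[c8]][cell[1], cell[2], cell[3]],
                   numeric(1))
    inside <- val8 >= iso
    base <- (cell - 1) * spacing          # physical coord of corner 1
    coords <- sweep(.mt_corners, 2L, spacing, `*`)
    coords <- sweep(coords, 2L, base, `+`)
    ## vertex on edge a-b at the linear iso crossing
    mid <- function(a, b) {
      den <- val8[b] - val8[a]
      t <- if (abs(den) < 1e-12) 0.5 else (iso - val8[a]) / den
      t <- min(max(t, 0), 1)
      coords[a, ] + t * (coords[b, ] - coords[a, ])
    }
    for (t in 1:6) {
      v4 <- .mt_tets[t, ]
      f <- inside[v4]
      k <- sum(f)
      if (k == 0L || k == 4L) next
      ref <- colMeans(coords[v4[f], , drop = FALSE])  # inside-side point
      if (k == 1L || k == 3L) {
        a <- if (k == 1L) v4[f] else v4[!f]
        rest <- setdiff(v4, a)
        add_tri(mid(a, rest[1]), mid(a, rest[2]), mid(a, rest[3]), ref)
      } else {
        ins <- v4[f]; out <- v4[!f]
        q1 <- mid(ins[1], out[1]); q2 <- mid(ins[1], out[2])
        q3 <- mid(ins[2], out[2]); q4 <- mid(ins[2], out[1])
        add_tri(q1, q2, q3, ref)
        add_tri(q1, q3, q4, ref)
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6)
}

max_diameter <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(coords)
  sqrt(max(0, max(d2)))
}

#' Morphologic (shape) features of a segmentation
#'
#' Volume from the voxel count, surface area from a triangulated
#' iso-surface, and derived compactness/sphericity descriptors; maximum 3D
#' diameter over boundary voxel centers; elongation and flatness from the
#' principal axes of the voxel-center cloud. A single-voxel mask has
#' diameter 0 and elongation/flatness 1 by convention.
#'
#' @param mask Binary 3D array.
#' @param spacing Length-3 voxel spacing, mm.
#' @return Named numeric vector of the 12 morphologic features.
#' @export
morphology_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- as_mask(mask)
  spacing <- as.numeric(spacing)
  vox_vol <- prod(spacing)                       # mm^3
  n_vox <- sum(m)
  vol_mm3 <- n_vox * vox_vol
  ms <- mesh_surface(m, spacing)
  area_mm2 <- ms$area
  mesh_mm3 <- ms$volume          # used in the isoperimetric ratios
  ## boundary voxels: any 6-neighbor outside the mask (or grid edge)
  d <- dim(m)
  pm <- array(FALSE, d + 2L)
  pm[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1)] <- m
  core <- pm[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1), drop = FALSE]
  nb <- pm[1:d[1], 2:(d[2]+1), 2:(d[3]+1), drop = FALSE] &
        pm[3:(d[1]+2), 2:(d[2]+1), 2:(d[3]+1), drop = FALSE] &
        pm[2:(d[1]+1), 1:d[2], 2:(d[3]+1), drop = FALSE] &
        pm[2:(d[1]+1), 3:(d[2]+2), 2:(d[3]+1), drop = FALSE] &
        pm[2:(d[1]+1), 2:(d[2]+1), 1:d[3], drop = FALSE] &
        pm[2:(d[1]+1), 2:(d[2]+1), 3:(d[3]+2), drop = FALSE]
  boundary <- core & !nb
  bidx <- which(boundary, arr.ind = TRUE)
  bco <- sweep(bidx - 1, 2L, spacing, `*`)
  diam <- max_diameter(bco)
  ## principal axes of all in-mask voxel centers
  idx <- which(m, arr.ind = TRUE)
  co <- sweep(idx - 1, 2L, spacing, `*`)
  if (nrow(co) > 1L) {
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat  <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  r_eq <- (3 * vol_mm3 / (4 * pi))^(1/3)
  sph  <- if (area_mm2 > 0) pi^(1/3) * (6 * mesh_mm3)^(2/3) / area_mm2 else 1
  c(morph_voxel_count = n_vox,
    morph_volume_cm3 = vol_mm3 / 1000,
    morph_equiv_diameter_mm = 2 * r_eq,
    morph_surface_area_mm2 = area_mm2,
    morph_surface_volume_ratio = if (vol_mm3 > 0) area_mm2 / vol_mm3 else 0,
    morph_sphericity = sph,
    morph_compactness1 = if (area_mm2 > 0)
      mesh_mm3 / (sqrt(pi) * area_mm2^1.5) else 0,
    morph_compactness2 = if (area_mm2 > 0)
      36 * pi * mesh_mm3^2 / area_mm2^3 else 0,
    morph_spherical_disproportion = if (sph > 0) 1 / sph else 0,
    morph_max_diameter_mm = diam,
    morph_elongation = elong,
    morph_flatness = flat)
}
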