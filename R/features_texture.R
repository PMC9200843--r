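## Gray-level texture matrices over the quantized ROI.
## GLRLM: runs accumulated over the 13 unique 3D directions and merged into
## one matrix before feature computation. GLSZM: zones are 26-connected
## components of equal gray level. NGTDM: 26-neighborhood gray-tone
## differences.

## the 13 unique 3D directions (one per +/- pair)
texture_directions <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- dirs$dz > 0 | (dirs$dz == 0 & (dirs$dy > 0 | (dirs$dy == 0 & dirs$dx > 0)))
  as.matrix(dirs[keep, ])
}

in_bounds <- function(co, d) {
  co[, 1] >= 1L & co[, 1] <= d[1] & co[, 2] >= 1L & co[, 2] <= d[2] &
    co[, 3] >= 1L & co[, 3] <= d[3]
}

## level at coordinates, NA when out of bounds or outside mask
lev_at <- function(lev, co, d) {
  ok <- in_bounds(co, d)
  out <- rep(NA_integer_, nrow(co))
  if (any(ok)) out[ok] <- lev[co[ok, , drop = FALSE]]
  out
}

#' Gray-level run-length matrix
#'
#' Accumulates run counts over the supplied directions (default: all 13
#' unique 3D directions, merged into a single matrix).
#'
#' @param quantized A \code{quantized_roi}.
#' @param directions Integer matrix of direction offsets (rows), default
#'   \code{texture_directions()}.
#' @return Matrix of counts, rows = gray level 1..N_g, columns = run length.
#' @export
glrlm_matrix <- function(quantized, directions = texture_directions()) {
  lev <- quantized$levels
  d <- dim(lev)
  ng <- quantized$n_levels
  vox <- which(!is.na(lev), arr.ind = TRUE)
  if (nrow(vox) == 0L) stop("quantized ROI is empty")
  maxlen <- max(d)
  P <- matrix(0, ng, maxlen)
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    lv <- lev[vox]
    prev <- sweep(vox, 2L, dir, `-`)
    pl <- lev_at(lev, prev, d)
    is_start <- is.na(pl) | pl != lv
    pos <- vox[is_start, , drop = FALSE]
    slev <- lv[is_start]
    rl <- rep(1L, nrow(pos))
    active <- seq_len(nrow(pos))
    cur <- pos
    while (length(active) > 0L) {
      nxt <- sweep(cur[active, , drop = FALSE], 2L, dir, `+`)
      nl <- lev_at(lev, nxt, d)
      cont <- !is.na(nl) & nl == slev[active]
      active <- active[cont]
      if (length(active) == 0L) break
      cur[active, ] <- nxt[cont, , drop = FALSE]
      rl[active] <- rl[active] + 1L
    }
    for (i in seq_along(rl)) P[slev[i], rl[i]] <- P[slev[i], rl[i]] + 1
  }
  ## trim trailing all-zero run-length columns (keep at least one)
  last <- max(1L, max(which(colSums(P) > 0)))
  P[, seq_len(last), drop = FALSE]
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal 26-connected sets of in-mask voxels sharing a gray
#' level.
#'
#' @param quantized A \code{quantized_roi}.
#' @return Matrix of counts, rows = gray level 1..N_g, columns = zone size.
#' @export
glszm_matrix <- function(quantized) {
  lev <- quantized$levels
  d <- dim(lev)
  ng <- quantized$n_levels
  lin <- which(!is.na(lev))
  if (length(lin) == 0L) stop("quantized ROI is empty")
  id <- array(NA_integer_, d)
  id[lin] <- seq_along(lin)
  co <- arrayInd(lin, d)
  lv <- lev[lin]
  dirs <- texture_directions()
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    nb <- sweep(co, 2L, dirs[r, ], `+`)
    ok <- in_bounds(nb, d)
    nid <- rep(NA_integer_, length(lin))
    nid[ok] <- id[nb[ok, , drop = FALSE]]   # NA if neighbor outside mask
    same <- !is.na(nid)
    if (any(same)) same[same] <- lv[same] == lv[nid[same]]
    efrom <- c(efrom, which(same))
    eto <- c(eto, nid[same])
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(efrom) > 0L)
    g <- igraph::add_edges(g, rbind(efrom, eto))
  comp <- igraph::components(g)
  zl <- lv[match(seq_len(comp$no), comp$membership)]
  zs <- comp$csize
  Z <- matrix(0, ng, max(zs))
  for (i in seq_along(zs)) Z[zl[i], zs[i]] <- Z[zl[i], zs[i]] + 1
  Z
}

#' Neighborhood gray-tone difference statistics
#'
#' For each gray level i: the number of contributing voxels n_i (those with
#' at least one in-mask 26-neighbor), the level probability p_i, and the
#' summed absolute difference s_i between the voxel level and the mean
#' level of its in-mask neighbors.
#'
#' @param quantized A \code{quantized_roi}.
#' @return List with \code{n}, \code{p}, \code{s} (length N_g) and
#'   \code{n_valid}.
#' @export
ngtdm_stats <- function(quantized) {
  lev <- quantized$levels
  d <- dim(lev)
  ng <- quantized$n_levels
  pl <- array(NA_integer_, d + 2L)
  pl[2:(d[1]+1), 2:(d[2]+1), 2:(d[3]+1)] <- lev
  nsum <- array(0, d); ncnt <- array(0L, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- pl[(2:(d[1]+1)) + dx, (2:(d[2]+1)) + dy, (2:(d[3]+1)) + dz,
             drop = FALSE]
    has <- !is.na(sh)
    nsum[has] <- nsum[has] + sh[has]
    ncnt <- ncnt + has
  }
  valid <- !is.na(lev) & ncnt > 0L
  if (!any(valid))
    stop("NGTDM undefined: no in-mask voxel has an in-mask neighbor")
  lv <- lev[valid]
  diffs <- abs(lv - nsum[valid] / ncnt[valid])
  n_i <- tabulate(lv, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(diffs[lv == i]), numeric(1))
  list(n = n_i, p = n_i / sum(n_i), s = s_i, n_valid = sum(n_i))
}

## ---- features from the matrices ------------------------------------------

rlm_style_features <- function(P, n_vox, n_dir) {
  Ns <- sum(P)
  ng <- nrow(P); nr <- ncol(P)
  i <- matrix(seq_len(ng), ng, nr)
  j <- matrix(seq_len(nr), ng, nr, byrow = TRUE)
  p <- P / Ns
  ri <- rowSums(P); rj <- colSums(P)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  nz <- p[p > 0]
  out <- c(
    sum(P / j^2) / Ns,            # short runs / small zones emphasis
    sum(P * j^2) / Ns,            # long runs / large zones emphasis
    sum(P / i^2) / Ns,            # low gray-level emphasis
    sum(P * i^2) / Ns,            # high gray-level emphasis
    sum(P / (i^2 * j^2)) / Ns,
    sum(P * i^2 / j^2) / Ns,
    sum(P * j^2 / i^2) / Ns,
    sum(P * i^2 * j^2) / Ns,
    sum(ri^2) / Ns,               # gray-level nonuniformity
    sum(ri^2) / Ns^2,             # ... normalized
    sum(rj^2) / Ns,               # run/zone-size nonuniformity
    sum(rj^2) / Ns^2,             # ... normalized
    Ns / (n_vox * n_dir),         # run/zone percentage
    sum(p * (i - mu_i)^2),        # gray-level variance
    sum(p * (j - mu_j)^2),        # run/zone-size variance
    -sum(nz * log2(nz)))          # entropy
  out
}

#' GLRLM features
#'
#' @param quantized A \code{quantized_roi}.
#' @param directions Direction offsets, default all 13.
#' @return Named numeric vector of the 16 GLRLM features.
#' @export
glrlm_features <- function(quantized, directions = texture_directions()) {
  P <- glrlm_matrix(quantized, directions)
  n_vox <- sum(!is.na(quantized$levels))
  out <- rlm_style_features(P, n_vox, nrow(directions))
  names(out) <- paste0("glrlm_", c(
    "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
    "gln", "glnn", "rln", "rlnn", "rp", "glv", "rlv", "re"))
  out
}

#' GLSZM features
#'
#' @param quantized A \code{quantized_roi}.
#' @return Named numeric vector of the 16 GLSZM features.
#' @export
glszm_features <- function(quantized) {
  Z <- glszm_matrix(quantized)
  n_vox <- sum(!is.na(quantized$levels))
  out <- rlm_style_features(Z, n_vox, 1L)
  names(out) <- paste0("glszm_", c(
    "sae", "lae", "lgze", "hgze", "salge", "sahge", "lalge", "lahge",
    "gln", "glnn", "zsn", "zsnn", "zp", "glv", "zsv", "ze"))
  out
}

#' NGTDM features
#'
#' Coarseness, contrast, busyness, complexity and strength following
#' Amadasun-King. A perfectly uniform region has all s_i = 0; its
#' coarseness is capped at 1e6 so the value stays finite while preserving
#' the ordering "smoother = coarser".
#'
#' @param quantized A \code{quantized_roi}.
#' @return Named numeric vector of the 5 NGTDM features.
#' @export
ngtdm_features <- function(quantized) {
  st <- ngtdm_stats(quantized)
  p <- st$p; s <- st$s; N <- st$n_valid
  ng <- length(p)
  act <- which(p > 0)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) min(1 / ps, 1e6) else 1e6
  npg <- length(act)
  contrast <- if (npg > 1) {
    grid <- expand.grid(i = act, j = act)
    (sum(p[grid$i] * p[grid$j] * (grid$i - grid$j)^2) /
       (npg * (npg - 1))) * (sum(s) / N)
  } else 0
  busy_den <- 0; cx <- 0; strength <- 0
  if (npg > 1) {
    grid <- expand.grid(i = act, j = act)
    gi <- grid$i; gj <- grid$j
    busy_den <- sum(abs(gi * p[gi] - gj * p[gj]))
    cx <- sum(abs(gi - gj) * (p[gi] * s[gi] + p[gj] * s[gj]) /
                (p[gi] + p[gj])) / N
    strength <- if (sum(s) > 0)
      sum((p[gi] + p[gj]) * (gi - gj)^2) / sum(s) else 0
  }
  busyness <- if (busy_den > 0) ps / busy_den else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = cx,
    ngtdm_strength = strength)
}
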