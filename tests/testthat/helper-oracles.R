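## Shared fixtures and independent oracles. The texture oracles are
## deliberately naive (explicit walks / flood fill / per-voxel neighbor
## loops) so they share no code path with the package implementations.

adjusted_rand <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  si <- sum(choose(t, 2))
  sa <- sum(choose(rowSums(t), 2))
  sb <- sum(choose(colSums(t), 2))
  e <- sa * sb / choose(n, 2)
  den <- (sa + sb) / 2 - e
  if (den == 0) return(1)
  (si - e) / den
}

## random quantized ROI on a small grid, with holes
random_quantized <- function(dims, n_levels, p_mask = 0.8) {
  lev <- array(NA_integer_, dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1] <- TRUE
  lev[m] <- sample.int(n_levels, sum(m), replace = TRUE)
  structure(list(levels = lev, edges = seq(0, 1, length.out = n_levels + 1),
                 n_levels = n_levels, spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

## oracle GLRLM: walk every line voxel by voxel
oracle_glrlm <- function(q, directions = radphen:::texture_directions()) {
  lev <- q$levels
  d <- dim(lev)
  get <- function(p) {
    if (any(p < 1) || any(p > d)) return(NA_integer_)
    lev[p[1], p[2], p[3]]
  }
  counts <- list()
  bump <- function(l, r) {
    key <- paste(l, r)
    counts[[key]] <<- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  for (r in seq_len(nrow(directions))) {
    dir <- directions[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z)
      v <- get(p)
      if (is.na(v)) next
      prev <- get(p - dir)
      if (!is.na(prev) && prev == v) next        # not a run start
      len <- 1L
      nxt <- p + dir
      while (!is.na(get(nxt)) && get(nxt) == v) {
        len <- len + 1L
        nxt <- nxt + dir
      }
      bump(v, len)
    }
  }
  maxr <- max(vapply(strsplit(names(counts), " "),
                     function(s) as.integer(s[2]), integer(1)))
  P <- matrix(0, q$n_levels, maxr)
  for (key in names(counts)) {
    s <- as.integer(strsplit(key, " ")[[1]])
    P[s[1], s[2]] <- counts[[key]]
  }
  P
}

## oracle GLSZM: breadth-first flood fill, 26-connectivity
oracle_glszm <- function(q) {
  lev <- q$levels
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- list()
  idx_all <- which(!is.na(lev), arr.ind = TRUE)
  for (s in seq_len(nrow(idx_all))) {
    p0 <- idx_all[s, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    v <- lev[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        np <- p + offs[k, ]
        if (any(np < 1) || any(np > d)) next
        if (seen[np[1], np[2], np[3]]) next
        lv <- lev[np[1], np[2], np[3]]
        if (is.na(lv) || lv != v) next
        seen[np[1], np[2], np[3]] <- TRUE
        queue[[length(queue) + 1L]] <- np
      }
    }
    zones[[length(zones) + 1L]] <- c(v, size)
  }
  zm <- do.call(rbind, zones)
  Z <- matrix(0, q$n_levels, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) Z[zm[r, 1], zm[r, 2]] <- Z[zm[r, 1], zm[r, 2]] + 1
  Z
}

## oracle NGTDM: per-voxel 26-neighborhood means by explicit loops
oracle_ngtdm <- function(q) {
  lev <- q$levels
  d <- dim(lev)
  n_i <- numeric(q$n_levels)
  s_i <- numeric(q$n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > d)) next
      u <- lev[p[1], p[2], p[3]]
      if (!is.na(u)) nb <- c(nb, u)
    }
    if (length(nb) == 0) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  list(n = n_i, s = s_i)
}

## greedy Ward agglomeration oracle (ward.D2 criterion, explicit centroids)
oracle_ward_partitions <- function(x) {
  x <- scale(x)
  n <- nrow(x)
  members <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(members) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(members)) for (j in seq_len(i - 1)) {
      a <- x[members[[i]], , drop = FALSE]
      b <- x[members[[j]], , drop = FALSE]
      na <- nrow(a); nb <- nrow(b)
      dc <- colMeans(a) - colMeans(b)
      crit <- 2 * na * nb / (na + nb) * sum(dc^2)   # Ward SS increase x2
      if (crit < best[1]) best <- c(crit, i, j)
    }
    i <- best[2]; j <- best[3]
    members[[j]] <- c(members[[j]], members[[i]])
    members[[i]] <- NULL
    k <- length(members)
    lab <- integer(n)
    for (ci in seq_along(members)) lab[members[[ci]]] <- ci
    partitions[[k]] <- lab
  }
  partitions
}

## small cohort specs reused across tests
spec_two_blobs <- function(n = 100, sep = 6, n_features = 10, seed = 3) {
  synthetic_spec(
    n_samples = n, n_features = n_features, batch_defs = list(),
    cluster_defs = list(k = 2, prop = c(0.5, 0.5), separation = sep,
                        informative_frac = 1),
    covariate_defs = list(),
    survival_defs = list(baseline_rate = 0.003, log_hr_cluster = 0,
                         log_hr_covariates = c(), censor_max = NULL),
    seed = seed)
}

spec_batch_only <- function(n = 200, n_features = 50, gamma = 1.5,
                            delta = 2, two_batches = TRUE, seed = 11) {
  bd <- list(contrast = list(prop = c(A = 0.6, B = 0.4),
                             gamma = c(0, gamma), delta = c(1, delta)))
  if (two_batches)
    bd$kernel <- list(prop = c(soft = 0.8, lung = 0.2),
                      gamma = c(0, gamma), delta = c(1, delta))
  synthetic_spec(
    n_samples = n, n_features = n_features, batch_defs = bd,
    cluster_defs = list(k = 1, prop = 1, separation = 0,
                        informative_frac = 0.5),
    covariate_defs = list(),
    survival_defs = list(baseline_rate = log(2) / 270, log_hr_cluster = 0,
                         log_hr_covariates = c(), censor_max = 1500),
    seed = seed)
}
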