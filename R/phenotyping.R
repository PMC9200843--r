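## Phenotype discovery: Ward hierarchical clustering on z-scored features,
## consensus-clustering stability over subsamples, SigClust significance of
## each binary split, and selection of the number of phenotypes.

zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2L, mu, `-`), 2L, s, `/`)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Euclidean distance and Ward's
#' minimum-variance criterion (merges chosen on the squared-Euclidean
#' increase, \code{hclust} method \code{ward.D2}); features are z-scored
#' per column first so mixed-scale radiomics do not dominate the metric.
#'
#' @param x Samples x features matrix.
#' @param k Number of clusters, 1 <= k <= n.
#' @param scale. Z-score columns first (default TRUE).
#' @return Integer vector of cluster labels in 1..k.
#' @export
ward_cluster <- function(x, k, scale. = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  if (k == 1L) return(rep(1L, n))
  if (scale.) x <- zscore_cols(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  unname(stats::cutree(hc, k = k))
}

#' Consensus clustering over subsamples
#'
#' For each candidate k, the cohort is repeatedly subsampled without
#' replacement, clustered with \code{\link{ward_cluster}}, and the
#' proportion of times each sample pair lands in the same cluster — out of
#' the times the pair was co-sampled — is accumulated into a consensus
#' matrix. Stability per k is summarized by the area under the empirical
#' CDF of the upper-triangular consensus values.
#'
#' @param x Samples x features matrix.
#' @param k_range Candidate cluster numbers (default 2:6).
#' @param n_resamples Number of subsamples (default 1000).
#' @param frac Subsample fraction in (0, 1] (default 0.8).
#' @param seed Integer seed.
#' @return Object of class \code{consensus_result}: per-k list with
#'   \code{consensus} matrix (NA where a pair was never co-sampled),
#'   \code{cdf} (function-ready sorted values), \code{auc}; plus
#'   \code{k_range}, \code{n_resamples}, \code{frac}, \code{seed}. Pairs
#'   never co-sampled are excluded from the CDF and counted in
#'   \code{n_missing_pairs}.
#' @export
consensus_cluster <- function(x, k_range = 2:6, n_resamples = 1000L,
                              frac = 0.8, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_resamples < 2L) stop("n_resamples must be >= 2")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  set.seed(seed)
  m <- max(2L, round(frac * n))
  co <- matrix(0, n, n)                        # times co-sampled
  hit <- lapply(k_range, function(k) matrix(0, n, n))
  names(hit) <- as.character(k_range)
  xz <- zscore_cols(x)
  for (r in seq_len(n_resamples)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    co[idx, idx] <- co[idx, idx] + 1
    hc <- stats::hclust(stats::dist(xz[idx, , drop = FALSE]),
                        method = "ward.D2")
    for (k in k_range) {
      lab <- stats::cutree(hc, k = min(k, m))
      same <- outer(lab, lab, `==`)
      hit[[as.character(k)]][idx, idx] <-
        hit[[as.character(k)]][idx, idx] + same
    }
  }
  per_k <- list()
  for (k in k_range) {
    M <- hit[[as.character(k)]] / co
    M[co == 0] <- NA
    diag(M) <- 1
    v <- M[upper.tri(M)]
    v <- v[!is.na(v)]
    sv <- sort(v)
    cdf <- seq_along(sv) / length(sv)
    ## area under the CDF over [0, 1]
    xs <- c(0, sv, 1)
    ys <- c(0, cdf, 1)
    auc <- sum(diff(xs) * ys[-length(ys)])
    per_k[[as.character(k)]] <- list(consensus = M, values = sv,
                                     cdf = cdf, auc = auc)
  }
  structure(list(per_k = per_k, k_range = k_range,
                 n_resamples = n_resamples, frac = frac, seed = seed,
                 n_missing_pairs = sum(co[upper.tri(co)] == 0)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(x$k_range, collapse = ", "),
      sprintf("(%d resamples, %.0f%% subsampling)\n",
              x$n_resamples, 100 * x$frac))
  for (k in x$k_range)
    cat(sprintf("  k=%d: area under CDF = %.3f\n", k,
                x$per_k[[as.character(k)]]$auc))
  if (x$n_missing_pairs > 0)
    cat("  pairs never co-sampled:", x$n_missing_pairs, "\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF",
                 main = "Consensus CDF by k", ...)
  cols <- grDevices::hcl.colors(length(x$k_range), "Dark 3")
  for (i in seq_along(x$k_range)) {
    pk <- x$per_k[[as.character(x$k_range[i])]]
    graphics::lines(c(0, pk$values, 1), c(0, pk$cdf, 1), type = "s",
                    col = cols[i])
  }
  graphics::legend("bottomright", legend = paste0("k=", x$k_range),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}

## 2-cluster index: within-cluster SS about cluster means over total SS
cluster_index_2means <- function(x, nstart = 10L) {
  km <- stats::kmeans(x, centers = 2L, nstart = nstart)
  km$tot.withinss / km$totss
}

#' SigClust significance test for two-cluster structure
#'
#' Compares the observed 2-cluster index (within-cluster sum of squares
#' over total sum of squares, from 2-means with restarts) to its null
#' distribution under a single Gaussian fitted to the data, and reports
#' the fraction of null indices at or below the observed one.
#'
#' The null covariance is diagonal in the data's eigenbasis; how its
#' eigenvalues are estimated matters at moderate n/d because raw sample
#' eigenvalues are overdispersed, which makes the simulated null easier to
#' split than the data and the test badly conservative. The default
#' \code{null_cov = "adaptive"} therefore pretests sphericity (John's
#' test, alpha 0.05): when sphericity is retained the null is spherical
#' with the average variance (exactly calibrated in that regime);
#' otherwise the eigenvalues of an oracle-approximating-shrinkage (OAS)
#' covariance estimate are used, floored at the background-noise variance
#' (the squared median absolute deviation of all centered entries), which
#' preserves genuine elongation. Both the pretest and the shrinkage
#' assume n appreciably larger than d, so when d > n/2 the adaptive mode
#' falls back to \code{"floored"} — the classic high-dimension
#' low-sample-size construction (raw eigenvalues hard-floored at the
#' background variance), which stays valid (if conservative) there.
#' \code{"raw"} uses the sample eigenvalues untouched.
#'
#' @param x Samples x features matrix, n >= 4.
#' @param n_sim Number of null simulations (default 10000).
#' @param seed Integer seed.
#' @param null_cov Null covariance eigenvalue construction:
#'   \code{"adaptive"} (default), \code{"floored"}, or \code{"raw"}.
#' @param nstart 2-means restarts (default 10).
#' @return Object of class \code{sigclust_result}: \code{ci},
#'   \code{null_ci}, \code{p}, \code{n_sim}, \code{eigenvalues} (used for
#'   the null), \code{sigma2_background}.
#' @export
sigclust <- function(x, n_sim = 10000L, seed = 1L,
                     null_cov = c("adaptive", "floored", "raw"),
                     nstart = 10L) {
  x <- as.matrix(x)
  null_cov <- match.arg(null_cov)
  n <- nrow(x); d <- ncol(x)
  if (n < 4L) stop("sigclust needs at least 4 samples")
  if (n_sim < 100L) stop("n_sim must be >= 100")
  set.seed(seed)
  xc <- sweep(x, 2L, colMeans(x))
  ## robust background-noise variance: MAD (consistent for the normal SD)
  ## of all centered entries, squared
  sig2_bg <- stats::mad(as.vector(xc))^2
  S <- crossprod(xc) / n
  ev <- pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
  ## the sphericity pretest and OAS shrinkage assume n appreciably larger
  ## than d; in the (near-)HDLSS regime fall back to the background-floor
  ## null, the appropriate construction there
  if (null_cov == "adaptive" && d > n / 2) null_cov <- "floored"
  lambda <- switch(null_cov,
    raw = ev,
    floored = pmax(ev, sig2_bg),
    adaptive = {
      mu <- mean(diag(S))
      john <- n * d * (sum((S / mu - diag(d))^2) / d) / 2
      p_sph <- stats::pchisq(john, d * (d + 1) / 2 - 1, lower.tail = FALSE)
      if (p_sph >= 0.05) {
        rep(mu, d)
      } else {
        tr2 <- sum(S^2)
        rho <- min(1, ((1 - 2 / d) * tr2 + sum(diag(S))^2) /
                     ((n + 1 - 2 / d) * (tr2 - sum(diag(S))^2 / d)))
        evs <- eigen((1 - rho) * S + rho * mu * diag(d),
                     symmetric = TRUE, only.values = TRUE)$values
        pmax(evs, sig2_bg)
      }
    })
  obs <- cluster_index_2means(xc, nstart)
  null_ci <- vapply(seq_len(n_sim), function(s) {
    z <- matrix(stats::rnorm(n * d), n, d)
    z <- sweep(z, 2L, sqrt(lambda[seq_len(d)]), `*`)
    cluster_index_2means(z, nstart)
  }, numeric(1))
  structure(list(ci = obs, null_ci = null_ci,
                 p = mean(null_ci <= obs), n_sim = n_sim,
                 sigma2_background = sig2_bg, eigenvalues = lambda),
            class = "sigclust_result")
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat(sprintf("sigclust: cluster index = %.4f, p = %.4g (%d null simulations)\n",
              x$ci, x$p, x$n_sim))
  invisible(x)
}

#' Select the number of phenotypes
#'
#' Chooses the largest candidate k whose relative increase in consensus
#' CDF area exceeds \code{rel_delta} and whose every binary split along
#' the Ward dendrogram is SigClust-significant at \code{alpha}. Falls back
#' to k = 2 (with a \code{no_structure} flag when even the root split is
#' not significant).
#'
#' @param consensus A \code{\link{consensus_cluster}} result starting at
#'   k = 2.
#' @param x The feature matrix the consensus was computed on.
#' @param alpha SigClust significance level (default 0.05).
#' @param rel_delta Relative delta-area stability threshold (default 0.1).
#' @param n_sim,seed,nstart Passed to \code{\link{sigclust}}.
#' @return List: \code{k}, \code{assignment} (Ward labels at k),
#'   \code{no_structure} flag, \code{splits} (per-split SigClust p),
#'   \code{rel_delta_area}.
#' @export
select_k <- function(consensus, x, alpha = 0.05, rel_delta = 0.1,
                     n_sim = 1000L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(consensus, "consensus_result"))
  kr <- consensus$k_range
  if (kr[1] != 2L) stop("k range must start at 2")
  x <- zscore_cols(x)
  auc <- vapply(kr, function(k) consensus$per_k[[as.character(k)]]$auc,
                numeric(1))
  rel <- c(auc[1], diff(auc) / auc[-length(auc)])
  names(rel) <- as.character(kr)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  ## p-value of the split introduced when moving from j-1 to j clusters
  split_p <- rep(NA_real_, max(kr))
  split_members <- function(j) {
    lab_lo <- stats::cutree(hc, k = j - 1L)
    lab_hi <- stats::cutree(hc, k = j)
    tab <- table(lab_lo, lab_hi)
    parent <- which(rowSums(tab > 0) == 2L)[1]  # the cluster that split
    which(lab_lo == parent)
  }
  sig_for <- function(j) {
    mem <- if (j == 2L) seq_len(nrow(x)) else split_members(j)
    if (length(mem) < 4L) return(1)
    sigclust(x[mem, , drop = FALSE], n_sim = n_sim,
             seed = seed + j, nstart = nstart)$p
  }
  valid <- logical(length(kr))
  for (i in seq_along(kr)) {
    k <- kr[i]
    if (rel[i] <= rel_delta) { valid[i] <- FALSE; next }
    ## family-wise control across the k-1 splits examined: a calibrated
    ## per-split test at alpha would inflate the selected k with
    ## probability ~ (k-1) alpha under the true model
    thr <- alpha / (k - 1)
    ok <- TRUE
    for (j in 2:k) {
      if (is.na(split_p[j])) split_p[j] <- sig_for(j)
      if (split_p[j] >= thr) { ok <- FALSE; break }
    }
    valid[i] <- ok
  }
  if (is.na(split_p[2])) split_p[2] <- sig_for(2L)
  no_structure <- split_p[2] >= alpha
  k_sel <- if (any(valid)) max(kr[valid]) else 2L
  if (no_structure) {
    k_sel <- 2L
    message("select_k: no significant cluster structure (root SigClust p = ",
            signif(split_p[2], 3), "); falling back to k = 2")
  }
  list(k = k_sel, assignment = unname(stats::cutree(hc, k = k_sel)),
       no_structure = no_structure, splits = split_p[2:max(kr)],
       rel_delta_area = rel)
}
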