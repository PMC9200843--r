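## k-sample Anderson-Darling test (Scholz-Stephens), tie-corrected
## (midrank) statistic with the asymptotic interpolation p-value; exact
## permutation p-values for small groups.

ad_statistic <- function(x, g) {
  g <- as.factor(g)
  N <- length(x)
  k <- nlevels(g)
  z <- sort(unique(x))
  L <- length(z)
  l_j <- vapply(z, function(v) sum(x == v), numeric(1))
  B_j <- cumsum(l_j)
  Ba <- B_j - l_j / 2
  A2 <- 0
  for (lev in levels(g)) {
    xi <- x[g == lev]
    n_i <- length(xi)
    f_ij <- vapply(z, function(v) sum(xi == v), numeric(1))
    M_ij <- cumsum(f_ij)
    Ma <- M_ij - f_ij / 2
    num <- (N * Ma - n_i * Ba)^2
    den <- Ba * (N - Ba) - N * l_j / 4
    inner <- sum((l_j / N) * num / den)
    A2 <- A2 + inner / n_i
  }
  A2 * (N - 1) / N
}

ad_sigma2 <- function(n_i, N) {
  k <- length(n_i)
  H <- sum(1 / n_i)
  h <- sum(1 / seq_len(N - 1))
  g <- 0  # sum_{i<j<N} 1 / ((N - i) j)
  for (ii in seq_len(N - 2)) g <- g + sum(1 / ((N - ii) * ((ii + 1):(N - 1))))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
}

## asymptotic p by quadratic interpolation of log significance levels
## against the tabulated critical values of the standardized statistic
ad_p_asymptotic <- function(tx, m) {
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  sig <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  crit <- b0 + b1 / sqrt(m) + b2 / m
  cf <- stats::lm.fit(cbind(1, crit, crit^2), log(sig))$coefficients
  logp_at <- function(t) cf[1] + cf[2] * t + cf[3] * t^2
  ## beyond the largest tabulated critical value the quadratic is not
  ## monotone; continue with its tangent so p keeps decreasing
  tmax <- max(crit)
  lp <- if (tx <= tmax) logp_at(tx)
        else logp_at(tmax) + (cf[2] + 2 * cf[3] * tmax) * (tx - tmax)
  unname(min(max(exp(lp), 0), 1))
}

#' k-sample Anderson-Darling test
#'
#' Tie-corrected (midrank) k-sample Anderson-Darling statistic with the
#' asymptotic interpolated p-value. When any group has fewer than
#' \code{exact_threshold} observations the asymptotic approximation is
#' unreliable; a seeded permutation p-value is used instead (with a
#' warning).
#'
#' @param x Numeric vector of observations.
#' @param g Group labels (>= 2 groups).
#' @param exact_threshold Minimum group size for the asymptotic p.
#' @param n_perm Number of permutations for the exact fallback.
#' @param perm_seed Seed for the permutation fallback.
#' @return List: \code{statistic} (A2akN), \code{standardized}, \code{p},
#'   \code{method}.
#' @export
ad_ksample <- function(x, g, exact_threshold = 5L, n_perm = 2000L,
                       perm_seed = 1L) {
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  n_i <- as.numeric(table(g))
  N <- length(x)
  A2 <- ad_statistic(x, g)
  m <- nlevels(g) - 1
  s2 <- ad_sigma2(n_i, N)
  tx <- (A2 - m) / sqrt(s2)
  if (min(n_i) < exact_threshold) {
    warning("group with < ", exact_threshold,
            " samples: using permutation p-value")
    set.seed(perm_seed)
    stat_perm <- replicate(n_perm, ad_statistic(x, sample(g)))
    p <- (1 + sum(stat_perm >= A2)) / (n_perm + 1)
    method <- "permutation"
  } else {
    p <- ad_p_asymptotic(tx, m)
    method <- "asymptotic"
  }
  list(statistic = A2, standardized = tx, p = p, method = method)
}

#' Count batch-associated features by the Anderson-Darling test
#'
#' Applies the k-sample AD test to every feature across the levels of one
#' batch variable and counts features significant at \code{alpha}.
#'
#' @param features Samples x features matrix or data.frame.
#' @param batch Batch labels.
#' @param alpha Significance level (default 0.05).
#' @param ... Passed to \code{\link{ad_ksample}}.
#' @return List: \code{count}, \code{p_values} (named), \code{alpha}.
#' @export
ad_significant_count <- function(features, batch, alpha = 0.05, ...) {
  X <- as.matrix(features)
  p <- vapply(seq_len(ncol(X)),
              function(j) ad_ksample(X[, j], batch, ...)$p, numeric(1))
  names(p) <- colnames(X)
  list(count = sum(p < alpha), p_values = p, alpha = alpha)
}
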