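## Empirical-Bayes location/scale harmonization (ComBat) with protected
## covariates. Parametric priors: normal on the per-batch location shifts,
## inverse-gamma on the per-batch scale factors, hyperparameters moment
## matched, conditional modes iterated to convergence.

#' Build the protected-covariate design matrix
#'
#' Encodes the biological variables preserved during harmonization:
#' categorical covariates are reference-coded (first level), continuous
#' ones standardized. Progression-free survival time and event status may
#' be included among the protected variables; this follows the harmonized
#' analysis design but leaks outcome information into the features, so it
#' is controlled by \code{protect_outcome} and off by default only when a
#' caller opts out.
#'
#' @param clinical data.frame of per-sample covariates.
#' @param protect Character vector of column names to protect (default:
#'   all columns).
#' @param protect_outcome Logical; keep \code{pfs_days}/\code{event}
#'   columns if present (default TRUE, matching the design that protects
#'   recurrence event and PFS months).
#' @return Numeric matrix (no intercept) with full column rank.
#' @export
protected_design <- function(clinical, protect = colnames(clinical),
                             protect_outcome = TRUE) {
  keep <- intersect(protect, colnames(clinical))
  if (!protect_outcome) keep <- setdiff(keep, c("pfs_days", "event"))
  if (length(keep) == 0L) return(NULL)
  cols <- list()
  for (nm in keep) {
    x <- clinical[[nm]]
    if (is.factor(x) || is.character(x)) {
      f <- factor(x)
      if (nlevels(f) < 2L) next
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(f)[-1])
      cols[[nm]] <- mm
    } else {
      s <- stats::sd(x)
      cols[[nm]] <- matrix(if (s > 0) (x - mean(x)) / s else x * 0,
                           ncol = 1, dimnames = list(NULL, nm))
    }
  }
  if (length(cols) == 0L) return(NULL)
  X <- do.call(cbind, cols)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  X
}

## iterated conditional modes for the EB posterior (per batch)
eb_iterate <- function(Z_b, g_hat, d_hat, g_bar, t2, a_pr, b_pr,
                       tol = 1e-4, maxit = 100L) {
  n_b <- nrow(Z_b)
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
    ss <- colSums((Z_b - matrix(g_new, n_b, length(g_new),
                                byrow = TRUE))^2)
    d_new <- (b_pr + 0.5 * ss) / (n_b / 2 + a_pr - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-8),
                  abs(d_new - d_old) / (abs(d_old) + 1e-8))
    g_old <- g_new; d_old <- d_new
    if (change < tol) break
  }
  list(gamma_star = g_old, delta_star = d_old, iterations = it)
}

#' ComBat harmonization by a single batch variable
#'
#' Standardizes each feature with a least-squares fit that includes batch
#' indicators and the protected covariates, shrinks per-batch location and
#' scale estimates toward their empirical-Bayes priors, and returns the
#' batch-adjusted features on the original scale with covariate effects
#' restored.
#'
#' @param features Samples x features numeric matrix (or data.frame).
#' @param batch Factor (or coercible) of batch levels, each with >= 2
#'   samples.
#' @param covariates Optional numeric design matrix of protected
#'   covariates (no intercept), e.g. from \code{\link{protected_design}}.
#' @param parametric Logical; parametric empirical Bayes (the only variant
#'   implemented; kept as an argument for config echo).
#' @param tol,maxit Convergence tolerance on the maximum relative
#'   parameter change and iteration cap for the EB updates.
#' @return List of class \code{combat_fit}: \code{harmonized} (matrix like
#'   \code{features}), \code{estimates} (per batch level: \code{gamma_hat},
#'   \code{gamma_star}, \code{delta_hat}, \code{delta_star}, priors),
#'   \code{sigma} (pooled per-feature SD), \code{batch}.
#' @export
combat <- function(features, batch, covariates = NULL, parametric = TRUE,
                   tol = 1e-4, maxit = 100L) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  batch <- droplevels(as.factor(batch))
  n <- nrow(X); G <- ncol(X)
  if (length(batch) != n) stop("batch length must match sample count")
  cnt <- table(batch)
  if (any(cnt < 2L))
    stop("batch level(s) with < 2 samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  v <- apply(X, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  B <- stats::model.matrix(~ -1 + batch)
  design <- if (is.null(covariates)) B else cbind(B, as.matrix(covariates))
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("singular design: protected covariates confounded with batch")
  nb <- nlevels(batch)
  ## least-squares fit, feature-wise
  Bhat <- solve(crossprod(design), crossprod(design, X))   # p x G
  w <- as.numeric(cnt[levels(batch)]) / n
  alpha <- drop(w %*% Bhat[seq_len(nb), , drop = FALSE])   # grand location
  stand_mean <- matrix(alpha, n, G, byrow = TRUE)
  if (!is.null(covariates))
    stand_mean <- stand_mean +
      as.matrix(covariates) %*% Bhat[-(seq_len(nb)), , drop = FALSE]
  resid <- X - design %*% Bhat
  sigma2 <- colSums(resid^2) / n                           # pooled variance
  Z <- (X - stand_mean) / matrix(sqrt(sigma2), n, G, byrow = TRUE)

  est <- list()
  Xadj <- Z
  for (b in levels(batch)) {
    sel <- batch == b
    Zb <- Z[sel, , drop = FALSE]
    g_hat <- colMeans(Zb)
    d_hat <- apply(Zb, 2L, stats::var)
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_pr <- (2 * s2 + m^2) / s2
    b_pr <- (m * s2 + m^3) / s2
    eb <- eb_iterate(Zb, g_hat, d_hat, g_bar, t2, a_pr, b_pr, tol, maxit)
    Xadj[sel, ] <- sweep(sweep(Zb, 2L, eb$gamma_star, `-`),
                         2L, sqrt(eb$delta_star), `/`)
    est[[b]] <- list(gamma_hat = g_hat, gamma_star = eb$gamma_star,
                     delta_hat = d_hat, delta_star = eb$delta_star,
                     gamma_bar = g_bar, tau2 = t2,
                     a_prior = a_pr, b_prior = b_pr,
                     iterations = eb$iterations, n = sum(sel))
  }
  harmonized <- Xadj * matrix(sqrt(sigma2), n, G, byrow = TRUE) + stand_mean
  dimnames(harmonized) <- dimnames(X)
  structure(list(harmonized = harmonized, estimates = est,
                 sigma = sqrt(sigma2), batch = batch,
                 parametric = parametric),
            class = "combat_fit")
}

#' @export
print.combat_fit <- function(x, ...) {
  cat("combat_fit:", length(x$sigma), "features,",
      nlevels(x$batch), "batch levels (",
      paste(levels(x$batch), collapse = ", "), ")\n")
  for (b in names(x$estimates)) {
    e <- x$estimates[[b]]
    cat(sprintf("  %s (n=%d): mean gamma* = %+.3f, mean delta* = %.3f\n",
                b, e$n, mean(e$gamma_star), mean(e$delta_star)))
  }
  invisible(x)
}
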