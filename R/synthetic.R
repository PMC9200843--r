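#' Specification for a synthetic radiomic cohort
#'
#' Defines the generative model used to exercise the pipeline without
#' patient data. Features follow the location/scale batch-effect model that
#' empirical-Bayes harmonization assumes: feature g of sample j in batch
#' level i and cluster c is
#' \deqn{x_{gj} = \mu_g + cluster_{cg} + covariates_j \beta_g +
#'   \gamma_{ig}\sigma_g + \delta_{ig}\sigma_g\varepsilon_{gj}}
#' with standard-normal noise. Per-feature scales \eqn{\sigma_g} are drawn
#' log-uniform in [0.5, 2] so harmonization is tested on unequal scales.
#' Defaults mirror a 107-patient two-batch CT cohort: batch levels with
#' 80/27 (contrast) and 90/17 (kernel) frequencies, location shift
#' \eqn{\gamma = 1.5} and scale factor \eqn{\delta = 2} on the minority
#' level, two planted phenotype clusters, and exponential
#' progression-free-survival times with uniform censoring.
#'
#' @param n_samples Number of samples.
#' @param n_features Number of features.
#' @param batch_defs Named list; each element a list with \code{prop}
#'   (named level proportions summing to 1), \code{gamma} (per-level
#'   location shift in units of the feature SD) and \code{delta}
#'   (per-level scale factor, > 0).
#' @param cluster_defs List: \code{k}, \code{prop} (length k, sums to 1),
#'   \code{separation} (difference between adjacent cluster means on
#'   informative features, in SD units), \code{informative_frac}
#'   (fraction of features carrying the cluster signal).
#' @param covariate_defs Named list of covariate definitions; each element
#'   is either \code{list(type = "continuous", mean, sd, feature_effect)}
#'   or \code{list(type = "categorical", prop = named proportions,
#'   feature_effect)}. \code{feature_effect} (SD units per standardized
#'   unit / per level step) is applied to the informative feature block.
#' @param survival_defs List: \code{baseline_rate} (events/day, > 0),
#'   \code{log_hr_cluster} (per cluster step), \code{log_hr_covariates}
#'   (named, per standardized unit), \code{censor_max} (days; NULL
#'   disables censoring).
#' @param batch_cluster_confounding In [0, 1); shifts batch-level
#'   probabilities with cluster membership to stress confounded designs.
#'   0 (default) draws batch and cluster independently.
#' @param seed Integer seed; all randomness flows through it.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_samples = 107L,
                           n_features = 102L,
                           batch_defs = list(
                             contrast = list(
                               prop = c(enhanced = 80 / 107,
                                        non_enhanced = 27 / 107),
                               gamma = c(0, 1.5), delta = c(1, 2)),
                             kernel = list(
                               prop = c(soft_tissue = 90 / 107,
                                        lung = 17 / 107),
                               gamma = c(0, 1.5), delta = c(1, 2))),
                           cluster_defs = list(k = 2L,
                                               prop = c(0.52, 0.48),
                                               separation = 2,
                                               informative_frac = 0.5),
                           covariate_defs = list(
                             age = list(type = "continuous", mean = 67,
                                        sd = 10, feature_effect = 0),
                             sex = list(type = "categorical",
                                        prop = c(male = 0.486,
                                                 female = 0.514),
                                        feature_effect = 0),
                             pdl1_pct = list(type = "continuous", mean = 34,
                                             sd = 30, feature_effect = 0),
                             ecog = list(type = "categorical",
                                         prop = c(`0` = 0.327, `1` = 0.486,
                                                  `2` = 0.140, `3` = 0.047),
                                         feature_effect = 0),
                             bmi = list(type = "continuous", mean = 26.7,
                                        sd = 4.5, feature_effect = 0),
                             smoking = list(type = "categorical",
                                            prop = c(former = 0.505,
                                                     current = 0.364,
                                                     never = 0.131),
                                            feature_effect = 0),
                             therapy = list(type = "categorical",
                                            prop = c(combination = 0.711,
                                                     monotherapy = 0.289),
                                            feature_effect = 0)),
                           survival_defs = list(
                             baseline_rate = log(2) / 270,
                             log_hr_cluster = 0.4,
                             log_hr_covariates = c(ecog = 0.25),
                             censor_max = 1500),
                           batch_cluster_confounding = 0,
                           seed = 1L) {
  chk_prop <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " proportions must be non-negative and sum to 1")
  }
  stopifnot(n_samples >= 4L, n_features >= 1L)
  for (nm in names(batch_defs)) {
    b <- batch_defs[[nm]]
    chk_prop(b$prop, paste("batch", nm))
    if (length(b$gamma) != length(b$prop) ||
        length(b$delta) != length(b$prop))
      stop("batch ", nm, ": gamma/delta must have one entry per level")
    if (any(b$delta <= 0)) stop("batch ", nm, ": delta must be > 0")
  }
  chk_prop(cluster_defs$prop, "cluster")
  if (length(cluster_defs$prop) != cluster_defs$k)
    stop("cluster prop must have k entries")
  if (survival_defs$baseline_rate <= 0)
    stop("baseline hazard rate must be > 0")
  if (batch_cluster_confounding < 0 || batch_cluster_confounding >= 1)
    stop("batch_cluster_confounding must be in [0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 batch_defs = batch_defs, cluster_defs = cluster_defs,
                 covariate_defs = covariate_defs,
                 survival_defs = survival_defs,
                 batch_cluster_confounding = batch_cluster_confounding,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_levels <- function(n, prop, shift = NULL) {
  lv <- names(prop)
  if (is.null(lv)) lv <- as.character(seq_along(prop))
  if (is.null(shift)) {
    factor(sample(lv, n, replace = TRUE, prob = prop), levels = lv)
  } else {
    ## per-sample probability shift toward the minority level (confounding)
    out <- character(n)
    for (j in seq_len(n)) {
      p <- prop + shift[j] * c(-1, 1) * min(prop)
      p <- pmax(p, 0.01); p <- p / sum(p)
      out[j] <- sample(lv, 1L, prob = p)
    }
    factor(out, levels = lv)
  }
}

#' Simulate a synthetic feature cohort
#'
#' Draws cluster, batch and covariate assignments, builds the feature
#' table under the planted location/scale batch model, and attaches
#' proportional-hazards survival outcomes. Deterministic for a fixed spec
#' seed.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Object of class \code{synthetic_cohort}: list with
#'   \code{features} (n x G matrix, named columns), \code{batches}
#'   (data.frame of factors), \code{clinical} (covariates + \code{pfs_days}
#'   + \code{event} + \code{tumor_volume_cm3}), \code{cluster_truth},
#'   \code{sigma} (per-feature SD), \code{informative} (logical per
#'   feature), and the \code{spec}.
#' @export
simulate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; G <- spec$n_features
  cd <- spec$cluster_defs
  cluster <- sample(seq_len(cd$k), n, replace = TRUE, prob = cd$prop)
  conf <- spec$batch_cluster_confounding
  shift <- if (conf > 0 && cd$k > 1)
    conf * (cluster - mean(seq_len(cd$k))) / (cd$k - 1) * 2 else NULL
  batches <- lapply(names(spec$batch_defs), function(nm) {
    b <- spec$batch_defs[[nm]]
    lab <- draw_levels(n, b$prop, shift)
    cnt <- table(lab)
    if (any(cnt < 2L))
      stop(sprintf("batch variable '%s': level '%s' received %d sample(s) (< 2)",
                   nm, names(cnt)[which.min(cnt)], min(cnt)))
    lab
  })
  names(batches) <- names(spec$batch_defs)
  batches <- as.data.frame(batches, stringsAsFactors = TRUE)

  ## covariates
  cov_list <- list()
  for (nm in names(spec$covariate_defs)) {
    cvd <- spec$covariate_defs[[nm]]
    cov_list[[nm]] <- if (cvd$type == "continuous")
      stats::rnorm(n, cvd$mean, cvd$sd)
    else draw_levels(n, cvd$prop)
  }
  clinical <- if (length(cov_list))
    as.data.frame(cov_list, stringsAsFactors = TRUE)
  else data.frame(row.names = seq_len(n))

  ## feature table
  sigma <- exp(stats::runif(G, log(0.5), log(2)))
  mu <- stats::rnorm(G, 0, 3)
  n_inf <- max(1L, round(cd$informative_frac * G))
  informative <- seq_len(G) <= n_inf   # fixed block, not resampled
  X <- matrix(mu, n, G, byrow = TRUE)
  if (cd$k > 1 && cd$separation != 0) {
    centered <- cluster - mean(seq_len(cd$k))
    X <- X + outer(centered, ifelse(informative, cd$separation, 0) * sigma)
  }
  for (nm in names(spec$covariate_defs)) {
    cvd <- spec$covariate_defs[[nm]]
    if (is.null(cvd$feature_effect) || cvd$feature_effect == 0) next
    z <- covariate_numeric(clinical[[nm]])
    X <- X + outer(z, ifelse(informative, cvd$feature_effect, 0) * sigma)
  }
  eps <- matrix(stats::rnorm(n * G), n, G)
  for (nm in names(spec$batch_defs)) {
    b <- spec$batch_defs[[nm]]
    i <- as.integer(batches[[nm]])
    X <- X + outer(b$gamma[i], sigma)
    eps <- eps * matrix(b$delta[i], n, G) # scale factors multiply the noise
  }
  X <- X + eps * matrix(sigma, n, G, byrow = TRUE)
  colnames(X) <- sprintf("feature_%03d", seq_len(G))
  rownames(X) <- sprintf("sample_%03d", seq_len(n))

  ## tumor volume: log-normal, larger in higher clusters
  vol <- exp(stats::rnorm(n, log(40) + 0.5 * (cluster - 1), 0.6))
  clinical$tumor_volume_cm3 <- vol

  ## survival
  sd_ <- spec$survival_defs
  lp <- sd_$log_hr_cluster * (cluster - mean(seq_len(cd$k)))
  for (nm in names(sd_$log_hr_covariates)) {
    z <- covariate_numeric(clinical[[nm]])
    lp <- lp + sd_$log_hr_covariates[[nm]] * z
  }
  surv <- simulate_survival(lp, baseline_rate = sd_$baseline_rate,
                            censor_max = sd_$censor_max, seed = NULL)
  clinical$pfs_days <- surv$time
  clinical$event <- surv$event
  structure(list(features = X, batches = batches, clinical = clinical,
                 cluster_truth = cluster, sigma = sigma,
                 informative = informative, spec = spec),
            class = "synthetic_cohort")
}

## numeric coding used for survival/feature effects: standardized for
## continuous covariates, 0-based level index for categorical ones
covariate_numeric <- function(x) {
  if (is.factor(x) || is.character(x)) {
    as.integer(factor(x)) - 1
  } else {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else x * 0
  }
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$features), "samples x",
      ncol(x$features), "features;",
      ncol(x$batches), "batch variable(s);",
      x$spec$cluster_defs$k, "planted cluster(s);",
      sum(x$clinical$event), "events\n")
  invisible(x)
}

#' Simulate proportional-hazards survival times
#'
#' Event times are exponential with rate
#' \code{baseline_rate * exp(linear_predictor)}; an independent uniform
#' censoring time on (0, censor_max] truncates them (event = 0 when
#' censoring comes first). \code{censor_max = NULL} disables censoring.
#'
#' @param linear_predictor Numeric per-sample log hazard ratios (finite).
#' @param baseline_rate Baseline hazard rate per day, > 0.
#' @param censor_max Upper end of the uniform censoring window (days), or
#'   NULL.
#' @param seed Optional integer seed (NULL inherits the current RNG
#'   state).
#' @return data.frame with \code{time} (days, > 0) and \code{event}
#'   (0/1).
#' @export
simulate_survival <- function(linear_predictor, baseline_rate,
                              censor_max = NULL, seed = NULL) {
  if (any(!is.finite(linear_predictor)))
    stop("linear predictor contains non-finite values")
  if (baseline_rate <= 0) stop("baseline rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(linear_predictor)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(linear_predictor))
  if (is.null(censor_max)) {
    data.frame(time = t_event, event = rep(1L, n))
  } else {
    if (censor_max <= 0) stop("censor_max must be > 0 (or NULL)")
    t_cens <- stats::runif(n, 0, censor_max)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  }
}

## reflective-padding 1D smoothing used by the texture simulator
smooth_gauss3 <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox); k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- pmax(pmin(abs(1:(n + 2 * r) - r - 0.5) + 0.5, n), 1) # reflect/clamp pad
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, n)
    mp <- m[idx, , drop = FALSE]
    sm <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2))
    sm <- sm[(r + 1):(r + n), , drop = FALSE]
    out <- array(sm, dim(ap))
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- conv_axis(a, ax)
  a
}

#' Simulate a textured ellipsoid tumor volume and mask
#'
#' The mask is a discretized ellipsoid centered in the grid; the image is
#' class-specific smoothed Gaussian noise inside and around it (correlated
#' noise emulates texture granularity; no CT physics is modeled).
#'
#' @param radii Length-3 ellipsoid radii in voxels, each >= 2.
#' @param texture Preset name ("constant", "fine", "coarse") or a list
#'   with \code{mean}, \code{sd}, \code{corr} (correlation length,
#'   voxels).
#' @param spacing Voxel spacing (mm).
#' @param margin Background margin in voxels around the ellipsoid.
#' @param seed Integer seed.
#' @return List with \code{image} (\code{image_volume}) and \code{mask}
#'   (binary array).
#' @export
simulate_tumor_volume <- function(radii = c(5, 5, 5), texture = "fine",
                                  spacing = c(1, 1, 1), margin = 3L,
                                  seed = 1L) {
  radii <- as.numeric(radii)
  if (length(radii) != 3L || any(radii < 2))
    stop("ellipsoid radii must be >= 2 voxels on each axis")
  presets <- list(constant = list(mean = -50, sd = 0, corr = 0),
                  fine = list(mean = 0, sd = 30, corr = 0.6),
                  coarse = list(mean = 60, sd = 30, corr = 2.0))
  tx <- if (is.character(texture)) {
    if (!texture %in% names(presets)) stop("unknown texture class: ", texture)
    presets[[texture]]
  } else texture
  set.seed(seed)
  d <- as.integer(2 * ceiling(radii) + 2 * margin + 1)
  if (any(2 * radii + 1 > d))
    stop("radii exceed the simulation grid")
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(a) ((1:d[a]) - ctr[a]) / radii[a])
  E <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- E <= 1
  img <- array(tx$mean, d)
  if (tx$sd > 0) {
    noise <- array(stats::rnorm(prod(d)), d)
    noise <- smooth_gauss3(noise, tx$corr)
    s <- stats::sd(as.vector(noise))
    if (s > 0) noise <- noise / s * tx$sd
    img <- img + noise
  }
  ## mild background offset so the lesion stands out of "parenchyma"
  img[!mask] <- img[!mask] - 200
  list(image = image_volume(img, spacing), mask = mask)
}
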