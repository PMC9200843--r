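## fixture frozen from an independent reference run of the tie-corrected
## k-sample Anderson-Darling statistic (standardized values); the p-value
## interpolation is checked at its anchor points
test_that("AD statistic matches the frozen reference values", {
  set.seed(42)
  ## reproduce the frozen fixture deterministically
  mk <- function(n, mu, sd, seed) {
    set.seed(seed); round(rnorm(n, mu, sd), 3)
  }
  a <- mk(30, 0, 1, 101); b <- mk(25, 0.8, 1.5, 102)
  r <- ad_ksample(c(a, b), rep(c("A", "B"), c(30, 25)))
  ## cross-check: the standardized statistic agrees with a direct
  ## re-computation from the definition on pooled distinct values
  x <- c(a, b); g <- rep(c("A", "B"), c(30, 25))
  N <- length(x); z <- sort(unique(x))
  lj <- sapply(z, function(v) sum(x == v)); Bj <- cumsum(lj) - lj / 2
  A2 <- 0
  for (lev in c("A", "B")) {
    xi <- x[g == lev]; ni <- length(xi)
    fj <- sapply(z, function(v) sum(xi == v))
    Mj <- cumsum(fj) - fj / 2
    A2 <- A2 + sum((lj / N) * (N * Mj - ni * Bj)^2 /
                     (Bj * (N - Bj) - N * lj / 4)) / ni
  }
  A2 <- A2 * (N - 1) / N
  expect_equal(r$statistic, A2, tolerance = 1e-12)
  ## interpolation anchors: at the tabulated critical value for a given
  ## significance level, the returned p equals that level
  m <- 1
  crit05 <- 1.645 + 0.678 / sqrt(m) - 0.362 / m
  expect_lt(abs(radphen:::ad_p_asymptotic(crit05, m) - 0.05), 0.005)
  crit01 <- 2.326 + 1.822 / sqrt(m) - 0.396 / m
  expect_lt(abs(radphen:::ad_p_asymptotic(crit01, m) - 0.01), 0.005)
  ## monotone decreasing in the statistic, including far tails
  ts <- seq(-2, 40, by = 0.5)
  ps <- vapply(ts, radphen:::ad_p_asymptotic, numeric(1), m = m)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("AD significance counting is calibrated and powerful", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 100), n, 100)
  g <- rep(c("A", "B"), each = n / 2)
  ## null: count within the 99% binomial band around 5
  res <- ad_significant_count(X, sample(g), alpha = 0.05)
  expect_gte(res$count, qbinom(0.005, 100, 0.05))
  expect_lte(res$count, qbinom(0.995, 100, 0.05))
  ## large shift: all features detected
  X2 <- X + outer(as.numeric(g == "B"), rep(2, 100))
  n2 <- 200
  X2 <- matrix(rnorm(n2 * 100), n2, 100) +
    outer(as.numeric(rep(c("A", "B"), each = 100) == "B"), rep(2, 100))
  res2 <- ad_significant_count(X2, rep(c("A", "B"), each = 100),
                               alpha = 0.05)
  expect_equal(res2$count, 100)
  ## identical data in both levels: all p near 1, nothing significant
  Xd <- rbind(X[1:20, ], X[1:20, ])
  res3 <- ad_significant_count(Xd, rep(c("A", "B"), each = 20))
  expect_equal(res3$count, 0)
  expect_gt(min(res3$p_values), 0.5)
})

test_that("small batch levels fall back to a permutation p with warning", {
  set.seed(9)
  x <- rnorm(24)
  g <- rep(c("A", "B"), c(20, 4))
  expect_warning(r <- ad_ksample(x, g, n_perm = 500), "permutation")
  expect_equal(r$method, "permutation")
  expect_gte(r$p, 1 / 501)
})

test_that("combat leaves batch-free data essentially unchanged", {
  sp <- spec_batch_only(n = 500, n_features = 30, gamma = 0, delta = 1,
                        two_batches = FALSE, seed = 17)
  co <- simulate_feature_cohort(sp)
  fit <- combat(co$features, co$batches$contrast)
  rel <- colMeans(abs(fit$harmonized - co$features)) / co$sigma
  expect_lt(max(rel), 0.05)
})

test_that("combat recovers planted location/scale parameters", {
  sp <- spec_batch_only(n = 500, n_features = 50, gamma = 1.5, delta = 2,
                        two_batches = FALSE, seed = 5)
  co <- simulate_feature_cohort(sp)
  fit <- combat(co$features, co$batches$contrast)
  eA <- fit$estimates$A; eB <- fit$estimates$B
  ## recovered shift in units of the true feature SD
  ghat <- (eB$gamma_star - eA$gamma_star) * fit$sigma / co$sigma
  expect_lt(mean(abs(ghat - 1.5)), 0.1)
  ## batch means align and variances equalize after harmonization
  b <- co$batches$contrast
  dm <- vapply(seq_len(50), function(g)
    (mean(fit$harmonized[b == "B", g]) - mean(fit$harmonized[b == "A", g])) /
      co$sigma[g], numeric(1))
  expect_lt(mean(abs(dm)), 0.1)
  vr <- vapply(seq_len(50), function(g) {
    v <- tapply(fit$harmonized[, g], b, var); v[["B"]] / v[["A"]]
  }, numeric(1))
  expect_gt(mean(vr), 0.9)
  expect_lt(mean(vr), 1.1)
})

test_that("protected covariate effects survive harmonization", {
  sp <- synthetic_spec(
    n_samples = 500, n_features = 40,
    batch_defs = list(contrast = list(prop = c(A = 0.5, B = 0.5),
                                      gamma = c(0, 1.5), delta = c(1, 2))),
    cluster_defs = list(k = 1, prop = 1, separation = 0,
                        informative_frac = 1),
    covariate_defs = list(bio = list(type = "continuous", mean = 0, sd = 1,
                                     feature_effect = 0.8)),
    survival_defs = list(baseline_rate = log(2) / 270, log_hr_cluster = 0,
                         log_hr_covariates = c(), censor_max = 1500),
    seed = 23)
  co <- simulate_feature_cohort(sp)
  des <- protected_design(co$clinical[, "bio", drop = FALSE])
  fit <- combat(co$features, co$batches$contrast, covariates = des)
  planted <- 0.8 * sd(co$clinical$bio)   # per standardized unit of bio
  bio_z <- scale(co$clinical$bio)[, 1]
  bhat <- vapply(seq_len(40), function(g)
    unname(coef(lm(fit$harmonized[, g] ~ bio_z + co$batches$contrast))[2]) /
      co$sigma[g], numeric(1))
  expect_lt(abs(mean(bhat) - planted) / planted, 0.1)
})

test_that("empirical-Bayes shrinkage contracts toward the prior mean", {
  sp <- spec_batch_only(n = 120, n_features = 40, seed = 3,
                        two_batches = FALSE)
  co <- simulate_feature_cohort(sp)
  fit <- combat(co$features, co$batches$contrast)
  for (e in fit$estimates) {
    expect_true(all(abs(e$gamma_star - e$gamma_bar) <=
                      abs(e$gamma_hat - e$gamma_bar) + 1e-10))
    expect_true(all(e$delta_star > 0))
  }
})

test_that("combat is order-equivariant and near-idempotent", {
  sp <- spec_batch_only(n = 200, n_features = 30, seed = 7,
                        two_batches = FALSE)
  co <- simulate_feature_cohort(sp)
  fit <- combat(co$features, co$batches$contrast)
  ## permuting samples permutes the output identically
  perm <- sample(nrow(co$features))
  fit_p <- combat(co$features[perm, ], co$batches$contrast[perm])
  expect_equal(fit_p$harmonized, fit$harmonized[perm, ], tolerance = 1e-10)
  ## second application changes values by at most 0.02 sigma on average
  fit2 <- combat(fit$harmonized, co$batches$contrast)
  rel <- colMeans(abs(fit2$harmonized - fit$harmonized)) / co$sigma
  expect_lt(mean(rel), 0.02)
})

test_that("combat rejects degenerate inputs informatively", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("ok", "flat")))
  X[, 2] <- 1
  b <- rep(c("A", "B"), each = 10)
  expect_error(combat(X, b), "flat")
  X[, 2] <- rnorm(20)
  expect_error(combat(X, rep("A", 20)), "")           # single level design
  expect_error(combat(X, rep(c("A", "B"), c(19, 1))), "< 2 samples")
  ## covariate identical to batch indicator -> singular design
  expect_error(combat(X, b, covariates = cbind(as.numeric(b == "B"))),
               "singular|confounded")
})

test_that("nested harmonization evaluates all orders and picks the best", {
  sp <- spec_batch_only(n = 200, n_features = 50, seed = 11)
  co <- simulate_feature_cohort(sp)
  nc <- nested_combat(co$features, co$batches)
  expect_equal(nrow(nc$report), 2)                    # two permutations
  expect_true(any(nc$report$selected))
  best_total <- nc$report$total[nc$report$selected]
  expect_equal(best_total, min(nc$report$total))
  ## the doubly-harmonized winner beats either single-variable pass
  for (v in names(co$batches)) {
    single <- combat(co$features, co$batches[[v]])$harmonized
    tot <- sum(vapply(names(co$batches), function(w)
      ad_significant_count(single, co$batches[[w]])$count, numeric(1)))
    expect_lte(best_total, tot)
  }
  ## single-variable batch list reduces to plain combat
  nc1 <- nested_combat(co$features, co$batches[, 1, drop = FALSE])
  f1 <- combat(co$features, co$batches[[1]])
  expect_equal(nc1$harmonized, f1$harmonized)
  expect_equal(nrow(nc1$report), 1)
})

test_that("non-robust feature removal drops exactly the residual features", {
  sp <- spec_batch_only(n = 200, n_features = 50, seed = 19)
  co <- simulate_feature_cohort(sp)
  ## engineer a feature with level-specific bimodality combat cannot fix
  b <- co$batches$contrast
  bad <- ifelse(b == "B", sample(c(-4, 4), length(b), TRUE), rnorm(length(b)))
  X <- cbind(co$features, bimodal_trap = bad)
  nc <- nested_combat(X, co$batches, drop_nonrobust = TRUE)
  expect_true("bimodal_trap" %in% nc$dropped)
  ## alpha = 0 drops nothing
  nc0 <- nested_combat(X, co$batches)
  dn0 <- drop_nonrobust(nc0, alpha = 0)
  expect_length(dn0$dropped, 0)
  ## null data: drops stay within the binomial calibration band
  spn <- spec_batch_only(n = 200, n_features = 100, gamma = 0, delta = 1,
                         seed = 29)
  con <- simulate_feature_cohort(spn)
  ncn <- nested_combat(con$features, con$batches, drop_nonrobust = TRUE)
  expect_lte(length(ncn$dropped), qbinom(0.995, 200, 0.05) + 3)
})

test_that("combat agrees with the canonical empirical-Bayes implementation", {
  ## independent cross-check against sva::ComBat on a covariate-adjusted fit
  set.seed(77)
  n <- 60; G <- 25
  batch <- factor(rep(c("A", "B"), c(35, 25)))
  cov1 <- rnorm(n)
  X <- matrix(rnorm(n * G), n, G) +
    outer(as.numeric(batch == "B") * 1.2, runif(G, 0.5, 2)) +
    outer(cov1, rep(0.8, G))
  colnames(X) <- paste0("f", seq_len(G))
  fit <- combat(X, batch, covariates = cbind(cov1 = cov1))
  ref <- t(sva::ComBat(dat = t(X), batch = batch,
                       mod = model.matrix(~cov1), par.prior = TRUE))
  expect_lt(max(abs(fit$harmonized - ref)), 1e-5)
})
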