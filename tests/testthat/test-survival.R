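test_that("cox fits are unbiased under the null and recover planted effects", {
  set.seed(1)
  n <- 500
  x <- rnorm(n)
  sv <- simulate_survival(rep(0, n), 0.005, censor_max = 600, seed = 2)
  f <- fit_cox(sv$time, sv$event, data.frame(x = x))
  se <- sqrt(diag(vcov(f$model)))
  expect_lt(abs(f$coefficients[["x"]]), 3 * se)

  xb <- rbinom(1000, 1, 0.5)
  svb <- simulate_survival(xb * 1.0, 0.005, censor_max = NULL, seed = 3)
  fb <- fit_cox(svb$time, svb$event, data.frame(x = xb))
  expect_lt(abs(fb$coefficients[["x"]] - 1), 0.15)

  ## duplicating every sample leaves the estimate essentially unchanged
  ## (exact equality is broken only by the Efron correction, since each
  ## event time becomes a tie pair)
  fd <- fit_cox(rep(svb$time, 2), rep(svb$event, 2),
                data.frame(x = rep(xb, 2)))
  expect_equal(fd$coefficients, fb$coefficients, tolerance = 0.005)

  expect_error(fit_cox(c(10, 20, 30), c(1, 0, 0), data.frame(x = 1:3)),
               "2 events")
  ## perfect separation triggers the guidance error
  t2 <- c(1:10, 101:110); e2 <- rep(1, 20); x2 <- rep(c(1, 0), each = 10)
  expect_error(fit_cox(t2, e2, data.frame(x = x2)), "separation")
})

test_that("cross-validated concordance is calibrated", {
  set.seed(4)
  n <- 400
  xnoise <- rnorm(n)
  sv <- simulate_survival(rep(0, n), 0.004, censor_max = 700, seed = 5)
  cv <- cv_concordance(sv$time, sv$event, data.frame(x = xnoise),
                       iterations = 50, seed = 6)
  expect_gte(cv$mean, 0.45)
  expect_lte(cv$mean, 0.55)
  expect_true(all(cv$concordance >= 0 & cv$concordance <= 1))
  expect_true(cv$ci[1] >= min(cv$concordance) &&
                cv$ci[2] <= max(cv$concordance))
  ## determinism
  cv2 <- cv_concordance(sv$time, sv$event, data.frame(x = xnoise),
                        iterations = 50, seed = 6)
  expect_identical(cv$concordance, cv2$concordance)
})

test_that("cv concordance tracks a simulation oracle for a planted effect", {
  set.seed(7)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  sv <- simulate_survival(x * 1.5, 0.005, censor_max = 1200, seed = 8)
  cv <- cv_concordance(sv$time, sv$event, data.frame(x = x),
                       iterations = 50, seed = 9)
  ## oracle: population concordance of the same generative model
  no <- 200000
  xo <- rbinom(no, 1, 0.5)
  svo <- simulate_survival(xo * 1.5, 0.005, censor_max = 1200, seed = 10)
  oracle <- unname(survival::concordance(
    survival::Surv(svo$time, svo$event) ~ xo, reverse = TRUE)$concordance)
  expect_lt(abs(cv$mean - oracle), 0.03)
})

test_that("concordance is invariant to monotone transforms of the score", {
  set.seed(11)
  n <- 200
  score <- rnorm(n)
  sv <- simulate_survival(score, 0.004, censor_max = 900, seed = 12)
  c1 <- radphen:::harrell_c(sv$time, sv$event, score)
  c2 <- radphen:::harrell_c(sv$time, sv$event, exp(3 * score) + 5)
  expect_equal(c1, c2)
})

test_that("median split forms equal groups and the log-rank is invariant", {
  set.seed(13)
  n <- 200
  score <- rnorm(n)
  sv <- simulate_survival(rep(0, n), 0.004, censor_max = 900, seed = 14)
  km <- median_split_km(score, sv$time, sv$event)
  expect_equal(as.integer(km$n_per_group), c(100L, 100L))
  ## affine rescale of scores leaves the test unchanged
  km2 <- median_split_km(10 - 2 * (-score), sv$time, sv$event)
  expect_equal(km$p, km2$p)
  ## ties go to the low group: median value 1 occurs 100 times
  km3 <- median_split_km(rep(c(0, 1, 1, 2), 50), sv$time, sv$event)
  expect_equal(unname(km3$n_per_group[["low"]]), 150)
  expect_error(median_split_km(rep(1, n), sv$time, sv$event), "empty group")
  ## survival curves start at 1 and never increase
  s <- summary(km$fit)
  expect_true(all(s$surv <= 1))
  expect_true(all(diff(km$fit$n.risk[seq_len(km$fit$strata[1])]) <= 0))
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(15)
  pvals <- vapply(1:300, function(r) {
    sv <- simulate_survival(rep(0, 100), 0.004, censor_max = 900,
                            seed = 1000 + r)
    median_split_km(rnorm(100), sv$time, sv$event)$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("median split detects a strong planted hazard ratio", {
  set.seed(16)
  hits <- vapply(1:40, function(r) {
    grp <- rep(c(0, 1), each = 100)
    sv <- simulate_survival(grp * log(3), 0.004, censor_max = 1500,
                            seed = 2000 + r)
    median_split_km(grp + rnorm(200, sd = 1e-3), sv$time, sv$event)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("therapy-stratified analysis partitions the cohort", {
  co <- simulate_feature_cohort(synthetic_spec(n_samples = 160, seed = 18))
  enc <- encode_clinical(co$clinical)
  enc$phenotype <- factor(co$cluster_truth)
  X <- enc[, c("phenotype", "pdl1_cat", "smoking"), drop = FALSE]
  res <- stratified_by_therapy(co$clinical$pfs_days, co$clinical$event, X,
                               co$clinical$therapy, iterations = 10,
                               seed = 19)
  expect_setequal(names(res), levels(co$clinical$therapy))
  expect_equal(sum(vapply(res, `[[`, numeric(1), "n")),
               nrow(co$clinical))
  ## a single stratum reproduces the unstratified analysis
  res1 <- stratified_by_therapy(co$clinical$pfs_days, co$clinical$event, X,
                                rep("all", 160), iterations = 10, seed = 19)
  cv_all <- cv_concordance(co$clinical$pfs_days, co$clinical$event, X,
                           iterations = 10, seed = 19)
  expect_equal(res1$all$cv$mean, cv_all$mean)
  expect_warning(
    stratified_by_therapy(co$clinical$pfs_days, co$clinical$event, X,
                          rep(c("big", "tiny"), c(155, 5)),
                          iterations = 5, seed = 20),
    "too small")
})

test_that("chi-square association matches hand computation", {
  ## balanced 2x2: no association
  a <- chi_square_assoc(rep(c(1, 2), each = 20),
                        rep(c("x", "y"), 20))
  expect_equal(a$statistic, 0)
  expect_equal(a$p, 1)
  ## [[20,5],[5,20]]: sum (O-E)^2/E = 18 with E = 12.5 everywhere
  b <- chi_square_assoc(rep(c(1, 2), c(25, 25)),
                        rep(c("a", "b", "a", "b"), c(20, 5, 5, 20)))
  expect_equal(b$statistic, 18)
  expect_equal(b$df, 1)
  expect_lt(b$p, 0.001)
  ## null calibration
  set.seed(21)
  pv <- vapply(1:500, function(r)
    chi_square_assoc(sample(rep(1:2, 50)), sample(rep(c("a", "b"), 50)))$p,
    numeric(1))
  expect_gt(mean(pv > 0.05), 0.9)
  ## an empty category level yields a zero expected count
  expect_error(
    chi_square_assoc(factor(c(1, 1, 2, 2)),
                     factor(c("a", "a", "a", "a"), levels = c("a", "b"))),
    "merge")
})

test_that("phenotype-based PD-L1 prediction hits the closed-form AUC", {
  ## phenotype identical to the class: AUC 1
  y <- rep(c("low", "high"), each = 100)
  r1 <- phenotype_predicts_pdl1(factor(y), factor(y), seed = 1)
  expect_equal(r1$holdout_auc, 1)
  ## independent phenotype: chance level
  set.seed(2)
  r2 <- phenotype_predicts_pdl1(factor(sample(1:2, 200, TRUE)),
                                factor(sample(c("low", "high"), 200, TRUE)),
                                seed = 3)
  expect_gte(r2$holdout_auc, 0.3)
  expect_lte(r2$holdout_auc, 0.7)
  ## 70/30 vs 30/70 mixing: two-point ROC gives AUC 0.70 exactly
  ph <- c(rep(1, 140), rep(2, 60), rep(1, 60), rep(2, 140))
  y3 <- factor(rep(c("high", "low"), each = 200), c("low", "high"))
  r3 <- phenotype_predicts_pdl1(factor(ph), y3, seed = 4)
  expect_lt(abs(r3$holdout_auc - 0.70), 0.08)
  expect_lt(abs(r3$cv_auc - 0.70), 0.08)
})
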