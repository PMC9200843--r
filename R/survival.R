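## Prognostic modeling: Cox proportional hazards (Efron ties) with
## repeated cross-validated Harrell concordance, Kaplan-Meier median-risk
## stratification with the log-rank test, therapy-line stratified
## analysis, and phenotype-covariate association tests.

DAYS_PER_MONTH <- 30.44

#' Encode a clinical covariate table for modeling
#'
#' Categorizes the standard clinical prognostic factors the way cohort
#' tables report them: PD-L1 expression into < 10% / 10-50% / >= 50%, BMI
#' into underweight/normal/overweight/obese, ECOG 0-3 and smoking status
#' as factors. Continuous columns are left numeric. Reference level =
#' first category listed.
#'
#' @param clinical data.frame with any of \code{pdl1_pct}, \code{bmi},
#'   \code{ecog}, \code{smoking} plus other columns.
#' @return data.frame of encoded covariates (factors/numerics).
#' @export
encode_clinical <- function(clinical) {
  out <- clinical
  if ("pdl1_pct" %in% names(out))
    out$pdl1_cat <- cut(out$pdl1_pct, c(-Inf, 10, 50, Inf),
                        labels = c("lt10", "10to50", "ge50"), right = FALSE)
  if ("bmi" %in% names(out) && is.numeric(out$bmi))
    out$bmi_cat <- cut(out$bmi, c(-Inf, 18.5, 25, 30, Inf),
                       labels = c("underweight", "normal", "overweight",
                                  "obese"), right = FALSE)
  if ("ecog" %in% names(out)) out$ecog <- factor(out$ecog)
  if ("smoking" %in% names(out)) out$smoking <- factor(out$smoking)
  out
}

model_design <- function(data, predictors) {
  missing_p <- setdiff(predictors, colnames(data))
  if (length(missing_p))
    stop("predictors not found: ", paste(missing_p, collapse = ", "))
  f <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  X <- stats::model.matrix(f, data = data)[, -1, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("model design is rank deficient")
  X
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times; returns coefficients and per-sample risk scores (linear
#' predictor).
#'
#' @param time Survival times (> 0).
#' @param event Event indicators (0/1), >= 2 events.
#' @param X Numeric design matrix (samples x predictors) or data.frame of
#'   predictors.
#' @return List: \code{coefficients}, \code{linear_predictor},
#'   \code{model} (the \code{coxph} fit).
#' @export
fit_cox <- function(time, event, X) {
  if (sum(event) < 2L) stop("need at least 2 events")
  X <- as.matrix(stats::model.matrix(~., data = as.data.frame(X))[, -1,
                                                                  drop = FALSE])
  ## the "coefficient may be infinite" warning is the separation signal we
  ## convert to an informative error below
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20))
    stop("monotone partial likelihood (perfect separation); ",
         "merge sparse categories or drop the offending predictor")
  names(beta) <- colnames(X)
  list(coefficients = beta,
       linear_predictor = drop(X %*% beta),
       model = fit)
}

## tolerant fit for cross-validation folds: sparse categories can give a
## monotone partial likelihood in a training split, which only means a few
## held-out samples get an extreme score; coefficients that did not
## converge (NA, e.g. a level absent from the split) contribute 0
cox_coef_lenient <- function(time, event, Xm) {
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ Xm, ties = "efron"))
  beta <- stats::coef(fit)
  beta[!is.finite(beta)] <- 0
  unname(beta)
}

harrell_c <- function(time, event, score) {
  cf <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  unname(cf$concordance)
}

#' Repeated cross-validated Cox concordance
#'
#' Per iteration: samples are shuffled into \code{folds} folds, a Cox
#' model is fitted on the training folds, held-out risk scores are pooled
#' over folds, and one Harrell concordance is computed on the pooled
#' out-of-fold scores. Reports the mean and percentile 95% CI over
#' iterations.
#'
#' @param time,event Survival outcome.
#' @param X Design matrix or data.frame of predictors.
#' @param folds Number of folds (default 5).
#' @param iterations Number of shuffles (default 200).
#' @param seed Integer seed.
#' @return Object of class \code{cox_cv}: \code{concordance} (per
#'   iteration), \code{mean}, \code{ci} (2.5/97.5 percentiles),
#'   \code{folds}, \code{iterations}, \code{seed}.
#' @export
cv_concordance <- function(time, event, X, folds = 5L, iterations = 200L,
                           seed = 1L) {
  X <- as.data.frame(X)
  ## fixed design over the full cohort so factor encodings are stable
  ## across folds
  Xm <- stats::model.matrix(~., data = X)[, -1, drop = FALSE]
  n <- length(time)
  set.seed(seed)
  cvec <- numeric(iterations)
  for (it in seq_len(iterations)) {
    ok <- FALSE
    for (attempt in 1:10) {
      fold <- sample(rep(seq_len(folds), length.out = n))
      ev_per_train <- vapply(seq_len(folds), function(f)
        sum(event[fold != f]), numeric(1))
      if (all(ev_per_train >= 2)) { ok <- TRUE; break }
      message("cv_concordance: fold without enough events, resampling folds")
    }
    if (!ok) stop("could not build folds with >= 2 training events each")
    score <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      beta <- cox_coef_lenient(time[tr], event[tr], Xm[tr, , drop = FALSE])
      score[!tr] <- drop(Xm[!tr, , drop = FALSE] %*% beta)
    }
    cvec[it] <- harrell_c(time, event, score)
  }
  structure(list(concordance = cvec, mean = mean(cvec),
                 ci = unname(stats::quantile(cvec, c(0.025, 0.975))),
                 folds = folds, iterations = iterations, seed = seed),
            class = "cox_cv")
}

#' @export
print.cox_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated Cox concordance, %d iterations:\n",
              x$folds, x$iterations))
  cat(sprintf("  c = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Kaplan-Meier curves split at the median risk score
#'
#' Splits the cohort at the median prognostic score (ties go to the
#' low-score group), fits Kaplan-Meier curves per group and tests their
#' separation with the log-rank test (1 df).
#'
#' @param score Per-sample risk scores (higher = higher risk).
#' @param time,event Survival outcome, n >= 4.
#' @return Object of class \code{km_result}: \code{fit} (survfit),
#'   \code{group}, \code{chisq}, \code{p}, \code{n_per_group}.
#' @export
median_split_km <- function(score, time, event) {
  n <- length(score)
  if (n < 4L) stop("need at least 4 samples")
  med <- stats::median(score)
  group <- factor(ifelse(score <= med, "low", "high"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L)) {
    ## coarse scores whose majority value sits above the median empty the
    ## high group under ties-to-low; flipping the ties is then the only
    ## non-empty split at the median
    group <- factor(ifelse(score < med, "low", "high"),
                    levels = c("low", "high"))
    if (any(table(group) == 0L))
      stop("median split produced an empty group (all scores identical?)")
  }
  sv <- survival::Surv(time, event)
  fit <- survival::survfit(sv ~ group)
  lr <- survival::survdiff(sv ~ group)
  p <- stats::pchisq(lr$chisq, df = 1L, lower.tail = FALSE)
  structure(list(fit = fit, group = group, chisq = unname(lr$chisq), p = p,
                 n_per_group = table(group)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("median-split Kaplan-Meier: n = %s, log-rank chi-square = %.3f, p = %.4g\n",
              paste(x$n_per_group, collapse = "/"), x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_result <- function(x, xlab = "days", ylab = "progression-free survival",
                           col = c("steelblue", "firebrick"), ...) {
  graphics::plot(x$fit, col = col, xlab = xlab, ylab = ylab, ...)
  graphics::legend("topright", legend = levels(x$group), col = col,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Stratified survival analysis by line of therapy
#'
#' Runs the cross-validated Cox model and the median-split Kaplan-Meier
#' analysis separately within each stratum (e.g. monotherapy vs
#' combination therapy). Strata too small for the downstream
#' preconditions are skipped with a warning.
#'
#' @param time,event Survival outcome.
#' @param X Predictor data.frame.
#' @param strata Factor of stratum labels.
#' @param folds,iterations,seed Passed to \code{\link{cv_concordance}}.
#' @param min_n Minimum stratum size (default 10).
#' @return Named list per stratum: \code{cv} (\code{cox_cv}) and \code{km}
#'   (\code{km_result}).
#' @export
stratified_by_therapy <- function(time, event, X, strata, folds = 5L,
                                  iterations = 200L, seed = 1L,
                                  min_n = 10L) {
  strata <- droplevels(as.factor(strata))
  X <- as.data.frame(X)
  out <- list()
  for (s in levels(strata)) {
    sel <- strata == s
    if (sum(sel) < min_n || sum(event[sel]) < 2L) {
      warning("stratum '", s, "' too small (n = ", sum(sel), "); skipped")
      next
    }
    cv <- cv_concordance(time[sel], event[sel], X[sel, , drop = FALSE],
                         folds = folds, iterations = iterations,
                         seed = seed)
    Xm <- stats::model.matrix(~., data = X)[, -1, drop = FALSE]
    beta <- cox_coef_lenient(time[sel], event[sel], Xm[sel, , drop = FALSE])
    km <- median_split_km(drop(Xm[sel, , drop = FALSE] %*% beta),
                          time[sel], event[sel])
    out[[s]] <- list(cv = cv, km = km, n = sum(sel))
  }
  out
}

#' Chi-square association between phenotype and a categorical covariate
#'
#' Pearson chi-square test of independence (no continuity correction) on
#' the phenotype x category contingency table.
#'
#' @param phenotype Cluster labels.
#' @param covariate Categorical covariate.
#' @return List: \code{statistic}, \code{df}, \code{p}, \code{table}.
#' @export
chi_square_assoc <- function(phenotype, covariate) {
  tab <- table(phenotype, covariate)
  if (any(dim(tab) < 2L))
    stop("need at least two categories per margin; ",
         "merge sparse categories before testing")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("expected count of zero; merge sparse categories before testing")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Predict PD-L1 class from the radiomic phenotype
#'
#' Random-forest classifier with the phenotype label as the sole
#' predictor; reports the fivefold cross-validated AUC within the
#' training split (70% by default, stratified) and the held-out AUC.
#'
#' @param phenotype Cluster labels.
#' @param pdl1 Numeric PD-L1 percentages or a binary class; numeric
#'   values are binarized at \code{threshold}.
#' @param threshold PD-L1-high threshold (default 50).
#' @param split Training fraction (default 0.7).
#' @param folds CV folds within the training set (default 5).
#' @param seed Integer seed.
#' @param ntree Random-forest size (default 500).
#' @return List: \code{cv_auc}, \code{holdout_auc}, \code{class_table}.
#' @export
phenotype_predicts_pdl1 <- function(phenotype, pdl1, threshold = 50,
                                    split = 0.7, folds = 5L, seed = 1L,
                                    ntree = 500L) {
  y <- if (is.numeric(pdl1) && length(unique(pdl1)) > 2L)
    factor(ifelse(pdl1 >= threshold, "high", "low"), c("low", "high"))
  else factor(pdl1)
  if (nlevels(y) != 2L) stop("PD-L1 outcome must be binary")
  ph <- factor(phenotype)
  set.seed(seed)
  n <- length(y)
  for (attempt in 1:20) {
    ## stratified split
    tr <- logical(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      tr[sample(idx, max(1L, round(split * length(idx))))] <- TRUE
    }
    if (nlevels(droplevels(y[tr])) == 2L &&
        nlevels(droplevels(y[!tr])) == 2L) break
    message("phenotype_predicts_pdl1: single-class split, re-drawing")
  }
  rf_auc <- function(train_idx, test_idx) {
    df_tr <- data.frame(ph = ph[train_idx], y = y[train_idx])
    rf <- randomForest::randomForest(y ~ ph, data = df_tr, ntree = ntree)
    pr <- stats::predict(rf, newdata = data.frame(ph = ph[test_idx]),
                         type = "prob")[, "high"]
    as.numeric(pROC::auc(pROC::roc(response = y[test_idx], predictor = pr,
                                   levels = c("low", "high"),
                                   direction = "<", quiet = TRUE)))
  }
  tr_idx <- which(tr)
  fold <- sample(rep(seq_len(folds), length.out = length(tr_idx)))
  cv_aucs <- vapply(seq_len(folds), function(f) {
    rf_auc(tr_idx[fold != f], tr_idx[fold == f])
  }, numeric(1))
  holdout <- rf_auc(tr_idx, which(!tr))
  list(cv_auc = mean(cv_aucs, na.rm = TRUE), holdout_auc = holdout,
       class_table = table(ph, y))
}
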