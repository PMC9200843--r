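## End-to-end orchestration: simulate (or read) -> harmonize -> cluster ->
## survival models -> report, with provenance.

VALID_MODELS <- c("volume", "phenotype", "clinical", "volume+clinical",
                  "phenotype+clinical")

#' Pipeline configuration
#'
#' One global seed fans out to per-stage seeds by fixed offsets, so a
#' single knob reproduces the whole run.
#'
#' @param input_dir Directory with the cohort CSV trio; NULL simulates one.
#' @param out_dir Output directory.
#' @param spec A \code{\link{synthetic_spec}} used when simulating
#'   (its seed is overridden by the global seed).
#' @param n_levels Gray levels for extraction when images are processed.
#' @param alpha AD significance level for harmonization scoring.
#' @param protect_outcome Protect PFS time and event during harmonization
#'   (default TRUE; set FALSE to avoid outcome leakage into features).
#' @param k_range Candidate phenotype numbers.
#' @param n_resamples Consensus resamples.
#' @param subsample_frac Consensus subsample fraction.
#' @param n_sim SigClust null simulations.
#' @param folds,iterations Cox cross-validation settings.
#' @param models Model menu; subset of
#'   volume, phenotype, clinical, volume+clinical, phenotype+clinical.
#' @param seed Global integer seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = "radphen_out",
                            spec = synthetic_spec(),
                            n_levels = 32L, alpha = 0.05,
                            protect_outcome = TRUE,
                            k_range = 2:6, n_resamples = 200L,
                            subsample_frac = 0.8, n_sim = 1000L,
                            folds = 5L, iterations = 200L,
                            models = VALID_MODELS, seed = 1L) {
  bad <- setdiff(models, VALID_MODELS)
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(VALID_MODELS, collapse = ", "))
  stopifnot(alpha > 0, alpha < 1, folds >= 2, iterations >= 1,
            n_resamples >= 2, n_sim >= 100)
  cfg <- as.list(environment())
  cfg$bad <- NULL
  structure(cfg, class = "pipeline_config")
}

stage_msg <- function(stage, t0) {
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

model_predictors <- function(model, clinical_vars) {
  clin <- clinical_vars
  switch(model,
         "volume" = "tumor_volume_cm3",
         "phenotype" = "phenotype",
         "clinical" = clin,
         "volume+clinical" = c("tumor_volume_cm3", clin),
         "phenotype+clinical" = c("phenotype", clin))
}

#' Run the full pipeline
#'
#' Executes simulate/load, nested ComBat harmonization with non-robust
#' feature removal, consensus + SigClust phenotype discovery, the Cox /
#' Kaplan-Meier model menu, association tests, and writes all artifacts
#' plus a provenance record into the output directory. Idempotent for a
#' fixed seed.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The output directory, invisibly; artifacts:
#'   \code{features.csv}, \code{clinical.csv}, \code{batches.csv},
#'   \code{harmonized_features.csv}, \code{harmonization_report.json},
#'   \code{phenotypes.csv}, \code{consensus.json}, \code{models.csv},
#'   \code{stats.json}, \code{provenance.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  counts <- list()

  ## ---- cohort ----
  t0 <- as.numeric(Sys.time())
  if (is.null(config$input_dir)) {
    spec <- config$spec
    spec$seed <- seed + 1L
    cohort <- simulate_feature_cohort(spec)
    write_cohort(cohort, out)
    src <- "simulated"
  } else {
    for (f in c("features.csv", "clinical.csv", "batches.csv"))
      file.copy(file.path(config$input_dir, f), file.path(out, f),
                overwrite = TRUE)
    src <- config$input_dir
  }
  data <- read_cohort(out)
  counts$n_samples <- nrow(data$features)
  counts$n_features <- ncol(data$features)
  stage_msg("cohort", t0)

  ## ---- harmonization ----
  t0 <- as.numeric(Sys.time())
  clin <- data$clinical
  prot <- clin[, intersect(c("age", "sex", "race", "pdl1_pct", "ecog",
                             "bmi", "smoking", "event"), names(clin)),
               drop = FALSE]
  if ("pfs_days" %in% names(clin))
    prot$pfs_months <- clin$pfs_days / DAYS_PER_MONTH
  design <- protected_design(prot, protect_outcome = config$protect_outcome)
  nc <- nested_combat(data$features, data$batches, covariates = design,
                      alpha = config$alpha, drop_nonrobust = TRUE)
  utils::write.csv(cbind(data.frame(sample_id = data$sample_id),
                         as.data.frame(nc$harmonized)),
                   file.path(out, "harmonized_features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(permutations = nc$report$permutation,
         counts = nc$report[, setdiff(names(nc$report), "permutation")],
         selected = paste(nc$selected, collapse = " -> "),
         dropped = nc$dropped, alpha = config$alpha),
    file.path(out, "harmonization_report.json"), auto_unbox = TRUE,
    digits = NA)
  counts$n_robust_features <- ncol(nc$harmonized)
  counts$n_dropped <- length(nc$dropped)
  stage_msg("harmonize", t0)

  ## ---- phenotyping ----
  t0 <- as.numeric(Sys.time())
  cons <- consensus_cluster(nc$harmonized, k_range = config$k_range,
                            n_resamples = config$n_resamples,
                            frac = config$subsample_frac, seed = seed + 3L)
  sel <- select_k(cons, nc$harmonized, alpha = 0.05,
                  n_sim = config$n_sim, seed = seed + 4L)
  phen <- sel$assignment
  utils::write.csv(data.frame(sample_id = data$sample_id,
                              phenotype = phen),
                   file.path(out, "phenotypes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k_range = config$k_range,
         auc = vapply(config$k_range, function(k)
           cons$per_k[[as.character(k)]]$auc, numeric(1)),
         selected_k = sel$k, no_structure = sel$no_structure,
         split_p = sel$splits),
    file.path(out, "consensus.json"), auto_unbox = TRUE, digits = NA)
  counts$selected_k <- sel$k
  counts$phenotype_sizes <- as.integer(table(phen))
  stage_msg("cluster", t0)

  ## ---- survival models ----
  t0 <- as.numeric(Sys.time())
  enc <- encode_clinical(clin)
  enc$phenotype <- factor(phen)
  clin_vars <- intersect(c("pdl1_cat", "ecog", "bmi_cat", "smoking"),
                         names(enc))
  time <- clin$pfs_days; event <- clin$event
  rows <- list(); km_stats <- list()
  for (mname in config$models) {
    preds <- model_predictors(mname, clin_vars)
    Xp <- enc[, preds, drop = FALSE]
    cv <- cv_concordance(time, event, Xp, folds = config$folds,
                         iterations = config$iterations, seed = seed + 5L)
    Xm <- stats::model.matrix(~., data = Xp)[, -1, drop = FALSE]
    beta <- cox_coef_lenient(time, event, Xm)
    km <- median_split_km(drop(Xm %*% beta), time, event)
    rows[[mname]] <- data.frame(model = mname, mean_c = cv$mean,
                                ci_low = cv$ci[1], ci_high = cv$ci[2],
                                logrank_chisq = km$chisq,
                                logrank_p = km$p)
    km_stats[[mname]] <- list(logrank_p = km$p,
                              groups = as.integer(km$n_per_group))
  }
  models_df <- do.call(rbind, rows)
  utils::write.csv(models_df, file.path(out, "models.csv"),
                   row.names = FALSE)

  stats <- list(km = km_stats)
  assoc_vars <- intersect(c("pdl1_cat", "ecog", "bmi_cat", "smoking"),
                          names(enc))
  stats$chi_square <- lapply(assoc_vars, function(v) {
    a <- chi_square_assoc(phen, enc[[v]])
    list(variable = v, statistic = a$statistic, df = a$df, p = a$p)
  })
  if ("pdl1_pct" %in% names(clin)) {
    pd <- tryCatch(phenotype_predicts_pdl1(phen, clin$pdl1_pct,
                                           seed = seed + 6L),
                   error = function(e) NULL)
    if (!is.null(pd))
      stats$pdl1_prediction <- list(cv_auc = pd$cv_auc,
                                    holdout_auc = pd$holdout_auc)
  }
  if ("therapy" %in% names(clin) &&
      "phenotype+clinical" %in% config$models) {
    Xp <- enc[, model_predictors("phenotype+clinical", clin_vars),
              drop = FALSE]
    strat <- withCallingHandlers(
      stratified_by_therapy(time, event, Xp, clin$therapy,
                            folds = config$folds,
                            iterations = config$iterations,
                            seed = seed + 7L),
      warning = function(w) invokeRestart("muffleWarning"))
    stats$by_therapy <- lapply(strat, function(s)
      list(n = s$n, mean_c = s$cv$mean, logrank_p = s$km$p))
  }
  jsonlite::write_json(stats, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_msg("survive", t0)

  ## ---- provenance ----
  cfg <- config
  cfg$spec <- unclass(cfg$spec)
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "spec")],
                               auto_unbox = TRUE, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("radphen")),
         r_version = as.character(getRversion()),
         seed = seed, source = src, config = jsonlite::fromJSON(cfg_json),
         config_md5 = unname(tools::md5sum(tf)), counts = counts,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)
  unlink(tf)
  invisible(out)
}
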