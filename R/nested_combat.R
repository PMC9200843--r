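## Nested multi-batch harmonization: every ordering of the batch variables
## is applied sequentially (each step a full ComBat fit starting from the
## previous step's output), the result of each ordering is scored by the
## total number of features still batch-associated under the k-sample
## Anderson-Darling test, and the minimizing ordering is kept.

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Nested ComBat harmonization over multiple batch variables
#'
#' @param features Samples x features numeric matrix (or data.frame).
#' @param batches data.frame of batch variables (factors), one column per
#'   batch effect; the supplied column order breaks score ties.
#' @param covariates Optional protected-covariate design matrix (see
#'   \code{\link{protected_design}}).
#' @param alpha Significance level for the AD scoring (default 0.05).
#' @param drop_nonrobust Logical: remove features still AD-significant for
#'   any batch variable after harmonization (default FALSE; see
#'   \code{\link{drop_nonrobust}}).
#' @param ... Passed to \code{\link{combat}}.
#' @return Object of class \code{nested_combat}: \code{harmonized}
#'   (selected feature set), \code{report} (per-permutation per-variable
#'   significant counts and totals), \code{selected} (ordering),
#'   \code{fits} (combat_fit per step of the selected ordering),
#'   \code{p_values} (per batch variable, selected set), \code{alpha}.
#' @export
nested_combat <- function(features, batches, covariates = NULL,
                          alpha = 0.05, drop_nonrobust = FALSE, ...) {
  X <- as.matrix(features)
  batches <- as.data.frame(batches)
  if (ncol(batches) < 1L) stop("need at least one batch variable")
  vars <- colnames(batches)
  perms <- all_permutations(vars)
  results <- vector("list", length(perms))
  for (pi in seq_along(perms)) {
    ord <- perms[[pi]]
    cur <- X
    fits <- list()
    res <- tryCatch({
      for (v in ord) {
        f <- combat(cur, batches[[v]], covariates = covariates, ...)
        cur <- f$harmonized
        fits[[v]] <- f
      }
      ad <- lapply(vars, function(v)
        ad_significant_count(cur, batches[[v]], alpha = alpha))
      names(ad) <- vars
      list(order = ord, harmonized = cur, fits = fits, ad = ad,
           counts = vapply(ad, `[[`, numeric(1), "count"))
    }, error = function(e)
      stop(sprintf("permutation [%s], step %s", paste(ord, collapse = " -> "),
                   conditionMessage(e)), call. = FALSE))
    results[[pi]] <- res
  }
  totals <- vapply(results, function(r) sum(r$counts), numeric(1))
  best <- which(totals == min(totals))[1]  # ties: first enumerated order,
                                           # which starts with the supplied one
  sel <- results[[best]]
  report <- data.frame(
    permutation = vapply(perms, paste, character(1), collapse = " -> "),
    do.call(rbind, lapply(results, function(r) as.data.frame(t(r$counts)))),
    total = totals, selected = seq_along(perms) == best)
  out <- structure(list(harmonized = sel$harmonized, report = report,
                        selected = sel$order, fits = sel$fits,
                        p_values = lapply(sel$ad, `[[`, "p_values"),
                        alpha = alpha, dropped = character(0)),
                   class = "nested_combat")
  if (drop_nonrobust) {
    dn <- drop_nonrobust(out)
    out$harmonized <- dn$harmonized
    out$dropped <- dn$dropped
  }
  out
}

#' @export
print.nested_combat <- function(x, ...) {
  cat("nested_combat:", ncol(x$harmonized), "features retained;",
      "selected order:", paste(x$selected, collapse = " -> "), "\n")
  print(x$report, row.names = FALSE)
  if (length(x$dropped))
    cat("dropped non-robust features:", length(x$dropped), "\n")
  invisible(x)
}

#' Remove features still batch-associated after harmonization
#'
#' A feature is non-robust if its AD p-value is below \code{alpha} for any
#' batch variable on the harmonized set.
#'
#' @param fit A \code{nested_combat} object.
#' @param alpha Significance level; defaults to the fit's alpha.
#' @return List: \code{harmonized} (reduced matrix), \code{dropped}
#'   (feature names).
#' @export
drop_nonrobust <- function(fit, alpha = fit$alpha) {
  stopifnot(inherits(fit, "nested_combat"))
  pmat <- do.call(cbind, fit$p_values)
  bad <- apply(pmat < alpha, 1L, any)
  if (all(bad))
    stop("all features non-robust after harmonization; pipeline cannot continue")
  list(harmonized = fit$harmonized[, !bad, drop = FALSE],
       dropped = colnames(fit$harmonized)[bad])
}
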