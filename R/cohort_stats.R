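#' Cohort association models
#'
#' Baseline gait variables are associated with clinical outcomes at the
#' cohort level: univariate ordinary least squares for the POMA gait and
#' balance sub-scores, and Poisson regression with a log exposure offset for
#' prospective fall counts (so coefficients describe fall *rates*, not raw
#' counts, regardless of how long each participant was observed). A
#' multivariate Poisson model is assembled from the univariately significant
#' features after pruning collinear pairs.
#'
#' Fitted models are wrapped in a lightweight `gait_regression` object with
#' [tidy()] and [glance()] methods.
#'
#' @name cohort-stats
NULL

new_gait_regression <- function(fit, model_type, outcome, predictors, n,
                                converged = TRUE, note = NULL) {
  structure(
    list(fit = fit, model_type = model_type, outcome = outcome,
         predictors = predictors, n = n, converged = converged, note = note),
    class = "gait_regression"
  )
}

complete_records <- function(records, vars) {
  records[complete.cases(records[, vars, drop = FALSE]), , drop = FALSE]
}

#' Univariate linear regression of an outcome score on one gait feature
#'
#' @param records Participant table with baseline features and outcomes.
#' @param feature Feature column name (see [gait_feature_names()]).
#' @param outcome Outcome column, `"poma_gait"` or `"poma_balance"`.
#' @return A `gait_regression` (OLS fit with intercept; two-sided p-value
#'   for the slope).
#' @export
univariate_linear <- function(records, feature,
                              outcome = c("poma_gait", "poma_balance")) {
  outcome <- match.arg(outcome)
  df <- complete_records(records, c(feature, outcome))
  if (nrow(df) < 3L) abort("Need at least 3 complete records.")
  if (sd(df[[feature]]) == 0) {
    abort(paste0("Feature '", feature, "' has zero variance; degenerate design."),
          class = "gaitvision_degenerate")
  }
  fit <- lm(stats::reformulate(feature, outcome), data = df)
  new_gait_regression(fit, "linear", outcome, feature, nrow(df))
}

#' Univariate Poisson regression of fall counts on one gait feature
#'
#' Log-link Poisson model of `n_falls` with `log(exposure_days)` as an
#' offset; the Wald z test gives the coefficient's two-sided p-value.
#'
#' @inheritParams univariate_linear
#' @param feature Feature column name, or `NULL` for the intercept-only
#'   (null) rate model.
#' @return A `gait_regression`. Non-convergence is recorded on the object
#'   (`converged = FALSE`) and warned about, never silently dropped.
#' @export
univariate_poisson <- function(records, feature) {
  vars <- c(feature, "n_falls", "exposure_days")
  df <- complete_records(records, vars)
  if (nrow(df) < 3L) abort("Need at least 3 complete records.")
  rhs <- if (is.null(feature)) "1" else feature
  if (!is.null(feature) && sd(df[[feature]]) == 0) {
    abort(paste0("Feature '", feature, "' has zero variance; degenerate design."),
          class = "gaitvision_degenerate")
  }
  fml <- stats::as.formula(paste("n_falls ~", rhs, "+ offset(log(exposure_days))"))
  fit <- glm(fml, family = poisson(), data = df)
  if (!fit$converged) {
    warn(paste0("Poisson fit for '", rhs, "' did not converge."))
  }
  new_gait_regression(fit, "poisson", "n_falls",
                      if (is.null(feature)) character() else feature,
                      nrow(df), converged = fit$converged)
}

#' Deviance pseudo-R-squared of a Poisson model
#'
#' `R2 = 1 - deviance / null deviance`, where the null model is intercept
#' plus offset; the adjusted value applies the predictor-count penalty
#' `1 - (1 - R2) * (n - 1) / (n - k - 1)` with `k` predictors.
#'
#' @param fit A fitted `glm` (Poisson) or a `gait_regression` wrapping one.
#' @return A list with `r2` and `adjusted_r2` (`NA` with zero null
#'   deviance).
#' @export
pseudo_r2 <- function(fit) {
  if (inherits(fit, "gait_regression")) fit <- fit$fit
  if (fit$null.deviance <= .Machine$double.eps) {
    warn("Null deviance is zero; pseudo-R2 undefined.")
    return(list(r2 = NA_real_, adjusted_r2 = NA_real_))
  }
  r2 <- 1 - fit$deviance / fit$null.deviance
  n <- length(fit$y)
  k <- length(coef(fit)) - 1L
  adj <- if (n - k - 1L > 0L) 1 - (1 - r2) * (n - 1L) / (n - k - 1L) else NA_real_
  list(r2 = r2, adjusted_r2 = adj)
}

#' Multivariate Poisson fall model from univariate screening
#'
#' Implements the model-building rule used for the fall-count analysis:
#' keep the features univariately significant at `alpha`; among any pair
#' whose baseline values correlate with `|r|` above `collinearity_r`, keep
#' only the one with the higher univariate deviance pseudo-R-squared; fit
#' the multivariate Poisson model (with exposure offset) on the survivors.
#'
#' @inheritParams univariate_linear
#' @param univariate Optional named list of univariate `gait_regression`
#'   results (one per feature); computed when `NULL`.
#' @param features Candidate feature set (default all seven).
#' @param alpha Significance level for inclusion (default 0.05).
#' @param collinearity_r Absolute Pearson correlation above which two
#'   features are treated as redundant (default 0.8).
#' @return A `gait_regression` whose `predictors` are the selected features
#'   (empty, with an intercept-only fit and a note, when nothing is
#'   significant) and with `selection` metadata attached
#'   (`significant`, `dropped_collinear`).
#' @export
build_multivariate <- function(records, univariate = NULL,
                               features = gait_feature_names(),
                               alpha = 0.05, collinearity_r = 0.8) {
  if (is.null(univariate)) {
    univariate <- purrr::map(setNames(features, features),
                             ~ univariate_poisson(records, .x))
  }
  pvals <- purrr::map_dbl(univariate, function(m) {
    td <- tidy(m)
    td$p.value[td$term != "(Intercept)"][1]
  })
  r2s <- purrr::map_dbl(univariate, ~ pseudo_r2(.x)$r2)
  significant <- names(pvals)[!is.na(pvals) & pvals < alpha]

  dropped <- character()
  if (length(significant) > 1L) {
    # strongest-association-first greedy pruning of collinear pairs
    order_by_r2 <- significant[order(r2s[significant], decreasing = TRUE)]
    kept <- character()
    cors <- cor(records[, significant, drop = FALSE],
                use = "pairwise.complete.obs")
    for (f in order_by_r2) {
      if (length(kept) && any(abs(cors[f, kept]) > collinearity_r)) {
        dropped <- c(dropped, f)
      } else {
        kept <- c(kept, f)
      }
    }
    selected <- significant[significant %in% kept]
  } else {
    selected <- significant
  }

  df <- complete_records(records, c(selected, "n_falls", "exposure_days"))
  rhs <- if (length(selected)) paste(selected, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("n_falls ~", rhs, "+ offset(log(exposure_days))"))
  fit <- glm(fml, family = poisson(), data = df)
  note <- if (!length(selected)) {
    "No feature was univariately significant; intercept-only model reported."
  }
  out <- new_gait_regression(fit, "poisson", "n_falls", selected, nrow(df),
                             converged = fit$converged, note = note)
  out$selection <- list(significant = significant, dropped_collinear = dropped,
                        univariate_p = pvals, univariate_r2 = r2s)
  out
}

#' @export
tidy.gait_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  stat_col <- if (x$model_type == "linear") "t value" else "z value"
  p_col <- grep("^Pr", colnames(sm), value = TRUE)[1]
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, stat_col]),
    p.value = unname(sm[, p_col])
  )
}

#' @export
glance.gait_regression <- function(x, ...) {
  if (x$model_type == "linear") {
    sm <- summary(x$fit)
    # a constant outcome has no variance to explain: report R2 = 0
    y <- stats::model.response(stats::model.frame(x$fit))
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0 && is.finite(sm$r.squared)) sm$r.squared else 0
    adj <- if (tss > 0 && is.finite(sm$adj.r.squared)) sm$adj.r.squared else 0
    tibble(
      model_type = "linear", outcome = x$outcome,
      predictors = paste(x$predictors, collapse = "+"),
      r2 = r2, adjusted_r2 = adj,
      n = x$n, converged = TRUE
    )
  } else {
    pr <- pseudo_r2(x)
    tibble(
      model_type = "poisson", outcome = x$outcome,
      predictors = paste(x$predictors, collapse = "+"),
      r2 = pr$r2, adjusted_r2 = pr$adjusted_r2,
      n = x$n, converged = x$converged
    )
  }
}

#' @export
print.gait_regression <- function(x, ...) {
  cat(sprintf("<gait_regression: %s %s ~ %s, n = %d>\n",
              x$model_type, x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n))
  print(tidy(x))
  invisible(x)
}
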