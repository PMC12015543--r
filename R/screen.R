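# Wald z critical value for 95% intervals.
Z_95 <- 1.959964

#' Univariate logistic regression of ALN status on one feature
#'
#' Fits `label ~ intercept + slope * x` by maximum likelihood (iteratively
#' reweighted least squares via [stats::glm()]) and reports the slope with
#' Wald inference: standard error from the inverse observed information,
#' `OR = exp(beta)`, 95% CI `exp(beta +/- 1.959964 * SE)` and a two-sided
#' p-value from the Wald z statistic.
#'
#' Degenerate inputs are detected rather than reported as spurious estimates:
#' a zero-variance predictor, a binary predictor with an empty cell of its
#' 2x2 table against the label, or a fitted `|beta| > 15` (quasi-complete
#' separation) yield `status = "degenerate"` with NA estimates.
#'
#' @param x Numeric predictor vector.
#' @param y Binary 0/1 outcome vector of the same length, both classes present.
#' @param feature Feature name recorded in the result.
#' @return One-row tibble with columns `feature`, `coefficient`, `std_error`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `status`, `selected`
#'   (initialised to FALSE; see [screen_features()]).
#' @export
fit_univariate_logistic <- function(x, y, feature = "x") {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "alngraph_parameter_error")
  }
  if (length(y) < 2L) {
    abort("Need at least two observations.",
          class = "alngraph_parameter_error")
  }
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary 0/1.", class = "alngraph_parameter_error")
  }
  if (length(unique(y)) < 2L) {
    abort("`y` must contain both classes.",
          class = "alngraph_parameter_error")
  }
  degenerate <- function() {
    tibble::tibble(feature = feature, coefficient = NA_real_,
                   std_error = NA_real_, odds_ratio = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, status = "degenerate",
                   selected = FALSE)
  }
  if (sd(x) == 0) return(degenerate())
  is_binary <- all(x %in% c(0, 1))
  if (is_binary) {
    counts <- table(factor(x, c(0, 1)), factor(y, c(0, 1)))
    if (any(counts == 0)) return(degenerate())
  }
  fit <- suppressWarnings(
    glm(y ~ x, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- unname(coef(fit)[["x"]])
  if (!is.finite(beta) || abs(beta) > 15) return(degenerate())
  se <- sqrt(vcov(fit)["x", "x"])
  z <- beta / se
  tibble::tibble(
    feature = feature,
    coefficient = beta,
    std_error = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - Z_95 * se),
    ci_high = exp(beta + Z_95 * se),
    p_value = 2 * pnorm(-abs(z)),
    status = "converged",
    selected = FALSE)
}

#' Odds ratio implied by a logistic coefficient
#'
#' @param beta Finite log-odds coefficient(s).
#' @return `exp(beta)`.
#' @export
odds_ratio_from_coefficient <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    abort("`beta` must be finite numeric.",
          class = "alngraph_parameter_error")
  }
  exp(beta)
}

#' Screen cohort features by univariate logistic regression
#'
#' Runs [fit_univariate_logistic()] for each of the 18 cohort features
#' against the ALN label, marking features as selected either by a p-value
#' cutoff or by an explicit include list. The pipeline default for
#' reproducing the published factor set uses
#' `include = default_candidate_factors()` (size, location, Terms 1--7 and 9):
#' the study's stated candidate set excludes BI-RADS despite its nominal
#' significance, so both behaviours are exposed.
#'
#' @param cohort A cohort tibble with the full feature schema.
#' @param alpha Significance level; converged features with `p < alpha` are
#'   selected when `include` is NULL.
#' @param include Optional character vector of feature names to select
#'   regardless of p-values.
#' @return A tibble with one row per feature (same columns as
#'   [fit_univariate_logistic()]).
#' @export
screen_features <- function(cohort, alpha = 0.05, include = NULL) {
  feats <- cohort_feature_names()
  missing <- setdiff(feats, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort is missing feature column(s): ",
                 paste(missing, collapse = ", ")),
          class = "alngraph_schema_error")
  }
  if (!is.null(include)) {
    bad <- setdiff(include, feats)
    if (length(bad)) {
      abort(paste0("Unknown feature(s) in `include`: ",
                   paste(bad, collapse = ", ")),
            class = "alngraph_parameter_error")
    }
  }
  res <- purrr::map_dfr(feats, function(f) {
    fit_univariate_logistic(cohort[[f]], cohort$aln_status, feature = f)
  })
  if (is.null(include)) {
    res$selected <- res$status == "converged" & !is.na(res$p_value) &
      res$p_value < alpha
  } else {
    res$selected <- res$feature %in% include
  }
  res
}

#' Write a screening report as CSV
#'
#' Columns mirror the published univariate table: feature, coefficient,
#' odds ratio with CI bounds, p-value and the selection flag.
#'
#' @param screen A tibble from [screen_features()].
#' @param path File path.
#' @export
write_screen_csv <- function(screen, path) {
  readr::write_csv(
    dplyr::select(screen, "feature", "coefficient", "odds_ratio",
                  "ci_low", "ci_high", "p_value", "status", "selected"),
    path)
  invisible(path)
}
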