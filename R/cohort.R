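#' Specify a synthetic breast-cancer cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. Defaults
#' emulate the training cohort of the motivating study: ALNM prevalence
#' 42.3%, age 50.46 +/- 10.36 years, ultrasound tumour size 19.06 +/- 6.57 mm,
#' axillary-ultrasound term positivity rates from the observed training
#' marginals, and per-feature log-odds effects equal to the published
#' univariate logistic coefficients.
#'
#' Binary features (HER2 and Terms 1--9) are generated through a latent
#' logistic link: `P(feature = 1 | label) = plogis(b + effect * label)`,
#' with the base logit `b` calibrated so the marginal positivity rate matches
#' the requested base rate. This makes each planted `effect` exactly the 2x2
#' log odds ratio between feature and label, so univariate screening recovers
#' it. Continuous features use class-conditional distributions whose implied
#' logistic slope equals the planted effect (equal-variance Gaussian shifts
#' for age/size, exponentially tilted uniforms for the percent-scale markers),
#' and ordinal features use exponentially tilted categorical distributions.
#'
#' @param n_patients Number of patients (>= 0).
#' @param prevalence Probability of ALN metastasis.
#' @param age_mean,age_sd Age marginal, years (truncated to \[18, 100\]).
#' @param size_mean,size_sd Ultrasound size marginal, mm (truncated to (0, 40\]).
#' @param term_base_rates Named numeric of marginal positivity probabilities
#'   for `term1`..`term9`. Term 8 defaults to 0 (no positives in the training
#'   cohort), which makes it degenerate under screening.
#' @param her2_rate Marginal HER2-positive probability.
#' @param location_probs,tumor_type_probs,birads_probs Marginal category
#'   probabilities for the ordinal codes (location 1--4, tumour type 1--3,
#'   BI-RADS 1--4 standing for 4A/4B/4C/5).
#' @param effect_log_odds Named numeric of per-feature log-odds of ALNM;
#'   names must be a subset of the 18 feature names. Unlisted features get 0.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 200, seed = 1)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_patients = 584L,
                        prevalence = 0.423,
                        age_mean = 50.46, age_sd = 10.36,
                        size_mean = 19.06, size_sd = 6.57,
                        term_base_rates = c(
                          term1 = 0.380, term2 = 0.067, term3 = 0.165,
                          term4 = 0.273, term5 = 0.195, term6 = 0.075,
                          term7 = 0.028, term8 = 0.000, term9 = 0.174),
                        her2_rate = 0.223,
                        location_probs = c(0.270, 0.139, 0.172, 0.419),
                        tumor_type_probs = c(0.884, 0.026, 0.090),
                        birads_probs = c(0.051, 0.275, 0.451, 0.223),
                        effect_log_odds = default_effect_log_odds(),
                        seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 0) {
    abort("`n_patients` must be a non-negative integer.",
          class = "alngraph_parameter_error")
  }
  assert_probability(prevalence, "prevalence")
  assert_positive(age_sd, "age_sd")
  assert_positive(size_sd, "size_sd")
  assert_probability(term_base_rates, "term_base_rates")
  assert_probability(her2_rate, "her2_rate")
  if (!setequal(names(term_base_rates), paste0("term", 1:9))) {
    abort("`term_base_rates` must be named term1..term9.",
          class = "alngraph_parameter_error")
  }
  for (p in list(location_probs = location_probs,
                 tumor_type_probs = tumor_type_probs,
                 birads_probs = birads_probs)) {
    assert_probability(p, "category probabilities")
  }
  if (abs(sum(location_probs) - 1) > 1e-6 ||
      abs(sum(tumor_type_probs) - 1) > 1e-6 ||
      abs(sum(birads_probs) - 1) > 1e-6) {
    abort("Category probabilities must sum to 1.",
          class = "alngraph_parameter_error")
  }
  eff <- setNames(numeric(length(cohort_feature_names())),
                  cohort_feature_names())
  if (length(effect_log_odds)) {
    bad <- setdiff(names(effect_log_odds), names(eff))
    if (length(bad)) {
      abort(paste0("Unknown feature(s) in `effect_log_odds`: ",
                   paste(bad, collapse = ", ")),
            class = "alngraph_parameter_error")
    }
    eff[names(effect_log_odds)] <- effect_log_odds
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         age_mean = age_mean, age_sd = age_sd,
         size_mean = size_mean, size_sd = size_sd,
         term_base_rates = term_base_rates[paste0("term", 1:9)],
         her2_rate = her2_rate,
         location_probs = location_probs,
         tumor_type_probs = tumor_type_probs,
         birads_probs = birads_probs,
         effect_log_odds = eff,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Published univariate log-odds effects used as generator defaults
#'
#' Coefficients of the per-feature univariate logistic regressions in the
#' training cohort of the motivating study, on the units the features are
#' generated in (years, mm, ordinal codes, percents, 0/1 indicators).
#' Term 8 had no positives in the training cohort; its effect defaults to 0.
#'
#' @return Named numeric vector over the 18 cohort features.
#' @export
default_effect_log_odds <- function() {
  c(age = 0.0010, location = 0.1788, us_size = 0.0575, tumor_type = 0.0152,
    birads = -0.1867, er = 0.0003, pr = -0.0024, ki67 = 0.0033,
    her2 = 0.1766,
    term1 = 0.9057, term2 = 2.6872, term3 = 1.1147, term4 = 0.6735,
    term5 = 2.4585, term6 = 2.0237, term7 = 2.0663, term8 = 0,
    term9 = 1.4958)
}

# Base logit b with (1-pi)*plogis(b) + pi*plogis(b + beta) = rate.
calibrate_base_logit <- function(rate, beta, prevalence) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(b) {
    (1 - prevalence) * plogis(b) + prevalence * plogis(b + beta) - rate
  }
  uniroot(f, lower = -40, upper = 40, tol = 1e-12)$root
}

# Class-conditional category probabilities with P1 propto P0 * exp(beta*x)
# and mixture marginal equal to `target`; solved by fixed-point iteration.
calibrate_categorical <- function(target, beta, prevalence) {
  x <- seq_along(target)
  p0 <- target
  for (i in 1:200) {
    z <- sum(p0 * exp(beta * x))
    p0_new <- target / ((1 - prevalence) + prevalence * exp(beta * x) / z)
    p0_new <- p0_new / sum(p0_new)
    if (max(abs(p0_new - p0)) < 1e-12) break
    p0 <- p0_new
  }
  p1 <- p0 * exp(beta * x)
  list(p0 = p0 / sum(p0), p1 = p1 / sum(p1))
}

# Truncated normal sampling by inverse CDF (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# Density propto exp(beta * x) on [0, 100], sampled by inverse CDF.
rtilted_percent <- function(n, beta) {
  u <- runif(n)
  if (abs(beta) < 1e-12) return(100 * u)
  log1p(u * expm1(100 * beta)) / beta
}

empty_cohort <- function() {
  cols <- c(list(patient_id = character()),
            setNames(rep(list(numeric()), 18L), cohort_feature_names()),
            list(aln_status = integer()))
  tibble::as_tibble(cols)
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n_patients` patients: a Bernoulli ALN-status label at the
#' configured prevalence, then features conditional on the label so that each
#' feature's univariate log odds ratio with the label equals the planted
#' effect while marginals match the configured targets (exactly for binary
#' terms, asymptotically for the rest). See [cohort_spec()] for the
#' generating mechanisms.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `patient_id`, the 18 features
#'   (`age`, `us_size`, `location`, `tumor_type`, `birads`, `er`, `pr`,
#'   `ki67`, `her2`, `term1`..`term9`) and `aln_status` (1 = metastasis).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (n == 0L) return(empty_cohort())
  eff <- spec$effect_log_odds
  pi <- spec$prevalence

  withr::with_seed(spec$seed, {
    label <- rbinom(n, 1L, pi)

    # Continuous: equal-variance Gaussian shift Delta = beta * sigma^2 gives
    # a logistic slope of exactly beta; mixture mean kept at the target.
    gauss <- function(target_mean, sd, beta, lower, upper) {
      shift <- beta * sd^2
      mu0 <- target_mean - pi * shift
      rtruncnorm(n, mu0 + shift * label, sd, lower, upper)
    }
    age <- gauss(spec$age_mean, spec$age_sd, eff[["age"]], 18, 100)
    us_size <- gauss(spec$size_mean, spec$size_sd, eff[["us_size"]], 1e-6, 40)

    ordinal <- function(target, beta) {
      cal <- calibrate_categorical(target, beta, pi)
      x <- integer(n)
      k <- seq_along(target)
      n1 <- sum(label == 1L)
      x[label == 1L] <- sample(k, n1, replace = TRUE, prob = cal$p1)
      x[label == 0L] <- sample(k, n - n1, replace = TRUE, prob = cal$p0)
      x
    }
    location <- ordinal(spec$location_probs, eff[["location"]])
    tumor_type <- ordinal(spec$tumor_type_probs, eff[["tumor_type"]])
    birads <- ordinal(spec$birads_probs, eff[["birads"]])

    percent <- function(beta) {
      x <- numeric(n)
      x[label == 0L] <- 100 * runif(sum(label == 0L))
      x[label == 1L] <- rtilted_percent(sum(label == 1L), beta)
      x
    }
    er <- percent(eff[["er"]])
    pr <- percent(eff[["pr"]])
    ki67 <- percent(eff[["ki67"]])

    bin <- function(rate, beta) {
      b <- calibrate_base_logit(rate, beta, pi)
      rbinom(n, 1L, plogis(b + beta * label))
    }
    her2 <- bin(spec$her2_rate, eff[["her2"]])
    terms <- lapply(1:9, function(k) {
      bin(spec$term_base_rates[[paste0("term", k)]],
          eff[[paste0("term", k)]])
    })

    out <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age, us_size = us_size,
      location = location, tumor_type = tumor_type, birads = birads,
      er = er, pr = pr, ki67 = ki67, her2 = her2)
    for (k in 1:9) out[[paste0("term", k)]] <- terms[[k]]
    out$aln_status <- label
    out
  })
}

#' Split a cohort into training and test parts
#'
#' Random 4:1-style partition. With `stratified = TRUE` (the default) each
#' class is split independently with `floor(n_class * ratio)` patients going
#' to training, so class proportions in the two parts agree with the input
#' to within one patient. A 584-patient cohort with 247 metastases at
#' `ratio = 0.8` yields the 466/118 split with 197 and 50 positives.
#' Without stratification, `floor(n * ratio)` rows are sampled.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param ratio Training fraction, in (0, 1).
#' @param stratified Preserve class balance across the parts?
#' @param seed Integer seed; the partition is reproducible.
#' @return A named list with tibbles `train` and `test`; the two parts are
#'   disjoint and their union is the input.
#' @export
split_cohort <- function(cohort, ratio = 0.8, stratified = TRUE, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio <= 0 || ratio >= 1) {
    abort("`ratio` must lie strictly between 0 and 1.",
          class = "alngraph_parameter_error")
  }
  if (nrow(cohort) == 0L) {
    abort("`cohort` must be non-empty.", class = "alngraph_parameter_error")
  }
  idx <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      unlist(lapply(split(seq_len(nrow(cohort)), cohort$aln_status),
                    function(i) sample(i, floor(length(i) * ratio))),
             use.names = FALSE)
    } else {
      sample(seq_len(nrow(cohort)), floor(nrow(cohort) * ratio))
    }
  })
  idx <- sort(idx)
  list(train = cohort[idx, , drop = FALSE],
       test = cohort[setdiff(seq_len(nrow(cohort)), idx), , drop = FALSE])
}

#' Summarise cohort composition
#'
#' @param cohort A cohort tibble.
#' @return One-row tibble with patient count, metastasis count, and
#'   prevalence both as a proportion and as a percentage rounded to one
#'   decimal (the convention used for reporting metastatic rates).
#' @export
cohort_prevalence <- function(cohort) {
  n <- nrow(cohort)
  pos <- sum(cohort$aln_status == 1)
  tibble::tibble(
    n_patients = n, n_positive = pos,
    prevalence = if (n > 0) pos / n else NA_real_,
    prevalence_pct = if (n > 0) round(100 * pos / n, 1) else NA_real_)
}

#' Read and write cohort CSV files
#'
#' The on-disk format is a UTF-8 comma-separated file with '.' decimals and
#' the fixed header `patient_id, age, us_size, location, tumor_type, birads,
#' er, pr, ki67, her2, term1..term9, aln_status`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(identical(names(cohort), cohort_column_names()))
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      .default = readr::col_double()))
  rep <- validate_cohort_table(out)
  if (!rep$ok) {
    abort(paste0("Invalid cohort file: ",
                 paste(rep$issues$message, collapse = "; ")),
          class = "alngraph_schema_error")
  }
  out
}

# Shared schema checks used by read_cohort_csv() and validate_cohort_csv().
validate_cohort_table <- function(tbl) {
  issues <- list()
  note <- function(column, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      column = column, message = message)
  }
  expected <- cohort_column_names()
  if (!identical(names(tbl), expected)) {
    missing <- setdiff(expected, names(tbl))
    extra <- setdiff(names(tbl), expected)
    for (m in missing) note(m, sprintf("missing column '%s'", m))
    for (e in extra) note(e, sprintf("unexpected column '%s'", e))
    if (!length(missing) && !length(extra)) {
      note(NA_character_, "columns out of order")
    }
    return(list(ok = FALSE, issues = dplyr::bind_rows(issues)))
  }
  if (anyDuplicated(tbl$patient_id)) {
    dup <- unique(tbl$patient_id[duplicated(tbl$patient_id)])
    note("patient_id", sprintf("duplicate patient_id: %s",
                               paste(head(dup, 5L), collapse = ", ")))
  }
  for (col in setdiff(expected, "patient_id")) {
    if (anyNA(tbl[[col]])) note(col, sprintf("missing values in '%s'", col))
  }
  for (col in c(binary_feature_names(), "aln_status")) {
    v <- tbl[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad)) {
      note(col, sprintf("non-binary values in '%s' at rows %s", col,
                        paste(head(bad, 5L), collapse = ", ")))
    }
  }
  ranges <- list(location = c(1, 4), tumor_type = c(1, 3), birads = c(1, 4))
  for (col in names(ranges)) {
    v <- tbl[[col]]
    ok <- is.na(v) | (v >= ranges[[col]][1] & v <= ranges[[col]][2] &
                        v == round(v))
    if (any(!ok)) {
      note(col, sprintf("ordinal codes out of range in '%s' at rows %s", col,
                        paste(head(which(!ok), 5L), collapse = ", ")))
    }
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(column = character(), message = character())
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Validate a cohort CSV against the expected schema
#'
#' Checks the header, missing values, binary domains, ordinal code ranges
#' and `patient_id` uniqueness.
#'
#' @param path Path to a CSV file.
#' @return A list with `ok` (logical) and `issues`, a tibble with columns
#'   `column` and `message` describing every violation found.
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "alngraph_schema_error")
  }
  tbl <- tryCatch(
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(),
                                     show_col_types = FALSE)),
    error = function(e) NULL)
  if (is.null(tbl)) {
    return(list(ok = FALSE,
                issues = tibble::tibble(column = NA_character_,
                                        message = "unreadable CSV")))
  }
  validate_cohort_table(tbl)
}

#' Serialize a cohort specification to a flat key=value file
#'
#' Vector-valued fields are written as comma-separated values; names of
#' named vectors are preserved as `field.name` keys.
#'
#' @param spec A [cohort_spec()].
#' @param path File path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  lines <- character()
  for (field in names(spec)) {
    v <- spec[[field]]
    if (!is.null(names(v)) && length(v) > 1L) {
      lines <- c(lines, sprintf("%s.%s=%.17g", field, names(v), v))
    } else {
      lines <- c(lines, sprintf("%s=%s", field,
                                paste(sprintf("%.17g", v), collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  kv <- read_flat_config(path)
  num <- function(key, default) {
    if (key %in% names(kv)) as.numeric(strsplit(kv[[key]], ",")[[1]]) else default
  }
  named_group <- function(prefix, default) {
    keys <- grep(paste0("^", prefix, "\\."), names(kv), value = TRUE)
    if (!length(keys)) return(default)
    setNames(vapply(keys, function(k) as.numeric(kv[[k]]), numeric(1)),
             sub(paste0("^", prefix, "\\."), "", keys))
  }
  d <- cohort_spec()
  cohort_spec(
    n_patients = num("n_patients", d$n_patients),
    prevalence = num("prevalence", d$prevalence),
    age_mean = num("age_mean", d$age_mean), age_sd = num("age_sd", d$age_sd),
    size_mean = num("size_mean", d$size_mean),
    size_sd = num("size_sd", d$size_sd),
    term_base_rates = named_group("term_base_rates", d$term_base_rates),
    her2_rate = num("her2_rate", d$her2_rate),
    location_probs = num("location_probs", d$location_probs),
    tumor_type_probs = num("tumor_type_probs", d$tumor_type_probs),
    birads_probs = num("birads_probs", d$birads_probs),
    effect_log_odds = named_group("effect_log_odds", d$effect_log_odds),
    seed = num("seed", d$seed))
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
           vapply(kv, `[[`, character(1), 1L))
}
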