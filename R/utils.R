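#' @importFrom rlang abort warn .data
#' @importFrom stats plogis qlogis rnorm runif rbinom qnorm pnorm uniroot
#'   setNames quantile cor sd glm binomial coef vcov predict
#' @importFrom utils head packageVersion
NULL

# Canonical cohort column order: id, 18 features, label.
cohort_feature_names <- function() {
  c("age", "us_size", "location", "tumor_type", "birads",
    "er", "pr", "ki67", "her2", paste0("term", 1:9))
}

cohort_column_names <- function() {
  c("patient_id", cohort_feature_names(), "aln_status")
}

binary_feature_names <- function() c("her2", paste0("term", 1:9))

# The ten candidate factors the screening stage reduces to by default
# (tumour size, location, and eight of the nine axillary-US terms).
#' Default candidate-factor list used to build the patient graphs
#'
#' The ten features carried forward to graph construction when screening
#' uses the explicit pipeline default rather than a p-value cutoff:
#' ultrasound tumour size, tumour location, and axillary-ultrasound
#' Terms 1--7 and 9.
#'
#' @return Character vector of ten feature names.
#' @export
default_candidate_factors <- function() {
  c("us_size", "location", paste0("term", c(1:7, 9)))
}

# Deterministic per-stage seed derivation from one global seed.
# Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "alngraph_parameter_error")
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    abort(sprintf("`%s` must be > 0.", name),
          class = "alngraph_parameter_error")
  }
  invisible(x)
}

relu <- function(x) pmax(x, 0)

# Numerically stable row-wise softmax; -Inf entries get weight 0.
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e[is.na(e)] <- 0  # rows that are all -Inf (cannot occur with self-loops)
  e / rowSums(e)
}
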