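#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings: the input (synthetic cohort or CSV), the
#' train/test split, screening, graph construction, the per-architecture
#' model settings, training, and evaluation. The defaults are the study
#' conditions: 4:1 stratified split, cosine threshold 0.95, the explicit
#' ten-factor candidate list, learning rate 0.0001, 1000 epochs, and all
#' three architectures. One global seed deterministically derives every
#' stage seed so stages can be re-run in isolation.
#'
#' @param input_mode `"synthetic"` (default) or `"csv"`.
#' @param csv_path Cohort CSV path (csv mode only).
#' @param spec A [cohort_spec()] (synthetic mode only); its `seed` is
#'   overridden by the derived cohort seed.
#' @param ratio Training fraction (default 0.8, the 4:1 split).
#' @param stratified Stratify the split by ALN status? Default TRUE.
#' @param alpha Screening significance level (used when `include` is NULL).
#' @param include Explicit candidate-factor list; default
#'   [default_candidate_factors()]. Set NULL to select by `p < alpha`.
#' @param tau Cosine-similarity threshold (default 0.95).
#' @param architectures Architectures to train (subset of gcn/gat/gin).
#' @param hidden_dim,n_layers,dropout Shared [model_config()] settings.
#' @param epochs,lr,batch_size,batch_mode Shared [train_config()] settings.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "csv"),
                            csv_path = NULL,
                            spec = cohort_spec(),
                            ratio = 0.8, stratified = TRUE,
                            alpha = 0.05,
                            include = default_candidate_factors(),
                            tau = 0.95,
                            architectures = c("gcn", "gat", "gin"),
                            hidden_dim = 16L, n_layers = 2L, dropout = 0,
                            epochs = 1000L, lr = 1e-4, batch_size = 32L,
                            batch_mode = "full",
                            n_boot = 2000L, seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "csv") {
    if (is.null(csv_path) || !file.exists(csv_path)) {
      abort("`csv_path` must point to an existing file in csv mode.",
            class = "alngraph_parameter_error")
    }
  }
  bad <- setdiff(architectures, c("gcn", "gat", "gin"))
  if (length(bad)) {
    abort(paste0("Unknown architecture(s): ", paste(bad, collapse = ", ")),
          class = "alngraph_parameter_error")
  }
  structure(
    list(input_mode = input_mode, csv_path = csv_path, spec = spec,
         ratio = ratio, stratified = stratified, alpha = alpha,
         include = include, tau = tau, architectures = architectures,
         hidden_dim = as.integer(hidden_dim), n_layers = as.integer(n_layers),
         dropout = dropout, epochs = as.integer(epochs), lr = lr,
         batch_size = as.integer(batch_size), batch_mode = batch_mode,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "pipeline_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[alngraph] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes the stages in order: cohort (generate or load) -> split ->
#' univariate screen -> scaler fit on the training cohort -> one patient
#' graph per cohort -> train each architecture -> evaluate on both graphs ->
#' inter-model agreement, writing every artifact under `outdir`:
#' `cohort.csv`, `screen.csv`, edge lists and node tables per cohort,
#' parameter checkpoints, per-architecture evaluation reports,
#' `metrics_train.csv` / `metrics_test.csv`, `agreement.csv` and
#' `manifest.json`. Outputs are pure functions of (inputs, config, seed):
#' re-running with the same config reproduces them byte-for-byte
#' (manifest timestamps aside).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param verbose Log per-stage progress messages?
#' @return Invisibly, a list with the run `manifest`, the `screen` table,
#'   the two graphs, the trained `models` and both sets of evaluations.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(
    cohort = derive_seed(config$seed, "cohort"),
    split = derive_seed(config$seed, "split"),
    boot = derive_seed(config$seed, "bootstrap"))
  for (arch in config$architectures) {
    seeds[[paste0("init_", arch)]] <- derive_seed(config$seed,
                                                  paste0("init_", arch))
    seeds[[paste0("train_", arch)]] <- derive_seed(config$seed,
                                                   paste0("train_", arch))
  }

  # stage: cohort
  cohort <- if (config$input_mode == "synthetic") {
    sp <- config$spec
    sp$seed <- seeds$cohort
    generate_cohort(sp)
  } else {
    read_cohort_csv(config$csv_path)
  }
  cohort_path <- file.path(outdir, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)
  pipeline_log(verbose, "cohort: %d patients, prevalence %.1f%%",
               nrow(cohort), 100 * mean(cohort$aln_status))

  # stage: split
  parts <- split_cohort(cohort, ratio = config$ratio,
                        stratified = config$stratified, seed = seeds$split)
  pipeline_log(verbose, "split: %d train / %d test",
               nrow(parts$train), nrow(parts$test))

  # stage: screen (always on the training cohort)
  screen <- screen_features(parts$train, alpha = config$alpha,
                            include = config$include)
  write_screen_csv(screen, file.path(outdir, "screen.csv"))
  selected <- screen$feature[screen$selected]
  if (length(selected) < 1L) {
    abort("Screening selected no features; cannot build a graph.",
          class = "alngraph_pipeline_error")
  }
  pipeline_log(verbose, "screen: %d factors selected (%s)",
               length(selected), paste(selected, collapse = ", "))

  # stage: scale + graphs
  scaler <- fit_scaler(parts$train[, selected, drop = FALSE])
  graphs <- list(
    train = assemble_graph(parts$train, selected, scaler, tau = config$tau),
    test = assemble_graph(parts$test, selected, scaler, tau = config$tau))
  for (part in names(graphs)) {
    write_edge_tsv(graphs[[part]],
                   file.path(outdir, sprintf("edges_%s.tsv", part)))
    write_node_csv(graphs[[part]],
                   file.path(outdir, sprintf("nodes_%s.csv", part)))
    gs <- graph_summary(graphs[[part]])
    pipeline_log(verbose, "graph %s: %d nodes, %d edges, %d components",
                 part, gs$n_nodes, gs$n_edges, gs$n_components)
  }

  # stage: train + evaluate per architecture
  models <- list()
  evals_train <- list()
  evals_test <- list()
  for (arch in config$architectures) {
    mc <- model_config(architecture = arch, n_layers = config$n_layers,
                       hidden_dim = config$hidden_dim,
                       dropout = config$dropout,
                       init_seed = seeds[[paste0("init_", arch)]])
    tc <- train_config(epochs = config$epochs, lr = config$lr,
                       batch_size = config$batch_size,
                       batch_mode = config$batch_mode,
                       seed = seeds[[paste0("train_", arch)]])
    model <- train_model(graphs$train, mc, tc)
    models[[arch]] <- model
    write_checkpoint(model$params, mc,
                     file.path(outdir, sprintf("checkpoint_%s.json", arch)))
    evals_train[[arch]] <- evaluate_model(model, graphs$train,
                                          n_boot = config$n_boot,
                                          seed = seeds$boot)
    evals_test[[arch]] <- evaluate_model(model, graphs$test,
                                         n_boot = config$n_boot,
                                         seed = seeds$boot)
    write_eval_report(evals_test[[arch]], outdir, prefix = arch)
    pipeline_log(verbose,
                 "%s: final loss %.4f, test acc %.3f, test auc %.3f",
                 arch, model$loss_history[config$epochs],
                 evals_test[[arch]]$metrics$acc, evals_test[[arch]]$auc)
  }
  metrics_train <- purrr::map_dfr(evals_train, glance)
  metrics_test <- purrr::map_dfr(evals_test, glance)
  readr::write_csv(metrics_train, file.path(outdir, "metrics_train.csv"))
  readr::write_csv(metrics_test, file.path(outdir, "metrics_test.csv"))

  # stage: agreement between architectures on the test graph
  agreement <- NULL
  if (length(config$architectures) > 1L) {
    preds <- lapply(evals_test, function(e) e$predictions$pred)
    agreement <- tryCatch(agreement_matrix(preds), error = function(e) NULL)
    if (!is.null(agreement)) {
      readr::write_csv(agreement, file.path(outdir, "agreement.csv"))
    } else {
      pipeline_log(verbose,
                   "agreement skipped: a model predicted a single class")
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("alngraph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, derived_seeds = seeds,
    input_mode = config$input_mode,
    input_checksum = unname(tools::md5sum(cohort_path)),
    config = list(
      ratio = config$ratio, stratified = config$stratified,
      alpha = config$alpha, include = config$include, tau = config$tau,
      architectures = config$architectures,
      hidden_dim = config$hidden_dim, n_layers = config$n_layers,
      dropout = config$dropout, epochs = config$epochs, lr = config$lr,
      batch_size = config$batch_size, batch_mode = config$batch_mode,
      n_boot = config$n_boot),
    counts = list(
      n_patients = nrow(cohort),
      n_train = nrow(parts$train), n_test = nrow(parts$test),
      n_selected = length(selected),
      edges_train = nrow(graphs$train$edges),
      edges_test = nrow(graphs$test$edges)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = cohort, screen = screen,
                 graphs = graphs, models = models,
                 evals_train = evals_train, evals_test = evals_test,
                 agreement = agreement))
}

#' Read and write pipeline configurations as flat key=value files
#'
#' All scalar settings are `key=value` lines; vectors are comma-separated;
#' synthetic cohort settings use the `cohort.`-prefixed keys of
#' [write_cohort_spec()]. Unknown keys are rejected.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- c(
    sprintf("input_mode=%s", config$input_mode),
    if (!is.null(config$csv_path)) sprintf("csv_path=%s", config$csv_path),
    sprintf("ratio=%.17g", config$ratio),
    sprintf("stratified=%s", tolower(config$stratified)),
    sprintf("alpha=%.17g", config$alpha),
    sprintf("include=%s",
            if (is.null(config$include)) "auto"
            else paste(config$include, collapse = ",")),
    sprintf("tau=%.17g", config$tau),
    sprintf("architectures=%s", paste(config$architectures, collapse = ",")),
    sprintf("hidden_dim=%d", config$hidden_dim),
    sprintf("n_layers=%d", config$n_layers),
    sprintf("dropout=%.17g", config$dropout),
    sprintf("epochs=%d", config$epochs),
    sprintf("lr=%.17g", config$lr),
    sprintf("batch_size=%d", config$batch_size),
    sprintf("batch_mode=%s", config$batch_mode),
    sprintf("n_boot=%d", config$n_boot),
    sprintf("seed=%d", config$seed))
  writeLines(lines, path)
  spec_path <- paste0(path, ".cohort")
  if (config$input_mode == "synthetic") write_cohort_spec(config$spec,
                                                          spec_path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  kv <- read_flat_config(path)
  known <- c("input_mode", "csv_path", "ratio", "stratified", "alpha",
             "include", "tau", "architectures", "hidden_dim", "n_layers",
             "dropout", "epochs", "lr", "batch_size", "batch_mode",
             "n_boot", "seed")
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "alngraph_schema_error")
  }
  get <- function(key, default, f = identity) {
    if (key %in% names(kv)) f(kv[[key]]) else default
  }
  include <- get("include", default_candidate_factors(), function(v) {
    if (identical(v, "auto")) NULL else strsplit(v, ",")[[1]]
  })
  spec_path <- paste0(path, ".cohort")
  spec <- if (file.exists(spec_path)) read_cohort_spec(spec_path)
          else cohort_spec()
  pipeline_config(
    input_mode = get("input_mode", "synthetic"),
    csv_path = get("csv_path", NULL),
    spec = spec,
    ratio = get("ratio", 0.8, as.numeric),
    stratified = get("stratified", TRUE, function(v) v == "true"),
    alpha = get("alpha", 0.05, as.numeric),
    include = include,
    tau = get("tau", 0.95, as.numeric),
    architectures = get("architectures", c("gcn", "gat", "gin"),
                        function(v) strsplit(v, ",")[[1]]),
    hidden_dim = get("hidden_dim", 16L, as.integer),
    n_layers = get("n_layers", 2L, as.integer),
    dropout = get("dropout", 0, as.numeric),
    epochs = get("epochs", 1000L, as.integer),
    lr = get("lr", 1e-4, as.numeric),
    batch_size = get("batch_size", 32L, as.integer),
    batch_mode = get("batch_mode", "full"),
    n_boot = get("n_boot", 2000L, as.integer),
    seed = get("seed", 1L, as.integer))
}
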