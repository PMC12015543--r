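#' Configure the training loop
#'
#' The published training recipe: Adam, learning rate 0.0001, batch size 32,
#' 1000 epochs. A "batch" is not well defined for full-graph transductive
#' training, so the default mode is full-batch gradient descent with Adam;
#' `batch_mode = "subsample"` instead draws `batch_size` labelled nodes per
#' step for the loss while keeping the full-graph forward pass, preserving
#' message-passing semantics.
#'
#' @param epochs Number of epochs (>= 1; default 1000).
#' @param lr Learning rate (> 0; default 0.0001).
#' @param batch_size Labelled nodes per step in subsample mode (default 32).
#' @param batch_mode `"full"` (default) or `"subsample"`.
#' @param seed Seed for training-time randomness (subsampling, dropout).
#' @param log_every Epoch interval for progress messages; 0 disables logging.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, lr = 1e-4, batch_size = 32L,
                         batch_mode = c("full", "subsample"),
                         seed = 1L, log_every = 0L) {
  batch_mode <- match.arg(batch_mode)
  if (epochs < 1L) {
    abort("`epochs` must be >= 1.", class = "alngraph_parameter_error")
  }
  if (lr <= 0) {
    abort("`lr` must be > 0.", class = "alngraph_parameter_error")
  }
  structure(
    list(epochs = as.integer(epochs), lr = lr,
         batch_size = as.integer(batch_size), batch_mode = batch_mode,
         seed = as.integer(seed), log_every = as.integer(log_every)),
    class = "train_config")
}

#' Train a graph neural network on a patient graph
#'
#' Full-batch transductive training: every epoch runs one forward pass over
#' the whole graph, computes the softmax cross-entropy against the one-hot
#' labels, backpropagates analytically, and applies one Adam update. Results
#' are bit-reproducible given (`config$init_seed`, `tc$seed`).
#'
#' @param graph Training `patient_graph`.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @return An object of class `gnn_model`: trained `params`, the configs,
#'   `loss_history` (one finite value per epoch) and `d_in`.
#' @export
train_model <- function(graph, config, tc = train_config()) {
  stopifnot(inherits(graph, "patient_graph"), inherits(config, "model_config"),
            inherits(tc, "train_config"))
  params <- init_params(config, ncol(graph$x))
  state <- adam_init(params, lr = tc$lr)
  n <- nrow(graph$x)
  hidden_dims <- rep(config$hidden_dim, max(config$n_layers - 1L, 0L))
  loss_history <- numeric(tc$epochs)
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      node_mask <- if (tc$batch_mode == "subsample") {
        sample(n, min(tc$batch_size, n))
      } else NULL
      drop_masks <- if (config$dropout > 0 && length(hidden_dims)) {
        lapply(hidden_dims, function(d) {
          matrix(rbinom(n * d, 1L, 1 - config$dropout) /
                   (1 - config$dropout), n, d)
        })
      } else NULL
      lg <- loss_and_gradients(graph, params, config, node_mask, drop_masks)
      if (!is.finite(lg$loss)) {
        abort(sprintf("Non-finite loss %g at epoch %d; training aborted.",
                      lg$loss, epoch),
              class = "alngraph_training_error")
      }
      loss_history[epoch] <- lg$loss
      upd <- adam_step(params, lg$grads, state)
      params <- upd$params
      state <- upd$state
      if (tc$log_every > 0L && epoch %% tc$log_every == 0L) {
        message(sprintf("[%s] epoch %d/%d loss %.6f",
                        config$architecture, epoch, tc$epochs, lg$loss))
      }
    }
  })
  structure(
    list(params = params, config = config, train_config = tc,
         loss_history = loss_history, d_in = ncol(graph$x)),
    class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  cat(sprintf(
    "<gnn_model> %s, %d layer(s), width %d, %d parameters, final loss %.6f\n",
    toupper(x$config$architecture), x$config$n_layers, x$config$hidden_dim,
    n_params(x$params), x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict ALN status for every node of a graph
#'
#' Softmax class probabilities from the trained network applied to the
#' graph; the hard label is 1 (metastasis) when the class-1 probability is
#' `>= 0.5`, so exact ties classify positive.
#'
#' @param object A trained [train_model()] object.
#' @param graph A `patient_graph` whose feature width matches the model.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `prob_alnm`, `pred` and the true
#'   `aln_status`.
#' @export
predict.gnn_model <- function(object, graph, ...) {
  stopifnot(inherits(graph, "patient_graph"))
  logits <- gnn_forward(graph, object$params, object$config)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  prob <- e[, 2L] / rowSums(e)
  tibble::tibble(
    patient_id = graph$node_ids,
    prob_alnm = prob,
    pred = as.integer(prob >= 0.5),
    aln_status = graph$labels)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model into its loss history
#'
#' @param x A `gnn_model`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.gnn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a trained model
#'
#' @param x A `gnn_model`.
#' @param ... Unused.
#' @return Tibble with architecture, depth, width, parameter count, epochs
#'   and final loss.
#' @export
glance.gnn_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$config$architecture,
    n_layers = x$config$n_layers,
    hidden_dim = x$config$hidden_dim,
    n_parameters = n_params(x$params),
    epochs = x$train_config$epochs,
    final_loss = x$loss_history[length(x$loss_history)])
}
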