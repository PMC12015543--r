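#' Configure a graph neural network classifier
#'
#' All three architectures are two-class node classifiers: a stack of
#' `n_layers` message-passing layers whose final layer maps to 2 logits.
#' The depth, width and activation are not dictated by the message-passing
#' formulations themselves; the defaults (2 layers, width 16, single-head
#' attention, ReLU, no dropout) are the small-data choices of the works that
#' introduced the layers, and are fully configurable.
#'
#' @param architecture One of `"gcn"`, `"gat"`, `"gin"`.
#' @param n_layers Number of message-passing layers (>= 1).
#' @param hidden_dim Hidden width (>= 1).
#' @param activation `"relu"` (default) or `"identity"` between layers.
#' @param dropout Dropout rate in \[0, 1) applied to hidden activations
#'   during training (default 0, i.e. off).
#' @param leaky_slope Negative slope of the LeakyReLU inside GAT attention.
#' @param init_seed Seed for Glorot-uniform initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c("gcn", "gat", "gin"),
                         n_layers = 2L, hidden_dim = 16L,
                         activation = c("relu", "identity"),
                         dropout = 0, leaky_slope = 0.2, init_seed = 1L) {
  architecture <- match.arg(architecture)
  activation <- match.arg(activation)
  if (n_layers < 1L || hidden_dim < 1L) {
    abort("`n_layers` and `hidden_dim` must be >= 1.",
          class = "alngraph_parameter_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must lie in [0, 1).", class = "alngraph_parameter_error")
  }
  if (leaky_slope <= 0 || leaky_slope >= 1) {
    abort("`leaky_slope` must lie in (0, 1).",
          class = "alngraph_parameter_error")
  }
  structure(
    list(architecture = architecture, n_layers = as.integer(n_layers),
         hidden_dim = as.integer(hidden_dim), activation = activation,
         dropout = dropout, leaky_slope = leaky_slope,
         init_seed = as.integer(init_seed), n_classes = 2L),
    class = "model_config")
}

glorot_uniform <- function(fan_in, fan_out, nrow, ncol) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -limit, limit), nrow, ncol)
}

#' Initialise trainable parameters
#'
#' Glorot-uniform weights, zero biases, zero GIN epsilon, seeded by
#' `config$init_seed` for bit-reproducibility.
#'
#' @param config A [model_config()].
#' @param d_in Input feature dimension.
#' @return A list of per-layer parameter lists; structure depends on the
#'   architecture (GCN: `W`, `b`; GAT: `W`, `a`; GIN: `eps`, `W1`, `b1`,
#'   `W2`, `b2`).
#' @export
init_params <- function(config, d_in) {
  stopifnot(inherits(config, "model_config"))
  L <- config$n_layers
  dims <- c(d_in, rep(config$hidden_dim, max(L - 1L, 0L)), config$n_classes)
  withr::with_seed(config$init_seed, {
    lapply(seq_len(L), function(k) {
      di <- dims[k]; do <- dims[k + 1L]
      switch(config$architecture,
        gcn = list(W = glorot_uniform(di, do, di, do),
                   b = numeric(do)),
        gat = list(W = glorot_uniform(di, do, di, do),
                   a = runif(2L * do, -sqrt(6 / (2 * do + 1)),
                             sqrt(6 / (2 * do + 1)))),
        gin = {
          dh <- config$hidden_dim
          list(eps = 0,
               W1 = glorot_uniform(di, dh, di, dh), b1 = numeric(dh),
               W2 = glorot_uniform(dh, do, dh, do), b2 = numeric(do))
        })
    })
  })
}

# Flatten nested parameter lists to one numeric vector and back,
# preserving array dims. Used by Adam and finite-difference checks.
params_flatten <- function(params) {
  unlist(params, use.names = FALSE)
}

params_relist <- function(vec, skeleton) {
  i <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(i + 1L):(i + n)]
    i <<- i + n
    dim(out) <- dim(x)
    out
  }
  walk(skeleton)
}

n_params <- function(params) length(params_flatten(params))

#' Save and load parameter checkpoints
#'
#' Flat, versioned JSON container holding the model configuration and every
#' parameter array with its dimensions; save/load round-trips preserve
#' values to within decimal-representation precision (~1e-15 relative).
#'
#' @param params Parameter list from [init_params()] or training.
#' @param config The matching [model_config()].
#' @param path File path (JSON).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns `list(params, config)`.
#' @export
write_checkpoint <- function(params, config, path) {
  ser <- function(x) {
    if (is.list(x)) return(lapply(x, ser))
    list(dim = if (is.null(dim(x))) length(x) else dim(x),
         values = as.numeric(x))
  }
  jsonlite::write_json(
    list(format = "alngraph-checkpoint", version = 1L,
         config = unclass(config), params = ser(params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$format, "alngraph-checkpoint")) {
    abort("Not an alngraph checkpoint file.",
          class = "alngraph_schema_error")
  }
  deser <- function(x) {
    if (is.list(x) && all(c("dim", "values") %in% names(x))) {
      v <- as.numeric(unlist(x$values))
      d <- as.integer(unlist(x$dim))
      if (length(d) > 1L) dim(v) <- d
      return(v)
    }
    lapply(x, deser)
  }
  cfg <- lapply(raw$config, function(v) if (is.list(v)) unlist(v) else v)
  config <- model_config(
    architecture = cfg$architecture, n_layers = cfg$n_layers,
    hidden_dim = cfg$hidden_dim, activation = cfg$activation,
    dropout = cfg$dropout, leaky_slope = cfg$leaky_slope,
    init_seed = cfg$init_seed)
  list(params = deser(raw$params), config = config)
}
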