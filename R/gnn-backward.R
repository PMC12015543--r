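#' Softmax cross-entropy loss and its gradient
#'
#' Mean over nodes of the negative log softmax probability of the true
#' (one-hot) class, stabilized by row-max subtraction. The gradient with
#' respect to the logits is `(softmax(logits) - Y) / n`.
#'
#' @param logits n x 2 logit matrix.
#' @param y_onehot n x 2 one-hot label matrix (each row sums to 1).
#' @return List with `loss` (scalar) and `grad` (n x 2).
#' @export
softmax_cross_entropy <- function(logits, y_onehot) {
  if (!all(dim(logits) == dim(y_onehot))) {
    abort("`logits` and `y_onehot` must have the same shape.",
          class = "alngraph_shape_error")
  }
  if (any(abs(rowSums(y_onehot) - 1) > 1e-12)) {
    abort("Each row of `y_onehot` must sum to 1.",
          class = "alngraph_parameter_error")
  }
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  shifted <- logits - mx
  lse <- log(rowSums(exp(shifted)))
  p <- exp(shifted - lse)
  loss <- -mean(rowSums(y_onehot * (shifted - lse)))
  list(loss = loss, grad = (p - y_onehot) / n)
}

# --- analytic backward passes -------------------------------------------

gcn_backward <- function(a_hat, cache, layers, config, dlogits, drop_masks) {
  L <- length(layers)
  grads <- vector("list", L)
  dz <- dlogits
  for (k in rev(seq_len(L))) {
    ck <- cache[[k]]
    grads[[k]] <- list(W = crossprod(ck$ah, dz), b = colSums(dz))
    if (k > 1L) {
      dh <- a_hat %*% (dz %*% t(layers[[k]]$W))  # a_hat symmetric
      prev <- cache[[k - 1L]]
      if (!is.null(drop_masks)) dh <- dh * drop_masks[[k - 1L]]
      dz <- dh * act_grad(prev$z, config$activation)
    }
  }
  grads
}

gat_backward <- function(a, cache, layers, config, dlogits, drop_masks) {
  m <- gat_mask(a)
  L <- length(layers)
  grads <- vector("list", L)
  dh_out <- dlogits
  for (k in rev(seq_len(L))) {
    ck <- cache[[k]]
    W <- layers[[k]]$W
    av <- layers[[k]]$a
    do <- ncol(W)
    dzmix <- dh_out
    dalpha <- dzmix %*% t(ck$z)
    dalpha[!m] <- 0
    dz <- crossprod(ck$alpha, dzmix)
    # softmax rows over the closed neighbourhood
    de <- ck$alpha * (dalpha - rowSums(ck$alpha * dalpha))
    depre <- de * ifelse(ck$epre > 0, 1, config$leaky_slope)
    depre[!m] <- 0
    ds <- rowSums(depre)
    dt <- colSums(depre)
    a_src <- av[seq_len(do)]
    a_dst <- av[do + seq_len(do)]
    dz <- dz + outer(ds, a_src) + outer(dt, a_dst)
    da <- c(as.vector(crossprod(ck$z, ds)), as.vector(crossprod(ck$z, dt)))
    grads[[k]] <- list(W = crossprod(ck$h_in, dz), a = da)
    if (k > 1L) {
      dh <- dz %*% t(W)
      prev <- cache[[k - 1L]]
      if (!is.null(drop_masks)) dh <- dh * drop_masks[[k - 1L]]
      dh_out <- dh * act_grad(prev$zmix, config$activation)
    }
  }
  grads
}

gin_backward <- function(a, cache, layers, config, dlogits, drop_masks) {
  L <- length(layers)
  grads <- vector("list", L)
  dz <- dlogits
  for (k in rev(seq_len(L))) {
    ck <- cache[[k]]
    ly <- layers[[k]]
    dW2 <- crossprod(ck$u, dz)
    db2 <- colSums(dz)
    du <- dz %*% t(ly$W2)
    du0 <- du * (ck$u0 > 0)
    dW1 <- crossprod(ck$p, du0)
    db1 <- colSums(du0)
    dp <- du0 %*% t(ly$W1)
    deps <- sum(dp * ck$h_in)
    grads[[k]] <- list(eps = deps, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    if (k > 1L) {
      dh <- (1 + ly$eps) * dp + a %*% dp  # a symmetric
      prev <- cache[[k - 1L]]
      if (!is.null(drop_masks)) dh <- dh * drop_masks[[k - 1L]]
      dz <- dh * act_grad(prev$z, config$activation)
    }
  }
  grads
}

#' Full loss and analytic parameter gradients for one graph
#'
#' Runs the architecture's forward pass with caching, evaluates the softmax
#' cross-entropy over the (optionally subsampled) labelled nodes, and
#' backpropagates to every trainable parameter. The gradients are validated
#' against central finite differences in the test suite.
#'
#' @param graph A `patient_graph`.
#' @param layers Parameter list.
#' @param config A [model_config()].
#' @param node_mask Optional integer vector of node indices contributing to
#'   the loss (all nodes by default); the forward pass always uses the whole
#'   graph so message passing is unaffected.
#' @param drop_masks Optional dropout masks (internal; used during training).
#' @return List with `loss`, `grads` (same structure as `layers`) and
#'   `logits`.
#' @export
loss_and_gradients <- function(graph, layers, config, node_mask = NULL,
                               drop_masks = NULL) {
  arch <- config$architecture
  op <- if (arch == "gcn") normalize_adjacency(graph$a) else graph$a
  fw <- switch(arch,
    gcn = gcn_forward(op, graph$x, layers, config, TRUE, drop_masks),
    gat = gat_forward(op, graph$x, layers, config, TRUE, drop_masks),
    gin = gin_forward(op, graph$x, layers, config, TRUE, drop_masks))
  n <- nrow(fw$logits)
  if (is.null(node_mask)) node_mask <- seq_len(n)
  ce <- softmax_cross_entropy(fw$logits[node_mask, , drop = FALSE],
                              graph$y[node_mask, , drop = FALSE])
  dlogits <- matrix(0, n, config$n_classes)
  dlogits[node_mask, ] <- ce$grad
  grads <- switch(arch,
    gcn = gcn_backward(op, fw$cache, layers, config, dlogits, drop_masks),
    gat = gat_backward(op, fw$cache, layers, config, dlogits, drop_masks),
    gin = gin_backward(op, fw$cache, layers, config, dlogits, drop_masks))
  list(loss = ce$loss, grads = grads, logits = fw$logits)
}

#' Adam optimizer
#'
#' `adam_init()` allocates zero moment accumulators shaped like the
#' parameters; `adam_step()` applies one standard bias-corrected Adam update
#' and increments the step counter. A zero gradient leaves the parameters
#' unchanged.
#'
#' @param params Parameter list (any nesting of numeric arrays).
#' @param lr Learning rate (default 0.0001, the training default).
#' @param beta1,beta2 Moment decay rates.
#' @param eps_hat Denominator stabilizer.
#' @return `adam_init()`: an `adam_state`; `adam_step()`: a list with
#'   updated `params` and `state`.
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps_hat = 1e-8) {
  n <- n_params(params)
  structure(
    list(step = 0L, m = numeric(n), v = numeric(n), lr = lr,
         beta1 = beta1, beta2 = beta2, eps_hat = eps_hat),
    class = "adam_state")
}

#' @rdname adam_init
#' @param grads Gradient list with the same structure as `params`.
#' @param state An `adam_state`.
#' @export
adam_step <- function(params, grads, state) {
  stopifnot(inherits(state, "adam_state"))
  p <- params_flatten(params)
  g <- params_flatten(grads)
  if (length(p) != length(g)) {
    abort("Parameter and gradient shapes do not match.",
          class = "alngraph_shape_error")
  }
  t <- state$step + 1L
  m <- state$beta1 * state$m + (1 - state$beta1) * g
  v <- state$beta2 * state$v + (1 - state$beta2) * g^2
  mhat <- m / (1 - state$beta1^t)
  vhat <- v / (1 - state$beta2^t)
  p <- p - state$lr * mhat / (sqrt(vhat) + state$eps_hat)
  state$step <- t
  state$m <- m
  state$v <- v
  list(params = params_relist(p, params), state = state)
}
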