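# Dense forward passes. Cohort graphs have at most a few hundred nodes, so
# all adjacency arithmetic is dense; contracts specify results, not storage.

#' Symmetric GCN renormalization of an adjacency matrix
#'
#' Adds self-loops and applies the symmetric degree normalization:
#' `A_hat = D~^{-1/2} (A + I) D~^{-1/2}` with `D~ = diag(rowSums(A + I))`.
#'
#' @param a Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return The normalized matrix `A_hat` (symmetric; equals the identity for
#'   an edgeless graph).
#' @export
normalize_adjacency <- function(a) {
  a <- as.matrix(a)
  if (any(abs(a - t(a)) > 0) || any(diag(a) != 0)) {
    abort("`a` must be symmetric with zero diagonal.",
          class = "alngraph_parameter_error")
  }
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  at * outer(dinv, dinv)
}

act_forward <- function(z, activation) {
  switch(activation, relu = relu(z), identity = z)
}

act_grad <- function(z, activation) {
  switch(activation, relu = (z > 0) * 1, identity = array(1, dim(z)))
}

check_d_in <- function(x, W) {
  if (ncol(x) != nrow(W)) {
    abort(sprintf(
      "Feature width %d does not match parameter input width %d.",
      ncol(x), nrow(W)), class = "alngraph_shape_error")
  }
}

#' GCN forward pass
#'
#' `H_{k+1} = act(A_hat H_k W_k + b_k)` for hidden layers; the final layer is
#' linear into 2 logits.
#'
#' @param a_hat Normalized adjacency from [normalize_adjacency()].
#' @param x Node feature matrix (n x d).
#' @param layers List of layer parameters (`W`, `b`).
#' @param config A [model_config()].
#' @param keep_cache Return intermediates for backpropagation?
#' @param drop_masks Optional list of dropout masks for hidden activations.
#' @return Logit matrix (n x 2), or `list(logits, cache)` if `keep_cache`.
#' @export
gcn_forward <- function(a_hat, x, layers, config, keep_cache = FALSE,
                        drop_masks = NULL) {
  check_d_in(x, layers[[1L]]$W)
  L <- length(layers)
  h <- x
  cache <- vector("list", L)
  for (k in seq_len(L)) {
    ah <- a_hat %*% h
    z <- ah %*% layers[[k]]$W
    z <- sweep(z, 2L, layers[[k]]$b, "+")
    hout <- if (k < L) act_forward(z, config$activation) else z
    if (k < L && !is.null(drop_masks)) hout <- hout * drop_masks[[k]]
    if (keep_cache) cache[[k]] <- list(h_in = h, ah = ah, z = z)
    h <- hout
  }
  if (keep_cache) list(logits = h, cache = cache) else h
}

# mask of the closed neighbourhood used by GAT attention
gat_mask <- function(a) (a + diag(nrow(a))) > 0

#' GAT forward pass
#'
#' Per layer with single-head attention over closed neighbourhoods:
#' `z_i = W h_i`, `e_ij = LeakyReLU(a^T [z_i || z_j])` for
#' `j in N(i) + {i}`, `alpha_ij = softmax_j(e_ij)`, and
#' `h'_i = act(sum_j alpha_ij z_j)` (linear on the final layer). Each
#' attention row sums to 1 over the node's closed neighbourhood.
#'
#' @param a Symmetric 0/1 adjacency matrix with zero diagonal.
#' @inheritParams gcn_forward
#' @param layers List of layer parameters (`W`, `a`).
#' @return Logit matrix (n x 2), or `list(logits, cache)` if `keep_cache`.
#' @export
gat_forward <- function(a, x, layers, config, keep_cache = FALSE,
                        drop_masks = NULL) {
  check_d_in(x, layers[[1L]]$W)
  m <- gat_mask(a)
  L <- length(layers)
  h <- x
  cache <- vector("list", L)
  for (k in seq_len(L)) {
    W <- layers[[k]]$W
    av <- layers[[k]]$a
    do <- ncol(W)
    z <- h %*% W
    s <- as.vector(z %*% av[seq_len(do)])          # source part a_src . z_i
    tt <- as.vector(z %*% av[do + seq_len(do)])    # target part a_dst . z_j
    epre <- outer(s, tt, "+")
    e <- ifelse(epre > 0, epre, config$leaky_slope * epre)
    e[!m] <- -Inf
    alpha <- row_softmax(e)
    zmix <- alpha %*% z
    hout <- if (k < L) act_forward(zmix, config$activation) else zmix
    if (k < L && !is.null(drop_masks)) hout <- hout * drop_masks[[k]]
    if (keep_cache) {
      cache[[k]] <- list(h_in = h, z = z, epre = epre, alpha = alpha,
                         zmix = zmix)
    }
    h <- hout
  }
  if (keep_cache) list(logits = h, cache = cache) else h
}

#' GIN forward pass
#'
#' Per layer: `h'_i = MLP((1 + eps) h_i + sum_{j in N(i)} h_j)` where the MLP
#' is two affine maps with ReLU between; hidden layers apply the activation
#' to the MLP output, the final layer's MLP ends in 2 linear logits.
#'
#' @param a Symmetric 0/1 adjacency matrix with zero diagonal.
#' @inheritParams gcn_forward
#' @param layers List of layer parameters (`eps`, `W1`, `b1`, `W2`, `b2`).
#' @return Logit matrix (n x 2), or `list(logits, cache)` if `keep_cache`.
#' @export
gin_forward <- function(a, x, layers, config, keep_cache = FALSE,
                        drop_masks = NULL) {
  check_d_in(x, layers[[1L]]$W1)
  L <- length(layers)
  h <- x
  cache <- vector("list", L)
  for (k in seq_len(L)) {
    ly <- layers[[k]]
    p <- (1 + ly$eps) * h + a %*% h
    u0 <- sweep(p %*% ly$W1, 2L, ly$b1, "+")
    u <- relu(u0)
    z <- sweep(u %*% ly$W2, 2L, ly$b2, "+")
    hout <- if (k < L) act_forward(z, config$activation) else z
    if (k < L && !is.null(drop_masks)) hout <- hout * drop_masks[[k]]
    if (keep_cache) cache[[k]] <- list(h_in = h, p = p, u0 = u0, u = u, z = z)
    h <- hout
  }
  if (keep_cache) list(logits = h, cache = cache) else h
}

#' Forward pass dispatching on the configured architecture
#'
#' @param graph A `patient_graph` (or any list with `a` and `x`).
#' @param layers Parameter list matching `config`.
#' @param config A [model_config()].
#' @return Logit matrix (n x 2).
#' @export
gnn_forward <- function(graph, layers, config) {
  switch(config$architecture,
    gcn = gcn_forward(normalize_adjacency(graph$a), graph$x, layers, config),
    gat = gat_forward(graph$a, graph$x, layers, config),
    gin = gin_forward(graph$a, graph$x, layers, config))
}
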