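# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain loops, separate from the package's
# vectorized implementations.

oracle_cosine <- function(x) {
  n <- nrow(x)
  s <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s[i, j] <- sum(x[i, ] * x[j, ]) /
        (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
    }
  }
  s
}

# connected components by explicit breadth-first search
oracle_components <- function(a) {
  n <- nrow(a)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (start in seq_len(n)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (u in which(a[v, ] == 1)) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
  }
  comps
}

oracle_log_or <- function(x, y) {
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  log((n11 * n00) / (n10 * n01))
}

# AUC as the Mann-Whitney probability with tie credit 1/2, by explicit pairs
oracle_mw_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# average precision by explicit threshold enumeration and counting loops
oracle_avg_precision <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thr) {
    tp <- 0
    pp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        pp <- pp + 1
        if (y[i] == 1) tp <- tp + 1
      }
    }
    r <- tp / sum(y == 1)
    ap <- ap + (r - r_prev) * (tp / pp)
    r_prev <- r
  }
  ap
}

# explicit-loop GCN stack: symmetric renormalized neighbour average,
# linear map, ReLU between layers, linear final layer
oracle_gcn <- function(a, x, layers) {
  n <- nrow(a)
  at <- a + diag(n)
  deg <- rowSums(at)
  h <- x
  for (k in seq_along(layers)) {
    agg <- matrix(0, n, ncol(h))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (at[i, j] == 1) {
          agg[i, ] <- agg[i, ] + h[j, ] / sqrt(deg[i] * deg[j])
        }
      }
    }
    z <- agg %*% layers[[k]]$W
    for (i in seq_len(n)) z[i, ] <- z[i, ] + layers[[k]]$b
    h <- if (k < length(layers)) pmax(z, 0) else z
  }
  h
}

# explicit-loop single-head GAT stack over closed neighbourhoods
oracle_gat <- function(a, x, layers, leaky_slope = 0.2) {
  n <- nrow(a)
  h <- x
  for (k in seq_along(layers)) {
    W <- layers[[k]]$W
    av <- layers[[k]]$a
    do <- ncol(W)
    z <- h %*% W
    hout <- matrix(0, n, do)
    for (i in seq_len(n)) {
      nbrs <- unique(c(i, which(a[i, ] == 1)))
      e <- numeric(length(nbrs))
      for (m in seq_along(nbrs)) {
        raw <- sum(av * c(z[i, ], z[nbrs[m], ]))
        e[m] <- if (raw > 0) raw else leaky_slope * raw
      }
      alpha <- exp(e - max(e))
      alpha <- alpha / sum(alpha)
      for (m in seq_along(nbrs)) {
        hout[i, ] <- hout[i, ] + alpha[m] * z[nbrs[m], ]
      }
    }
    h <- if (k < length(layers)) pmax(hout, 0) else hout
  }
  h
}

# explicit-loop GIN stack: (1 + eps) self term plus neighbour sum, then MLP
oracle_gin <- function(a, x, layers) {
  n <- nrow(a)
  h <- x
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    p <- matrix(0, n, ncol(h))
    for (i in seq_len(n)) {
      p[i, ] <- (1 + ly$eps) * h[i, ]
      for (j in which(a[i, ] == 1)) p[i, ] <- p[i, ] + h[j, ]
    }
    u <- pmax(sweep(p %*% ly$W1, 2L, ly$b1, "+"), 0)
    z <- sweep(u %*% ly$W2, 2L, ly$b2, "+")
    h <- if (k < length(layers)) pmax(z, 0) else z
  }
  h
}

fd_gradient <- function(f, v, h = 1e-6) {
  vapply(seq_along(v), function(i) {
    vp <- v
    vm <- v
    vp[i] <- vp[i] + h
    vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
}

# random patient_graph-shaped fixture
make_toy_graph <- function(n = 8, d = 4, p_edge = 0.3, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) a[i, j] <- a[j, i] <- 1
      }
    }
    x <- matrix(rnorm(n * d), n, d)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) == 1L) lab[1] <- 1 - lab[1]
    structure(
      list(node_ids = sprintf("P%03d", seq_len(n)), x = x,
           y = cbind(1 - lab, lab), labels = lab, a = a,
           edges = NULL, tau = NA_real_),
      class = "patient_graph")
  })
}

# two angularly separated blobs; node features are standardized (as the
# pipeline standardizes candidate factors), after which within-blob cosine
# is near 1 and between-blob cosine near -1, so thresholding yields two
# clusters aligned with the class labels
make_separable_graph <- function(n_per = 30, seed = 1, tau = 0.9) {
  withr::with_seed(seed, {
    x0 <- cbind(rnorm(n_per, 3, 0.2), rnorm(n_per, 0.5, 0.2))
    x1 <- cbind(rnorm(n_per, 0.5, 0.2), rnorm(n_per, 3, 0.2))
    x <- rbind(x0, x1)
    x <- apply_scaler(fit_scaler(x), x)
    lab <- c(rep(0L, n_per), rep(1L, n_per))
    s <- cosine_similarity_matrix(x)
    eb <- build_edges(s, tau)
    structure(
      list(node_ids = sprintf("P%03d", seq_len(2 * n_per)), x = x,
           y = cbind(1 - lab, lab), labels = lab, a = eb$a,
           edges = eb$edges, tau = tau),
      class = "patient_graph")
  })
}

flatten_params <- function(p) unlist(p, use.names = FALSE)
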