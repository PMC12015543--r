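#' Fit a standard scaler on training features
#'
#' Per-column mean and standard deviation, with the population (divide-by-n)
#' denominator used by the common standard-scaler convention. The scaler is
#' fit on the training cohort only and then applied unchanged to the test
#' cohort, so no test information leaks into standardization.
#'
#' @param x Numeric matrix or data frame of features (>= 2 rows).
#' @return An object of class `feature_scaler` with `mean` and `sd` vectors.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    abort("Need at least two rows to fit a scaler.",
          class = "alngraph_parameter_error")
  }
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  zero <- which(sdev == 0)
  if (length(zero)) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    abort(paste0("Zero-variance column(s): ", paste(nm, collapse = ", ")),
          class = "alngraph_parameter_error")
  }
  structure(list(mean = mu, sd = sdev, features = colnames(x)),
            class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler A [fit_scaler()] object.
#' @param x Matrix or data frame with the same columns the scaler was fit on.
#' @return Standardized numeric matrix.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) {
    abort("Column count does not match the fitted scaler.",
          class = "alngraph_parameter_error")
  }
  sweep(sweep(x, 2L, scaler$mean), 2L, scaler$sd, "/")
}

#' Pairwise cosine similarity between rows
#'
#' `S[i, j] = <x_i, x_j> / (||x_i|| ||x_j||)`. The matrix is symmetric with
#' unit diagonal and entries in \[-1, 1\].
#'
#' @param x Numeric matrix (n x d); no row may have zero norm.
#' @return n x n similarity matrix.
#' @export
cosine_similarity_matrix <- function(x) {
  x <- as.matrix(x)
  norms <- sqrt(rowSums(x^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    abort(paste0("Zero-norm row(s): ", paste(zero, collapse = ", "),
                 "; cosine similarity is undefined."),
          class = "alngraph_parameter_error")
  }
  s <- tcrossprod(x / norms)
  s <- (s + t(s)) / 2          # enforce exact symmetry
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Threshold a similarity matrix into an edge set and adjacency matrix
#'
#' An unordered pair \{i, j\} (i != j) becomes an edge iff `S[i, j] >= tau`;
#' ties at exactly `tau` are included. Self-loops are never emitted (each
#' architecture handles self-connection inside its layer). Isolated nodes
#' are permitted.
#'
#' @param s Symmetric similarity matrix with unit diagonal.
#' @param tau Threshold in (-1, 1\].
#' @return List with `edges` (tibble: `i`, `j`, `similarity`, i < j) and `a`
#'   (symmetric 0/1 adjacency with zero diagonal).
#' @export
build_edges <- function(s, tau = 0.95) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= -1 || tau > 1) {
    abort("`tau` must lie in (-1, 1].", class = "alngraph_parameter_error")
  }
  n <- nrow(s)
  a <- (s >= tau) * 1
  dimnames(a) <- NULL
  diag(a) <- 0
  idx <- which(upper.tri(s) & a == 1, arr.ind = TRUE)
  edges <- tibble::tibble(
    i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]),
    similarity = s[idx])
  edges <- edges[order(edges$i, edges$j), ]
  list(edges = edges, a = a)
}

#' Assemble a patient-similarity graph from a cohort
#'
#' Standardizes the selected candidate factors with a scaler fitted on the
#' training cohort, computes row-wise cosine similarity, and connects
#' patients whose similarity reaches the threshold. Training and test cohorts
#' produce separate graphs; the trained network is applied inductively to the
#' test graph.
#'
#' @param cohort A cohort tibble.
#' @param selected Character vector of feature columns used as node features.
#' @param scaler A [fit_scaler()] object fitted on the training cohort's
#'   `selected` columns.
#' @param tau Cosine-similarity cutoff (default 0.95, inclusive).
#' @return An object of class `patient_graph`: `node_ids`, standardized
#'   feature matrix `x` (n x d), one-hot label matrix `y` (n x 2,
#'   columns = non-metastasis, metastasis), `labels` (0/1 vector), `edges`
#'   tibble, adjacency `a`, and `tau`.
#' @export
assemble_graph <- function(cohort, selected, scaler, tau = 0.95) {
  missing <- setdiff(selected, names(cohort))
  if (length(missing)) {
    abort(paste0("Selected feature(s) not in cohort: ",
                 paste(missing, collapse = ", ")),
          class = "alngraph_schema_error")
  }
  x <- apply_scaler(scaler, as.matrix(cohort[, selected, drop = FALSE]))
  rownames(x) <- cohort$patient_id
  labels <- as.integer(cohort$aln_status)
  y <- cbind(1L - labels, labels)
  colnames(y) <- c("non_alnm", "alnm")
  if (nrow(x) == 1L) {
    edges <- tibble::tibble(i = integer(), j = integer(),
                            similarity = numeric())
    a <- matrix(0, 1L, 1L)
  } else {
    s <- cosine_similarity_matrix(x)
    eb <- build_edges(s, tau)
    edges <- eb$edges
    a <- eb$a
  }
  structure(
    list(node_ids = cohort$patient_id, x = x, y = y, labels = labels,
         edges = edges, a = a, tau = tau),
    class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat(sprintf(
    "<patient_graph> %d nodes, %d edges, %d features, tau = %g\n",
    length(x$node_ids), nrow(x$edges), ncol(x$x), x$tau))
  invisible(x)
}

#' Convert a patient graph to an igraph object
#'
#' @param graph A `patient_graph`.
#' @return An undirected [igraph::graph_from_adjacency_matrix()] graph with
#'   `name` and `label` vertex attributes and `similarity` edge weights.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$a, mode = "undirected")
  igraph::V(g)$name <- graph$node_ids
  igraph::V(g)$label <- graph$labels
  if (nrow(graph$edges)) {
    # igraph preserves edge order from the adjacency upper triangle
    key_g <- apply(igraph::as_edgelist(g, names = FALSE), 1L,
                   function(e) paste(sort(e), collapse = "-"))
    key_e <- paste(graph$edges$i, graph$edges$j, sep = "-")
    igraph::E(g)$similarity <- graph$edges$similarity[match(key_g, key_e)]
  }
  g
}

#' Structural summary of a patient graph
#'
#' @param graph A `patient_graph`.
#' @return One-row tibble: node and edge counts, density, connected
#'   components, isolated nodes, and degree quartiles.
#' @export
graph_summary <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  n <- length(graph$node_ids)
  m <- nrow(graph$edges)
  deg <- rowSums(graph$a)
  comp <- as.integer(igraph::components(as_igraph(graph))$no)
  tibble::tibble(
    n_nodes = n, n_edges = m,
    density = if (n > 1) m / (n * (n - 1) / 2) else 0,
    n_components = comp,
    n_isolated = sum(deg == 0),
    degree_q25 = unname(quantile(deg, 0.25)),
    degree_median = unname(stats::median(deg)),
    degree_q75 = unname(quantile(deg, 0.75)),
    degree_max = if (n) max(deg) else 0)
}

#' Export and import the edge list of a patient graph
#'
#' TSV with columns `source_id`, `target_id`, `similarity`. Reading requires
#' the node id order so the adjacency matrix can be reconstructed exactly;
#' round-tripping preserves edges, node order and adjacency.
#'
#' @param graph A `patient_graph`.
#' @param path File path.
#' @param node_ids Ordered node ids of the graph the edges belong to.
#' @return `write_edge_tsv()` returns `path` invisibly; `read_edge_tsv()`
#'   returns a list with `edges` and adjacency `a`.
#' @export
write_edge_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "patient_graph"))
  readr::write_tsv(
    tibble::tibble(
      source_id = graph$node_ids[graph$edges$i],
      target_id = graph$node_ids[graph$edges$j],
      similarity = graph$edges$similarity),
    path)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path, node_ids) {
  tbl <- readr::read_tsv(path, col_types = "ccd")
  i <- match(tbl$source_id, node_ids)
  j <- match(tbl$target_id, node_ids)
  if (anyNA(i) || anyNA(j)) {
    abort("Edge list refers to unknown node ids.",
          class = "alngraph_schema_error")
  }
  n <- length(node_ids)
  a <- matrix(0, n, n)
  a[cbind(i, j)] <- 1
  a[cbind(j, i)] <- 1
  edges <- tibble::tibble(i = pmin(i, j), j = pmax(i, j),
                          similarity = tbl$similarity)
  edges <- edges[order(edges$i, edges$j), ]
  list(edges = edges, a = a)
}

#' Write node attributes (id, label, degree) as CSV
#'
#' @param graph A `patient_graph`.
#' @param path File path.
#' @export
write_node_csv <- function(graph, path) {
  stopifnot(inherits(graph, "patient_graph"))
  readr::write_csv(
    tibble::tibble(id = graph$node_ids, label = graph$labels,
                   degree = as.integer(rowSums(graph$a))),
    path)
  invisible(path)
}
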