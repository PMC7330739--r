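#' Construct a graph for spectral analysis
#'
#' A light container for the (optionally weighted, optionally directed)
#' graphs the package works with: temporal Bayesian-network skeletons whose
#' nodes are condition-year pairs (labels like `"TBI_Y1"`), and weighted
#' undirected co-occurrence (lexicon) graphs.
#'
#' @param labels Character vector of node labels (unique, non-empty).
#' @param edges A data frame with columns `from`, `to` (1-based node indices
#'   or node labels) and optionally `weight` (nonnegative, default 1).
#'   `NULL` or a zero-row data frame gives an edgeless graph.
#' @param directed Logical; are edges ordered pairs?
#' @return An object of class `mcc_graph`: a list with `labels`, `edges`
#'   (data frame of integer `from`, `to` and double `weight`) and
#'   `directed`.
#' @examples
#' g <- mcc_graph(c("A", "B", "C"),
#'                data.frame(from = c(1, 2), to = c(2, 3)))
#' lambda2(g)
#' @export
mcc_graph <- function(labels, edges = NULL, directed = TRUE) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) || any(!nzchar(labels)))
    stop("node labels must be unique and non-empty")
  n <- length(labels)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(), to = integer(), weight = double())
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges need 'from' and 'to' columns")
    from <- resolve_nodes(edges$from, labels)
    to <- resolve_nodes(edges$to, labels)
    weight <- if ("weight" %in% names(edges)) as.double(edges$weight)
              else rep(1, length(from))
    if (any(!is.finite(weight)) || any(weight < 0))
      stop("edge weights must be finite and nonnegative")
    if (any(from == to))
      stop("self-loops are not allowed (node ",
           labels[from[which(from == to)[1L]]], ")")
    key <- if (directed) paste(from, to) else
      paste(pmin(from, to), pmax(from, to))
    if (anyDuplicated(key)) stop("duplicate edge in edge list")
    edges <- data.frame(from = from, to = to, weight = weight)
  }
  structure(list(labels = labels, edges = edges, directed = isTRUE(directed)),
            class = "mcc_graph")
}

resolve_nodes <- function(x, labels) {
  if (is.character(x) || is.factor(x)) {
    idx <- match(as.character(x), labels)
    if (anyNA(idx)) stop("unknown node label: ", x[which(is.na(idx))[1L]])
    return(idx)
  }
  idx <- as.integer(x)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(labels)))
    stop("node index out of range [1, ", length(labels), "]")
  idx
}

#' @export
print.mcc_graph <- function(x, ...) {
  cat(sprintf("<mcc_graph> %s, %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              length(x$labels), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(g) length(g$labels)
n_edges <- function(g) nrow(g$edges)

#' Number of nodes and edges of a graph
#' @param g An [mcc_graph()].
#' @return `graph_size()` returns a named integer vector `c(nodes, edges)`.
#' @export
graph_size <- function(g) {
  stopifnot(inherits(g, "mcc_graph"))
  c(nodes = n_nodes(g), edges = n_edges(g))
}

#' Adjacency matrix of a graph
#'
#' Entry (i, j) holds the weight of edge i -> j; for undirected graphs the
#' matrix is symmetric by construction.
#'
#' @param g An [mcc_graph()].
#' @return An n x n numeric matrix with zero diagonal, dimnames from the
#'   node labels.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "mcc_graph"))
  n <- n_nodes(g)
  A <- matrix(0, n, n, dimnames = list(g$labels, g$labels))
  if (n_edges(g) > 0L) {
    A[cbind(g$edges$from, g$edges$to)] <- g$edges$weight
    if (!g$directed) A[cbind(g$edges$to, g$edges$from)] <- g$edges$weight
  }
  A
}

#' Laplacian configuration
#'
#' Chooses which Laplacian is built from a graph. `"undirected"` is the
#' combinatorial L = D - A (requires a symmetric adjacency). For directed
#' graphs two symmetrized variants are offered. `"directed_total"` (the
#' default for directed graphs) takes the total-degree Laplacian
#' L = D - A with D = diag(in-degree + out-degree) and symmetrizes it as
#' (L + L')/2; adding an edge never decreases any eigenvalue of this
#' matrix, so its second-smallest eigenvalue grows with connectivity and
#' shrinks monotonically under pruning — the behavior the sparsity
#' penalty and the pruning criterion rely on. `"directed_chung"` is the
#' normalized random-walk construction: the transition matrix (dangling
#' rows replaced by uniform) smoothed by PageRank-style teleportation and
#' symmetrized through its stationary distribution. Note that on sparse
#' acyclic graphs the teleported walk mixes *fastest* when the graph has
#' least structure, so this variant's second eigenvalue can move opposite
#' to edge count; it is provided for normalized-spectrum analyses, not as
#' the penalty default.
#'
#' @param variant One of `"undirected"`, `"directed_total"`,
#'   `"directed_chung"`.
#' @param teleport Probability of following the walk (as opposed to jumping
#'   to a uniformly random node) in the teleportation smoothing; in (0, 1].
#'   `teleport = 1` is the raw chain and is only meaningful for walks that
#'   are already ergodic. Only used by `"directed_chung"`.
#' @return A list of class `lap_config`.
#' @export
lap_config <- function(variant = c("directed_total", "undirected",
                                   "directed_chung"),
                       teleport = 0.85) {
  variant <- match.arg(variant)
  if (!is.numeric(teleport) || length(teleport) != 1L ||
      teleport <= 0 || teleport > 1)
    stop("teleport must be a single number in (0, 1]")
  structure(list(variant = variant, teleport = teleport),
            class = "lap_config")
}

default_lap_config <- function(g) {
  if (g$directed) lap_config("directed_total") else lap_config("undirected")
}

#' Graph Laplacian
#'
#' Builds the symmetric Laplacian matrix of a graph under the requested
#' variant (see [lap_config()]). All variants return a symmetric positive
#' semidefinite matrix whose smallest eigenvalue is 0 up to round-off.
#'
#' @param g An [mcc_graph()].
#' @param config A [lap_config()]; defaults to `"undirected"` for
#'   undirected graphs and `"directed_chung"` for directed ones.
#' @param tol Numerical tolerance for symmetry/PSD checks.
#' @return A symmetric n x n matrix with attributes `variant` and (for
#'   the Chung variant) `teleport`.
#' @references Chung, F. (2005). Laplacians and the Cheeger inequality for
#'   directed graphs. Annals of Combinatorics 9, 1-19.
#' @export
graph_laplacian <- function(g, config = default_lap_config(g), tol = 1e-9) {
  stopifnot(inherits(g, "mcc_graph"))
  A <- adjacency_matrix(g)
  L <- switch(config$variant,
    undirected = undirected_laplacian(A, tol = tol),
    directed_chung = directed_laplacian(A, teleport = config$teleport),
    directed_total = {
      Dt <- diag(rowSums(A) + colSums(A), nrow(A))
      Lt <- Dt - A
      (Lt + t(Lt)) / 2
    })
  attr(L, "variant") <- config$variant
  if (config$variant == "directed_chung") attr(L, "teleport") <- config$teleport
  L
}

undirected_laplacian <- function(A, tol = 1e-9) {
  if (max(abs(A - t(A))) > tol)
    stop("undirected Laplacian requires a symmetric adjacency matrix")
  diag(rowSums(A), nrow(A)) - A
}

# Chung-style directed Laplacian: row-normalize A into a transition matrix
# (dangling rows -> uniform), smooth with teleportation so the walk is
# ergodic, take its stationary distribution phi, and symmetrize:
#   L = I - (Phi^{1/2} P Phi^{-1/2} + Phi^{-1/2} P' Phi^{1/2}) / 2.
directed_laplacian <- function(A, teleport = 0.85) {
  n <- nrow(A)
  if (n == 0L || all(A == 0)) stop("directed Laplacian of an empty graph")
  if (teleport <= 0 || teleport > 1) stop("teleport must be in (0, 1]")
  rs <- rowSums(A)
  P <- A / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 1 / n
  P <- teleport * P + (1 - teleport) / n
  phi <- stationary_distribution(P)
  s <- sqrt(phi)
  M <- (s * P / rep(s, each = n) + t(P * phi) / s / rep(s, each = n))
  # second term above is Phi^{-1/2} P' Phi^{1/2}: entry (i,j) = P[j,i]*phi[j]/(s_i s_j)
  L <- diag(n) - M / 2
  (L + t(L)) / 2
}

stationary_distribution <- function(P, tol = 1e-12, max_iter = 100000L) {
  n <- nrow(P)
  if (n <= 200L) {
    # direct solve of pi' (P - I) = 0 with sum(pi) = 1
    M <- rbind(t(P) - diag(n), rep(1, n))
    b <- c(rep(0, n), 1)
    phi <- as.vector(qr.solve(M, b))
  } else {
    phi <- rep(1 / n, n)
    for (i in seq_len(max_iter)) {
      phi_new <- as.vector(crossprod(P, phi))
      phi_new <- phi_new / sum(phi_new)
      if (max(abs(phi_new - phi)) < tol) { phi <- phi_new; break }
      phi <- phi_new
    }
  }
  if (any(phi <= 0)) stop("stationary distribution not strictly positive; ",
                          "walk not ergodic (use teleport < 1)")
  phi / sum(phi)
}

#' Eigenvalues of a Laplacian and the algebraic connectivity
#'
#' `spectral_summary()` returns the full ascending spectrum of a symmetric
#' Laplacian together with the second-smallest eigenvalue (the Fiedler
#' value / algebraic connectivity); `lambda2()` is a convenience returning
#' just that scalar for a graph. "Second eigenvalue" throughout this
#' package always means the second-*smallest*: it is zero exactly when the
#' (undirected view of the) graph is disconnected, and measures the
#' sparsest cut of a connected graph.
#'
#' @param L A symmetric Laplacian matrix (see [graph_laplacian()]).
#' @param tol Eigenvalues in `[-tol, 0)` are round-off and clipped to 0;
#'   larger negative values raise an error.
#' @return `spectral_summary()`: a list of class `spectral_summary` with
#'   `eigenvalues` (ascending), `lambda2` and `tol`.
#' @export
spectral_summary <- function(L, tol = 1e-9) {
  if (!is.matrix(L) || nrow(L) != ncol(L))
    stop("L must be a square matrix")
  if (max(abs(L - t(L))) > 1e-7) stop("L must be symmetric")
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[1L] < -tol * max(1, max(abs(ev))))
    stop("Laplacian is not positive semidefinite")
  ev[ev < 0 & ev >= -max(tol, tol * max(abs(ev)))] <- 0
  structure(list(eigenvalues = ev,
                 lambda2 = if (length(ev) >= 2L) ev[2L] else NA_real_,
                 tol = tol),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> n = %d, lambda2 = %.6g\n",
              length(x$eigenvalues), x$lambda2))
  invisible(x)
}

#' @rdname spectral_summary
#' @param g An [mcc_graph()].
#' @param config A [lap_config()].
#' @export
lambda2 <- function(g, config = default_lap_config(g), tol = 1e-9) {
  if (n_nodes(g) < 2L) return(0)
  if (n_edges(g) == 0L) return(0)
  spectral_summary(graph_laplacian(g, config), tol = tol)$lambda2
}

drop_edge <- function(g, from, to) {
  hit <- which(g$edges$from == from & g$edges$to == to)
  if (!g$directed && length(hit) == 0L)
    hit <- which(g$edges$from == to & g$edges$to == from)
  if (length(hit) == 0L)
    stop("edge ", g$labels[from], " -> ", g$labels[to], " not in graph")
  g$edges <- g$edges[-hit[1L], , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Change in algebraic connectivity from removing one edge
#'
#' Temporarily removes `edge` and reports how much the second-smallest
#' Laplacian eigenvalue moves. When the graph is connected
#' (lambda2 > tol) the change is *relative*,
#' |lambda2(G) - lambda2(G \ e)| / lambda2(G); when lambda2 is already ~0
#' (disconnected graph) the absolute change is returned and flagged.
#'
#' @param g An [mcc_graph()]; not modified.
#' @param edge Length-2 vector (from, to) of node indices or labels.
#' @param config A [lap_config()].
#' @param tol Zero-eigenvalue tolerance.
#' @return A double with attribute `relative` (TRUE unless the degenerate
#'   absolute fallback was used).
#' @export
delta_lambda2 <- function(g, edge, config = default_lap_config(g),
                          tol = 1e-9) {
  stopifnot(inherits(g, "mcc_graph"), length(edge) == 2L)
  idx <- resolve_nodes(edge, g$labels)
  l2 <- lambda2(g, config, tol = tol)
  l2_removed <- lambda2(drop_edge(g, idx[1L], idx[2L]), config, tol = tol)
  if (l2 > tol) {
    structure(abs(l2 - l2_removed) / l2, relative = TRUE)
  } else {
    structure(abs(l2 - l2_removed), relative = FALSE)
  }
}

# Connected components of the undirected view; returns membership vector.
graph_components <- function(g) {
  n <- n_nodes(g)
  comp <- rep(NA_integer_, n)
  adj <- undirected_adjacency_list(g)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      stack <- c(stack, adj[[u]][is.na(comp[adj[[u]]])])
    }
  }
  comp
}

undirected_adjacency_list <- function(g) {
  n <- n_nodes(g)
  adj <- rep(list(integer()), n)
  for (k in seq_len(n_edges(g))) {
    a <- g$edges$from[k]; b <- g$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) sort(unique(v)))
}

is_connected <- function(g) n_nodes(g) <= 1L || all(graph_components(g) == 1L)

# Kahn topological sort; NULL when a cycle exists.
topological_order <- function(g) {
  n <- n_nodes(g)
  indeg <- tabulate(g$edges$to, n)
  out <- split(g$edges$to, factor(g$edges$from, levels = seq_len(n)))
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) NULL else order
}

is_dag <- function(g) !is.null(topological_order(g))
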