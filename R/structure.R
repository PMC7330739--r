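#' Pairwise mutual information of binary cohort columns
#'
#' Plug-in (maximum-likelihood) estimate of the mutual information between
#' every pair of binary columns, in natural-log units. Used as the edge
#' weight for the Chow-Liu maximum-weight spanning tree that seeds the K2
#' node ordering. Negative round-off is clipped at 0; columns that are
#' constant in the sample get MI 0 with everything (with a warning), since
#' the plug-in estimate is undefined there.
#'
#' @param cohort A cohort table (see [read_cohort()] / [sample_cohort()]):
#'   a data frame or matrix of 0/1 values, one row per patient.
#' @return A symmetric nonnegative n x n matrix with zero diagonal.
#' @export
mutual_information <- function(cohort) {
  X <- cohort_matrix(cohort)
  m <- nrow(X)
  if (m < 2L) stop("mutual information needs at least 2 rows")
  n <- ncol(X)
  p1 <- colMeans(X)
  if (any(p1 == 0 | p1 == 1))
    warning("constant column(s): ",
            paste(colnames(X)[p1 == 0 | p1 == 1], collapse = ", "),
            "; MI set to 0 by convention")
  N11 <- crossprod(X)
  c1 <- as.vector(colSums(X))
  N10 <- outer(c1, rep(1, n)) - N11          # x=1, y=0
  N01 <- t(N10)
  N00 <- m - N11 - N10 - N01
  plogterm <- function(Nxy, Nx, Ny) {
    t <- matrix(0, n, n)
    pos <- Nxy > 0
    t[pos] <- (Nxy[pos] / m) * log(m * Nxy[pos] / (Nx[pos] * Ny[pos]))
    t
  }
  cx1 <- outer(c1, rep(1, n)); cx0 <- m - cx1
  cy1 <- t(cx1); cy0 <- m - cy1
  mi <- plogterm(N00, cx0, cy0) + plogterm(N01, cx0, cy1) +
        plogterm(N10, cx1, cy0) + plogterm(N11, cx1, cy1)
  mi[mi < 0] <- 0
  diag(mi) <- 0
  const <- p1 == 0 | p1 == 1
  mi[const, ] <- 0; mi[, const] <- 0
  dimnames(mi) <- list(colnames(X), colnames(X))
  mi
}

#' Maximum-weight spanning tree node ordering
#'
#' Prim's algorithm over a symmetric weight matrix (pairwise mutual
#' information in the Chow-Liu use), with deterministic tie-breaking by the
#' smaller node-index pair, followed by a breadth-first traversal from the
#' root to produce the K2 node ordering.
#'
#' @param mi Symmetric nonnegative weight matrix.
#' @param root Root node index; default the node with the largest total
#'   weight (ties by smaller index).
#' @return A list of class `node_ordering`: `order` (permutation of node
#'   indices), `tree` (data frame of undirected tree edges `from < to`),
#'   `root` and `provenance = "mwst"`.
#' @export
mwst_ordering <- function(mi, root = NULL) {
  n <- nrow(mi)
  if (is.null(n) || n == 0L) stop("empty weight matrix")
  if (max(abs(mi - t(mi))) > 1e-12) stop("weight matrix must be symmetric")
  if (is.null(root)) root <- which.max(rowSums(mi))  # ties -> smaller index
  root <- as.integer(root)
  in_tree <- rep(FALSE, n); in_tree[root] <- TRUE
  tree <- data.frame(from = integer(), to = integer())
  adj <- rep(list(integer()), n)
  for (k in seq_len(n - 1L)) {
    best <- c(-Inf, NA_integer_, NA_integer_)  # weight, inside, outside
    for (u in which(in_tree)) for (v in which(!in_tree)) {
      w <- mi[u, v]
      a <- min(u, v); b <- max(u, v)
      if (w > best[1L] ||
          (w == best[1L] &&
           (a < min(best[2L], best[3L]) ||
            (a == min(best[2L], best[3L]) && b < max(best[2L], best[3L]))))) {
        best <- c(w, u, v)
      }
    }
    u <- best[2L]; v <- best[3L]
    in_tree[v] <- TRUE
    tree <- rbind(tree, data.frame(from = min(u, v), to = max(u, v)))
    adj[[u]] <- sort(c(adj[[u]], v)); adj[[v]] <- sort(c(adj[[v]], u))
  }
  # BFS from root, neighbors in index order
  visited <- rep(FALSE, n); visited[root] <- TRUE
  order <- root; queue <- root
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (v in adj[[u]]) if (!visited[v]) {
      visited[v] <- TRUE; order <- c(order, v); queue <- c(queue, v)
    }
  }
  structure(list(order = order, tree = tree, root = root,
                 provenance = "mwst"),
            class = "node_ordering")
}

#' K2 (Cooper-Herskovits) local score of a node given a parent set
#'
#' Log marginal likelihood of the node's data under a uniform Dirichlet
#' prior, for binary variables (r = 2):
#' sum over parent configurations j of
#' \code{log (r-1)! - log (N_j + r - 1)! + sum_k log N_jk!},
#' evaluated with `lgamma` for stability.
#'
#' @param node Column index or name of the child in `cohort`.
#' @param parents Integer/character vector of parent columns (may be empty).
#' @param cohort Binary cohort table.
#' @return A single double (log scale; larger is better).
#' @export
k2_local_score <- function(node, parents, cohort) {
  cnt <- family_counts(node, parents, cohort)   # 2 x (configs) matrix
  Nj <- colSums(cnt)
  sum(lgamma(2) - lgamma(Nj + 2) + lgamma(cnt[1L, ] + 1) +
        lgamma(cnt[2L, ] + 1))
}

#' AIC local score of a node given a parent set
#'
#' Maximized multinomial log-likelihood minus the number of free parameters
#' \code{(r - 1) * r^|parents|}; larger is better. Empty cells contribute 0
#' via the `0 * log 0 = 0` convention.
#'
#' @inheritParams k2_local_score
#' @return A single double.
#' @export
aic_local_score <- function(node, parents, cohort) {
  cnt <- family_counts(node, parents, cohort)
  Nj <- colSums(cnt)
  pos <- cnt > 0
  Njm <- rbind(Nj, Nj)
  ll <- sum(cnt[pos] * log(cnt[pos] / Njm[pos]))
  ll - 2^length(parents)
}

# 2 x 2^{|parents|} table of child-value counts per parent configuration.
family_counts <- function(node, parents, cohort) {
  X <- cohort_matrix(cohort)
  if (nrow(X) == 0L) stop("empty cohort")
  node <- resolve_cols(node, X)
  parents <- resolve_cols(parents, X)
  y <- X[, node]
  k <- length(parents)
  if (k == 0L) {
    return(matrix(c(sum(y == 0), sum(y == 1)), nrow = 2L))
  }
  q <- as.vector(X[, parents, drop = FALSE] %*% 2^(seq_len(k) - 1L))
  cnt0 <- tabulate(q + 1L, nbins = 2^k) - tabulate(q[y == 1] + 1L, nbins = 2^k)
  cnt1 <- tabulate(q[y == 1] + 1L, nbins = 2^k)
  rbind(cnt0, cnt1)
}

resolve_cols <- function(x, X) {
  if (length(x) == 0L) return(integer())
  if (is.character(x)) {
    idx <- match(x, colnames(X))
    if (anyNA(idx)) stop("unknown column: ", x[which(is.na(idx))[1L]])
    idx
  } else as.integer(x)
}

#' Scoring configuration for structure learning
#'
#' @param score_family `"k2"` (Cooper-Herskovits marginal likelihood,
#'   the default) or `"aic"`.
#' @param lam Nonnegative tuning parameter of the spectral penalty
#'   `lam * lambda2(graph)`; `lam = 0` is the unpenalized score.
#' @param max_parents Cap on parents per node (default 5).
#' @param penalty_reference `"candidate"` (default; the penalty is
#'   evaluated on the graph including each tested edge) or `"previous"`
#'   (penalty frozen at the last accepted graph).
#' @param laplacian A [lap_config()] used for the penalty.
#' @param intra_year Allow same-year edges (earlier condition in the
#'   declared condition order -> later)? Default TRUE.
#' @return A list of class `score_config`.
#' @export
score_config <- function(score_family = c("k2", "aic"), lam = 0,
                         max_parents = 5L,
                         penalty_reference = c("candidate", "previous"),
                         laplacian = lap_config("directed_total"),
                         intra_year = TRUE) {
  score_family <- match.arg(score_family)
  penalty_reference <- match.arg(penalty_reference)
  if (!is.numeric(lam) || lam < 0) stop("lam must be >= 0")
  structure(list(score_family = score_family, lam = lam,
                 max_parents = as.integer(max_parents),
                 penalty_reference = penalty_reference,
                 laplacian = laplacian, intra_year = isTRUE(intra_year)),
            class = "score_config")
}

local_score_fun <- function(config) {
  switch(config$score_family, k2 = k2_local_score, aic = aic_local_score)
}

#' Total spectrally penalized score of a structure
#'
#' Sum of per-node local scores minus `lam * lambda2` of the structure's
#' Laplacian (the EAGL regularizer). Under the default total-degree
#' variant, adding an edge never decreases any Laplacian eigenvalue, so
#' the penalty consistently favors sparser structures; it is zero (hence
#' inert) while the structure leaves two or more nodes untouched, and
#' starts to bite once the graph spans its nodes — the regime of a dense
#' or spurious-edge-contaminated model.
#'
#' @param graph An acyclic [mcc_graph()] whose labels are cohort columns.
#' @param cohort Binary cohort table covering all nodes.
#' @param config A [score_config()].
#' @return A double with attributes `data_score` and `lambda2`.
#' @export
penalized_total_score <- function(graph, cohort, config = score_config()) {
  if (!is_dag(graph)) stop("structure must be acyclic")
  fscore <- local_score_fun(config)
  parents <- parent_sets(graph)
  data_score <- sum(vapply(seq_along(graph$labels), function(i) {
    fscore(graph$labels[i], graph$labels[parents[[i]]], cohort)
  }, numeric(1)))
  l2 <- lambda2(graph, config$laplacian)
  structure(data_score - config$lam * l2,
            data_score = data_score, lambda2 = l2)
}

parent_sets <- function(graph) {
  n <- n_nodes(graph)
  ps <- rep(list(integer()), n)
  for (k in seq_len(n_edges(graph)))
    ps[[graph$edges$to[k]]] <- c(ps[[graph$edges$to[k]]], graph$edges$from[k])
  ps
}

# Parse "COND_Y3" -> list(condition = "COND", year = 3L); NA year if not
# in temporal form.
parse_node_label <- function(labels) {
  m <- regmatches(labels, regexec("^(.*)_Y([0-9]+)$", labels))
  cond <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_,
                 character(1))
  year <- vapply(m, function(x) if (length(x) == 3L) as.integer(x[3L])
                 else NA_integer_, integer(1))
  list(condition = cond, year = year)
}

# Allowed-parent matrix under the temporal constraint: parent (c_i, y_s) ->
# child (c_j, y_t) iff s < t, or (intra_year) s == t and i < j in the
# condition order of first appearance. Non-temporal labels: all i != j.
allowed_parent_matrix <- function(labels, intra_year = TRUE) {
  n <- length(labels)
  pl <- parse_node_label(labels)
  allowed <- matrix(FALSE, n, n)   # [parent, child]
  if (anyNA(pl$year)) {
    allowed[] <- TRUE
  } else {
    conds <- unique(pl$condition)
    ci <- match(pl$condition, conds)
    for (p in seq_len(n)) for (ch in seq_len(n)) {
      allowed[p, ch] <- pl$year[p] < pl$year[ch] ||
        (intra_year && pl$year[p] == pl$year[ch] && ci[p] < ci[ch])
    }
  }
  diag(allowed) <- FALSE
  allowed
}

#' Learn a sparse temporal Bayesian network with a spectral penalty
#'
#' The fitting function of the package. A Chow-Liu maximum-weight spanning
#' tree over pairwise mutual information gives the node ordering (refined,
#' for temporal condition-year columns, so that year is nondecreasing along
#' it); a K2-style greedy sweep then adds, per node, the admissible parent
#' that most improves the penalized score
#' \code{local score - lam * lambda2(graph)} until no addition improves it
#' or `max_parents` is reached. `lam = 0` reproduces plain MWST + K2.
#' Conditional probability tables are then estimated on the full cohort so
#' the returned object supports prediction.
#'
#' @param cohort Binary cohort table; columns named `<COND>_Y<k>` for
#'   temporal networks.
#' @param lam Spectral penalty weight (overrides `config$lam`).
#' @param config A [score_config()].
#' @param ordering Optional [mwst_ordering()]-style object or integer
#'   permutation to use instead of the MWST ordering.
#' @param root Optional MWST root (see [mwst_ordering()]).
#' @param pseudo_count Additive smoothing for the CPT estimates.
#' @return An object of class `eagl_fit`: list with `graph`
#'   ([mcc_graph()]), `net` (an `mcc_bn`, see [fit_cpts()]),
#'   `local_scores`, `score` (penalized total), `data_score`, `lambda2`,
#'   `lambda2_trace` (after each accepted edge), `ordering`, `config`.
#' @examples
#' net <- make_ground_truth(bn_spec(conditions = c("A", "B"), years = 2))
#' co <- sample_cohort(net, 500, seed = 1)
#' fit <- eagl_learn(co, lam = 0)
#' fit
#' @export
eagl_learn <- function(cohort, lam = NULL, config = score_config(),
                       ordering = NULL, root = NULL, pseudo_count = 1) {
  X <- cohort_matrix(cohort)
  labels <- colnames(X)
  n <- ncol(X)
  if (!is.null(lam)) config$lam <- lam
  fscore <- local_score_fun(config)

  if (is.null(ordering)) {
    mi <- mutual_information(X)
    ordering <- mwst_ordering(mi, root = root)
  } else if (is.numeric(ordering)) {
    ordering <- structure(list(order = as.integer(ordering), tree = NULL,
                               root = ordering[[1L]], provenance = "user"),
                          class = "node_ordering")
  }
  ord <- ordering$order
  pl <- parse_node_label(labels)
  if (!anyNA(pl$year)) {   # temporal refinement: stable sort by year
    ord <- ord[order(pl$year[ord])]
    ordering$order <- ord
    ordering$provenance <- paste0(ordering$provenance, "+temporal")
  }
  allowed <- allowed_parent_matrix(labels, config$intra_year)
  pos <- match(seq_len(n), ord)   # position of each node in the ordering

  graph <- mcc_graph(labels, directed = TRUE)
  local <- vapply(seq_len(n), function(i) fscore(i, integer(), X), numeric(1))
  parents <- rep(list(integer()), n)
  l2_current <- 0
  lambda2_trace <- numeric(0)

  pen_l2 <- function(g) lambda2(g, config$laplacian)

  for (child in ord) {
    pool <- which(allowed[, child] & pos < pos[child])
    repeat {
      if (length(parents[[child]]) >= config$max_parents) break
      cand <- setdiff(pool, parents[[child]])
      if (length(cand) == 0L) break
      best_gain <- 1e-12; best_p <- NA_integer_   # require a strict gain
      best_local <- NA_real_; best_l2 <- NA_real_
      for (p in cand) {
        new_local <- fscore(child, c(parents[[child]], p), X)
        if (config$penalty_reference == "candidate") {
          g_cand <- graph
          g_cand$edges <- rbind(g_cand$edges,
                                data.frame(from = p, to = child, weight = 1))
          new_l2 <- pen_l2(g_cand)
        } else {
          new_l2 <- l2_current
        }
        gain <- (new_local - config$lam * new_l2) -
          (local[child] - config$lam * l2_current)
        if (gain > best_gain) {   # ties keep the earlier (smaller-index) parent
          best_gain <- gain; best_p <- p
          best_local <- new_local; best_l2 <- new_l2
        }
      }
      if (is.na(best_p)) break
      parents[[child]] <- c(parents[[child]], best_p)
      graph$edges <- rbind(graph$edges,
                           data.frame(from = best_p, to = child, weight = 1))
      local[child] <- best_local
      l2_current <- pen_l2(graph)
      lambda2_trace <- c(lambda2_trace, l2_current)
    }
  }
  rownames(graph$edges) <- NULL
  stopifnot(is_dag(graph))
  total <- sum(local) - config$lam * l2_current
  net <- fit_cpts(graph, X, pseudo_count = pseudo_count)
  structure(list(graph = graph, net = net, local_scores = local,
                 score = total, data_score = sum(local),
                 lambda2 = l2_current, lambda2_trace = lambda2_trace,
                 ordering = ordering, config = config,
                 n_obs = nrow(X)),
            class = "eagl_fit")
}

#' Learn structures across a grid of penalty weights
#'
#' Runs [eagl_learn()] for each value of `lam_grid` (the canonical grid is
#' 0, 1e-2, 1e-1, ..., 1e5) and optionally stops enlarging lambda once the
#' algebraic connectivity of the learned graph changes by less than
#' `stop_tol` between consecutive grid points.
#'
#' @inheritParams eagl_learn
#' @param lam_grid Numeric vector of penalty weights.
#' @param early_stop Apply the lambda2-stabilization stopping rule?
#' @param stop_tol Change in lambda2 below which the sweep stops.
#' @return A list of class `eagl_sweep`: `fits` (one `eagl_fit` per
#'   visited grid point, named by lambda), `summary` data frame with
#'   columns `lam`, `edges`, `lambda2`, `score`.
#' @export
eagl_sweep <- function(cohort, lam_grid = c(0, 10^(-2:5)),
                       config = score_config(), early_stop = FALSE,
                       stop_tol = 1e-6, ...) {
  fits <- list()
  prev_l2 <- NULL
  for (lam in lam_grid) {
    fit <- eagl_learn(cohort, lam = lam, config = config, ...)
    fits[[as.character(lam)]] <- fit
    if (early_stop && !is.null(prev_l2) &&
        abs(fit$lambda2 - prev_l2) < stop_tol) break
    prev_l2 <- fit$lambda2
  }
  summary <- data.frame(
    lam = as.numeric(names(fits)),
    edges = vapply(fits, function(f) n_edges(f$graph), integer(1)),
    lambda2 = vapply(fits, function(f) f$lambda2, numeric(1)),
    score = vapply(fits, function(f) f$score, numeric(1)),
    row.names = NULL)
  structure(list(fits = fits, summary = summary), class = "eagl_sweep")
}

#' @export
print.eagl_sweep <- function(x, ...) {
  cat("<eagl_sweep> over", nrow(x$summary), "penalty weights\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.eagl_fit <- function(x, ...) {
  cat(sprintf(
    "EAGL structure fit (%s score, lambda = %g)\n  %d nodes, %d edges, lambda2 = %.4f, penalized score = %.2f\n",
    x$config$score_family, x$config$lam, n_nodes(x$graph),
    n_edges(x$graph), x$lambda2, x$score))
  invisible(x)
}

#' @export
summary.eagl_fit <- function(object, ...) {
  g <- object$graph
  el <- data.frame(from = g$labels[g$edges$from], to = g$labels[g$edges$to])
  out <- list(edges = el, n_nodes = n_nodes(g), n_edges = n_edges(g),
              lambda2 = object$lambda2, score = object$score,
              data_score = object$data_score, lam = object$config$lam,
              score_family = object$config$score_family,
              n_obs = object$n_obs)
  class(out) <- "summary.eagl_fit"
  out
}

#' @export
print.summary.eagl_fit <- function(x, ...) {
  cat(sprintf("EAGL fit: %d nodes, %d edges (m = %d observations)\n",
              x$n_nodes, x$n_edges, x$n_obs))
  cat(sprintf("  score family %s, lambda %g\n", x$score_family, x$lam))
  cat(sprintf("  data score %.3f, lambda2 %.4f, penalized %.3f\n",
              x$data_score, x$lambda2, x$score))
  cat("Edges:\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' @export
coef.eagl_fit <- function(object, ...) coef(object$net, ...)

#' Predict future-condition probabilities from a fitted structure
#'
#' @param object An `eagl_fit`.
#' @param newdata Cohort rows supplying year-1 evidence.
#' @param condition,year Target condition name and year (>= 2).
#' @param ... Passed to [predict_future()].
#' @return Numeric vector of posterior probabilities, one per row.
#' @export
predict.eagl_fit <- function(object, newdata, condition, year, ...) {
  predict_future(object$net, newdata, condition = condition, year = year, ...)
}

#' @export
simulate.eagl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sample_cohort(object$net, m = nsim, seed = seed)
}

#' Plot the algebraic-connectivity trace of a fit or sweep
#'
#' For an `eagl_fit`, lambda2 after each accepted edge; for an
#' `eagl_sweep`, lambda2 and edge count against the penalty weight.
#'
#' @param x An `eagl_fit` or `eagl_sweep`.
#' @param ... Passed to [plot()].
#' @export
plot.eagl_fit <- function(x, ...) {
  plot(seq_along(x$lambda2_trace), x$lambda2_trace, type = "b",
       xlab = "accepted edge", ylab = expression(lambda[2]),
       main = "Algebraic connectivity during structure growth", ...)
  invisible(x)
}

#' @export
plot.eagl_sweep <- function(x, ...) {
  s <- x$summary
  lamx <- log10(pmax(s$lam, min(s$lam[s$lam > 0]) / 10))
  plot(lamx, s$lambda2, type = "b", xlab = "log10(lambda)",
       ylab = expression(lambda[2]),
       main = "Penalty weight vs algebraic connectivity", ...)
  invisible(x)
}
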