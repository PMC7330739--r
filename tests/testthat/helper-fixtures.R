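# Shared fixtures and independent oracles for the test suite.

cohort_fixture <- function(net, m, seed) sample_cohort(net, m, seed = seed)

# Random undirected graph on n nodes with edge probability p.
random_undirected_graph <- function(n, p = 0.4, seed = 1, weighted = FALSE) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  if (weighted) edges$weight <- round(runif(nrow(edges), 0.5, 3), 2)
  mcc_graph(paste0("n", seq_len(n)), edges, directed = FALSE)
}

# Random connected undirected graph: random tree + extra edges.
random_connected_graph <- function(n, extra = 3, seed = 1) {
  set.seed(seed)
  to <- if (n > 1) vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
        else integer(0)
  edges <- data.frame(from = pmin(to, 2:n), to = pmax(to, 2:n))
  pairs <- t(combn(n, 2))
  key <- paste(pairs[, 1], pairs[, 2])
  free <- which(!(key %in% paste(edges$from, edges$to)))
  add <- sample(free, min(extra, length(free)))
  edges <- rbind(edges, data.frame(from = pairs[add, 1], to = pairs[add, 2]))
  mcc_graph(paste0("n", seq_len(n)), edges, directed = FALSE)
}

# Random DAG over n nodes: edges only i -> j for i < j.
random_dag <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  mcc_graph(paste0("n", seq_len(n)),
            data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
            directed = TRUE)
}

# Number of connected components by breadth-first search (independent of
# the package's internal component routine in spirit: only uses the edge
# list).
count_components <- function(g) {
  n <- length(g$labels)
  if (n == 0) return(0L)
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges$from[k]; b <- g$edges$to[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, n); ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    q <- s
    while (length(q)) {
      v <- q[[1]]; q <- q[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      q <- c(q, adj[[v]][!seen[adj[[v]]]])
    }
  }
  ncomp
}

# Exact posterior by brute-force enumeration over all completions.
enumeration_posterior <- function(net, evidence, query) {
  labs <- net$graph$labels
  free <- setdiff(labs, names(evidence))
  num <- 0; den <- 0
  for (b in 0:(2^length(free) - 1)) {
    bits <- as.integer(intToBits(b)[seq_along(free)])
    a <- c(evidence, stats::setNames(bits, free))[labs]
    p <- joint_probability(net, a)
    den <- den + p
    if (a[[query]] == 1L) num <- num + p
  }
  num / den
}

# Exact-rational K2 oracle: ratio of factorial products, computed with
# exact small-integer factorials (valid for <= 8 observations).
k2_oracle_exact <- function(node, parents, cohort) {
  X <- if (is.matrix(cohort)) cohort else as.matrix(cohort)
  y <- X[, node]
  k <- length(parents)
  cfgs <- if (k == 0) matrix(0L, nrow(X), 1) else
    X[, parents, drop = FALSE]
  id <- apply(cfgs, 1, paste, collapse = "")
  log_val <- 0
  for (grp in split(seq_len(nrow(X)), id)) {
    n1 <- sum(y[grp] == 1); n0 <- sum(y[grp] == 0)
    log_val <- log_val +
      log(factorial(n0) * factorial(n1) / factorial(n0 + n1 + 1))
  }
  log_val
}

# Plain (unpenalized) K2 reference: independent greedy implementation.
k2_reference <- function(cohort, ordering, max_parents = 5) {
  X <- if (is.matrix(cohort)) cohort else as.matrix(cohort)
  n <- ncol(X)
  parents <- rep(list(integer()), n)
  total <- 0
  for (pos in seq_along(ordering)) {
    child <- ordering[pos]
    pool <- ordering[seq_len(pos - 1)]
    sc <- k2_local_score(child, integer(), X)
    repeat {
      if (length(parents[[child]]) >= max_parents) break
      cand <- setdiff(pool, parents[[child]])
      if (!length(cand)) break
      scores <- vapply(cand, function(p)
        k2_local_score(child, c(parents[[child]], p), X), numeric(1))
      if (max(scores) <= sc + 1e-12) break
      best <- cand[which.max(scores)]
      parents[[child]] <- c(parents[[child]], best)
      sc <- max(scores)
    }
    total <- total + sc
  }
  list(parents = parents, score = total)
}

edge_set_strings <- function(g) {
  sort(paste(g$labels[g$edges$from], g$labels[g$edges$to], sep = "->"))
}

edge_f1 <- function(estimated, truth) {
  e <- edge_set_strings(estimated); t <- edge_set_strings(truth)
  tp <- length(intersect(e, t))
  if (length(e) == 0 || tp == 0) return(0)
  prec <- tp / length(e); rec <- tp / length(t)
  2 * prec * rec / (prec + rec)
}

# Brute-force greedy single-edge summarization driver: at each step,
# recompute delta-lambda2 for every non-protected edge from scratch and
# remove the argmin (ties by source,target). Independent of the package's
# eagl_summarize loop.
brute_force_summarize <- function(g, steps,
                                  config = eagl:::default_lap_config(g),
                                  roots = eagl:::default_roots(g)) {
  prot <- protected_edges(g, roots)
  prot_keys <- paste(g$edges$from[prot], g$edges$to[prot])
  removed <- data.frame(from = integer(), to = integer())
  for (s in seq_len(steps)) {
    keys <- paste(g$edges$from, g$edges$to)
    cand <- which(!(keys %in% prot_keys))
    if (!length(cand)) break
    deltas <- vapply(cand, function(k)
      as.numeric(delta_lambda2(g, c(g$edges$from[k], g$edges$to[k]),
                               config)), numeric(1))
    ord <- order(deltas, g$edges$from[cand], g$edges$to[cand])
    pick <- cand[ord[1]]
    removed <- rbind(removed, data.frame(from = g$edges$from[pick],
                                         to = g$edges$to[pick]))
    g <- eagl:::drop_edge(g, g$edges$from[pick], g$edges$to[pick])
  }
  list(graph = g, removed = removed)
}
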