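#' Specification of a synthetic temporal ground-truth network
#'
#' Describes a layered binary Bayesian network over (condition, year)
#' nodes: baseline prevalences, year-to-year persistence of each
#' condition, and cross-condition edges with log-odds effect sizes. The
#' conditional probability of each node is built from a logistic link:
#' \code{logit P(node = 1 | pa) = logit(prevalence) + sum of effects over
#' active parents}.
#'
#' The default emulates a five-condition (TBI, PTSD, BaPa, SuAb, Depr),
#' five-year layered network with 18 true edges: full year-to-year
#' persistence for PTSD, BaPa and Depr (12 edges), short-range
#' persistence for TBI (year 1 to 2) and SuAb (years 1-4, 3 edges) —
#' brain-injury recurrence fades while the chronic conditions carry
#' forward — plus two cross-condition links, TBI_Y1 -> PTSD_Y2 and
#' PTSD_Y1 -> Depr_Y2. Every condition has an informative year-1 parent
#' for its year-2 node, and no node has more than two parents, so every
#' parent configuration keeps enough probability mass to be estimable
#' from moderate cohorts.
#'
#' @param conditions Character vector of condition names.
#' @param years Number of yearly layers T (>= 2).
#' @param prevalence Year-1 prevalences in (0, 1), recycled over
#'   conditions.
#' @param onset Baseline probability of spontaneous onset for year >= 2
#'   nodes (no active parents); default half the prevalence, reflecting
#'   that incident onset in a year is rarer than prevalent status.
#' @param edges Data frame with columns `from`, `to` (node labels
#'   `<COND>_Y<k>`) and `effect` (log-odds); `NULL` builds the default
#'   pattern below.
#' @param persistence Log-odds carried by the default same-condition
#'   year-to-year edges.
#' @param cross_effect Log-odds of the default cross-condition edges.
#' @return A list of class `bn_spec`.
#' @export
bn_spec <- function(conditions = c("TBI", "PTSD", "BaPa", "SuAb", "Depr"),
                    years = 5L,
                    prevalence = c(0.20, 0.30, 0.35, 0.20, 0.30),
                    onset = prevalence / 2,
                    edges = NULL, persistence = 2.2, cross_effect = 1.2) {
  years <- as.integer(years)
  if (years < 2L) stop("years must be >= 2")
  prevalence <- rep_len(prevalence, length(conditions))
  onset <- rep_len(onset, length(conditions))
  if (any(prevalence <= 0 | prevalence >= 1) ||
      any(onset <= 0 | onset >= 1))
    stop("prevalences and onset rates must be in (0, 1)")
  names(prevalence) <- conditions
  names(onset) <- conditions
  if (is.null(edges)) edges <- default_truth_edges(conditions, years,
                                                   persistence, cross_effect)
  stopifnot(all(c("from", "to", "effect") %in% names(edges)))
  spec <- structure(list(conditions = conditions, years = years,
                         prevalence = prevalence, onset = onset,
                         edges = edges),
                    class = "bn_spec")
  validate_temporal_edges(spec)
  spec
}

default_truth_edges <- function(conditions, years, persistence,
                                cross_effect) {
  # years of persistence per condition: chronic conditions carry across
  # every year; TBI recurrence fades after year 2, SuAb after year 4
  span <- function(cond, upto) {
    if (!cond %in% conditions) return(NULL)
    y <- seq_len(min(upto, years) - 1L)
    data.frame(from = paste0(cond, "_Y", y), to = paste0(cond, "_Y", y + 1L),
               effect = persistence)
  }
  rows <- list(span("PTSD", years), span("BaPa", years),
               span("Depr", years), span("TBI", 2L), span("SuAb", 4L))
  if (all(vapply(rows, is.null, logical(1))))
    rows <- lapply(conditions, span, upto = years)
  cross <- list(c("TBI", "PTSD", 1L), c("PTSD", "Depr", 1L))
  for (cr in cross) {
    if (!all(cr[1:2] %in% conditions)) next
    y <- min(as.integer(cr[3L]), years - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      from = paste0(cr[1L], "_Y", y), to = paste0(cr[2L], "_Y", y + 1L),
      effect = cross_effect)
  }
  unique(do.call(rbind, rows))
}

validate_temporal_edges <- function(spec) {
  labs <- spec_labels(spec)
  pf <- parse_node_label(spec$edges$from)
  pt <- parse_node_label(spec$edges$to)
  if (!all(spec$edges$from %in% labs) || !all(spec$edges$to %in% labs))
    stop("edge endpoint outside the condition-year grid")
  ci <- match(pf$condition, spec$conditions)
  cj <- match(pt$condition, spec$conditions)
  ok <- pf$year < pt$year | (pf$year == pt$year & ci < cj)
  if (!all(ok))
    stop("edge violates the temporal constraint: ",
         spec$edges$from[!ok][1L], " -> ", spec$edges$to[!ok][1L])
  invisible(spec)
}

spec_labels <- function(spec) {
  as.vector(t(outer(spec$conditions, seq_len(spec$years),
                    function(c, y) paste0(c, "_Y", y))))
}

#' Build the ground-truth temporal Bayesian network of a specification
#'
#' Deterministically constructs the `mcc_bn` implied by a [bn_spec()]:
#' nodes in condition-major, year-minor order, the spec's edges, and
#' logistic-link conditional probability tables. Effects with magnitude
#' above 30 are capped (a logistic saturation bound: the child becomes a
#' near-copy of the parent).
#'
#' @param spec A [bn_spec()].
#' @return An `mcc_bn` carrying the generating spec in attribute
#'   `gen_spec`.
#' @export
make_ground_truth <- function(spec = bn_spec()) {
  stopifnot(inherits(spec, "bn_spec"))
  labs <- spec_labels(spec)
  g <- mcc_graph(labs, data.frame(from = spec$edges$from,
                                  to = spec$edges$to), directed = TRUE)
  pl <- parse_node_label(labs)
  effects <- spec$edges$effect
  effects <- pmax(pmin(effects, 30), -30)
  parents <- parent_sets(g)
  edge_key <- paste(match(spec$edges$from, labs), match(spec$edges$to, labs))
  onset <- spec$onset %||% spec$prevalence
  cpts <- lapply(seq_along(labs), function(i) {
    pa <- parents[[i]]
    k <- length(pa)
    base <- stats::qlogis(if (pl$year[i] == 1L)
      spec$prevalence[[pl$condition[i]]] else onset[[pl$condition[i]]])
    eff <- vapply(pa, function(p)
      effects[match(paste(p, i), edge_key)], numeric(1))
    cfg <- lapply(seq_len(2^k) - 1L, function(j)
      as.integer(intToBits(j)[seq_len(max(k, 1))][seq_len(k)]))
    p1 <- vapply(cfg, function(bits)
      stats::plogis(base + sum(eff * bits)), numeric(1))
    list(node = labs[i], parents = labs[pa],
         table = data.frame(config = I(cfg), p1 = p1,
                            n = NA_real_, flagged = FALSE))
  })
  names(cpts) <- labs
  structure(list(graph = g, cpts = cpts, pseudo_count = NA_real_),
            class = "mcc_bn", gen_spec = spec)
}

#' Three-condition recovery benchmark specification
#'
#' A compact 15-node ground truth (3 conditions x 5 years, 18 true edges:
#' 12 persistence plus 6 cross-condition links) used to benchmark
#' structure recovery of [eagl_learn()] at moderate sample sizes.
#'
#' @inheritParams bn_spec
#' @return A [bn_spec()].
#' @export
bn_spec_recovery <- function(persistence = 2.2, cross_effect = 1.2) {
  conds <- c("TBI", "PTSD", "Depr")
  persist <- do.call(rbind, lapply(conds, function(cc)
    data.frame(from = paste0(cc, "_Y", 1:4), to = paste0(cc, "_Y", 2:5),
               effect = persistence)))
  cross <- data.frame(
    from = c("TBI_Y1", "TBI_Y2", "PTSD_Y1", "PTSD_Y2", "TBI_Y1", "PTSD_Y3"),
    to   = c("PTSD_Y2", "PTSD_Y3", "Depr_Y2", "Depr_Y3", "Depr_Y2",
             "Depr_Y4"),
    effect = cross_effect)
  bn_spec(conditions = conds, years = 5L,
          prevalence = c(0.10, 0.25, 0.25),
          edges = rbind(persist, cross))
}

#' Sample a synthetic patient cohort from a network
#'
#' Ancestral sampling in topological order; fully reproducible given the
#' seed. `simulate()` on an `mcc_bn` is an alias.
#'
#' @param net An `mcc_bn`.
#' @param m Number of patients (rows); `m = 0` gives an empty table with
#'   the right header.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A data frame of class `cohort_table`: `patient_id` plus one 0/1
#'   integer column per node.
#' @export
sample_cohort <- function(net, m, seed = NULL) {
  stopifnot(inherits(net, "mcc_bn"), m >= 0)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  labs <- net$graph$labels
  topo <- topological_order(net$graph)
  X <- matrix(0L, nrow = m, ncol = length(labs),
              dimnames = list(NULL, labs))
  for (i in topo) {
    cp <- net$cpts[[labs[i]]]
    k <- length(cp$parents)
    p1 <- if (k == 0L) rep(cp$table$p1[1L], m) else {
      idx <- 1L + as.vector(X[, cp$parents, drop = FALSE] %*%
                              2^(seq_len(k) - 1L))
      cp$table$p1[idx]
    }
    if (m > 0L) X[, i] <- as.integer(stats::runif(m) < p1)
  }
  out <- data.frame(patient_id = seq_len(m), X, check.names = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
simulate.mcc_bn <- function(object, nsim = 1, seed = NULL, ...) {
  sample_cohort(object, m = nsim, seed = seed)
}

#' Contaminate a ground-truth network with spurious edges
#'
#' Adds `count` randomly chosen temporally legal non-edges with small
#' logistic effects drawn uniformly from `[-effect_cap, effect_cap]`
#' (edges are marked in attribute `injected`), then rebuilds the
#' conditional probability tables from the generating spec. With
#' `effect_cap = 0` the added edges are pure noise: the sampling
#' distribution is unchanged.
#'
#' @param net An `mcc_bn` produced by [make_ground_truth()].
#' @param count Number of spurious edges to add.
#' @param effect_cap Maximum absolute log-odds effect (default 0.3).
#' @param seed Integer seed.
#' @return A new `mcc_bn` with attributes `gen_spec` (updated) and
#'   `injected` (data frame `from`, `to` of the added edges).
#' @export
inject_spurious_edges <- function(net, count, effect_cap = 0.3,
                                  seed = NULL) {
  spec <- attr(net, "gen_spec")
  if (is.null(spec)) stop("net must carry a generating spec ",
                          "(see make_ground_truth())")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  labs <- spec_labels(spec)
  allowed <- allowed_parent_matrix(labs, intra_year = TRUE)
  existing <- paste(match(spec$edges$from, labs), match(spec$edges$to, labs))
  legal <- which(allowed, arr.ind = TRUE)
  legal <- legal[!(paste(legal[, 1L], legal[, 2L]) %in% existing), ,
                 drop = FALSE]
  if (count > nrow(legal))
    stop("cannot inject ", count, " edges; only ", nrow(legal),
         " legal non-edges exist")
  pick <- sample(nrow(legal), count)
  new_edges <- data.frame(
    from = labs[legal[pick, 1L]], to = labs[legal[pick, 2L]],
    effect = stats::runif(count, -effect_cap, effect_cap))
  spec$edges <- rbind(spec$edges, new_edges)
  out <- make_ground_truth(spec)
  attr(out, "injected") <- new_edges[, c("from", "to")]
  out
}

#' Generate a synthetic weighted co-occurrence (lexicon) graph
#'
#' Emulates a term co-occurrence graph: a random spanning tree guarantees
#' connectivity, extra random pairs bring the edge count to `n_pairs`, and
#' weights are heavy-tailed co-occurrence counts. Defaults mirror the
#' scale of a 100-term, 200-pair lexicon.
#'
#' @param n_terms Number of terms (nodes).
#' @param n_pairs Number of word pairs (edges); at least `n_terms - 1`
#'   so the graph can be connected.
#' @param weight_law `"zipf"` (default; weight ~ ceiling of a Pareto
#'   draw) or `"lognormal"`.
#' @param seed Integer seed.
#' @return A connected weighted undirected [mcc_graph()] with labels
#'   `term001`, ...
#' @export
make_lexicon_graph <- function(n_terms = 100L, n_pairs = 200L,
                               weight_law = c("zipf", "lognormal"),
                               seed = NULL) {
  weight_law <- match.arg(weight_law)
  n_terms <- as.integer(n_terms); n_pairs <- as.integer(n_pairs)
  if (n_pairs > n_terms * (n_terms - 1L) / 2L)
    stop("n_pairs exceeds the number of possible term pairs")
  if (n_pairs < n_terms - 1L)
    stop("need at least n_terms - 1 pairs for a connected graph")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  labels <- sprintf("term%03d", seq_len(n_terms))
  # random recursive tree: node i attaches to a uniform earlier node
  tree_to <- if (n_terms > 1L)
    vapply(2:n_terms, function(i) sample.int(i - 1L, 1L), integer(1))
    else integer(0)
  edges <- data.frame(from = pmin(tree_to, 2:n_terms),
                      to = pmax(tree_to, 2:n_terms))
  have <- paste(edges$from, edges$to)
  while (nrow(edges) < n_pairs) {
    need <- n_pairs - nrow(edges)
    a <- sample.int(n_terms, 2L * need, replace = TRUE)
    b <- sample.int(n_terms, 2L * need, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    ok <- lo != hi & !duplicated(paste(lo, hi)) &
      !(paste(lo, hi) %in% have)
    add <- utils::head(which(ok), need)
    edges <- rbind(edges, data.frame(from = lo[add], to = hi[add]))
    have <- paste(edges$from, edges$to)
  }
  w <- switch(weight_law,
              zipf = ceiling(1 / stats::runif(n_pairs)^0.8),
              lognormal = ceiling(stats::rlnorm(n_pairs, 1, 1)))
  edges$weight <- pmin(as.numeric(w), 1e4)
  g <- mcc_graph(labels, edges, directed = FALSE)
  stopifnot(is_connected(g))
  g
}
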